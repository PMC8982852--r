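# Readers and writers for the standard interchange formats: FASTA, BED3/6,
# bedGraph, plus the dataset manifest and BED6 output for located regions.

#' Read a (multi-)FASTA file
#'
#' Sequences are upper-cased; record order is preserved. Parsing is
#' delegated to `Biostrings::readDNAStringSet`.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector mapping record name (first word of the
#'   header) to sequence.
#' @export
read_fasta <- function(path) {
  abort_if(!file.exists(path), sprintf("FASTA file not found: %s", path))
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  abort_if(length(first) == 0L, sprintf("empty FASTA file: %s", path))
  abort_if(!startsWith(first[[1L]], ">"), sprintf(
    "malformed FASTA (line 1 does not start with '>'): %s", path
  ))
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  abort_if(length(set) == 0L, sprintf("no FASTA records in: %s", path))
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(
    strsplit(names(set), "\\s+"), `[[`, character(1), 1L
  )
  seqs
}

#' Read BED intervals
#'
#' Accepts BED3 or wider; strand is taken from column 6 when present
#' (`"."` otherwise). Records with `start >= end` are rejected with a
#' warning; non-integer coordinates are a parse error.
#'
#' @param path Path to a tab-separated BED file.
#' @return A list of [genomic_interval()].
#' @export
read_bed_intervals <- function(path) {
  abort_if(!file.exists(path), sprintf("BED file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "", fill = TRUE)
  abort_if(ncol(tab) < 3L, "BED requires >= 3 tab-separated columns")
  starts <- suppressWarnings(as.numeric(tab[[2L]]))
  ends <- suppressWarnings(as.numeric(tab[[3L]]))
  bad <- is.na(starts) | is.na(ends) |
    starts != floor(starts) | ends != floor(ends)
  abort_if(any(bad), sprintf(
    "non-integer BED coordinates at line %d of %s", which(bad)[1L], path
  ))
  out <- vector("list", nrow(tab))
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (starts[i] >= ends[i]) {
      warning(sprintf("rejecting empty/inverted BED record at line %d (%s)",
                      i, path), call. = FALSE)
      next
    }
    strand <- if (ncol(tab) >= 6L && tab[[6L]][i] %in% c("+", "-")) {
      tab[[6L]][i]
    } else {
      "."
    }
    out[[i]] <- genomic_interval(tab[[1L]][i], starts[i], ends[i], strand)
    keep[i] <- TRUE
  }
  out[keep]
}

#' Extract a per-base signal track from a bedGraph file
#'
#' The bedGraph (`chrom start end value`) may cover the interval sparsely:
#' uncovered bases get 0 and overlapping records are resolved last-wins in
#' file order. If the interval's chromosome is absent from the track an
#' all-zero track is returned with a warning.
#'
#' @param path Path to a bedGraph / 4-column TSV file.
#' @param interval The `genomic_interval` to extract.
#' @return A [signal_track()] (raw, not normalized).
#' @export
read_signal_track <- function(path, interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  abort_if(!file.exists(path), sprintf("bedGraph file not found: %s", path))
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#", quote = "")
  abort_if(ncol(tab) < 4L, "bedGraph requires 4 columns")
  len <- interval_length(interval)
  values <- numeric(len)
  rows <- which(tab[[1L]] == interval$chrom)
  if (length(rows) == 0L) {
    warning(sprintf("chromosome %s absent from signal track %s; returning zeros",
                    interval$chrom, path), call. = FALSE)
    return(signal_track(interval, values))
  }
  for (i in rows) {
    s <- max(as.integer(tab[[2L]][i]), interval$start)
    e <- min(as.integer(tab[[3L]][i]), interval$end)
    if (s < e) {
      values[(s - interval$start + 1L):(e - interval$start)] <-
        as.numeric(tab[[4L]][i])
    }
  }
  signal_track(interval, values)
}

#' Write located binding regions as BED6
#'
#' One line per region: chrom, start, end, name, score (the sigmoid-of-max
#' binding probability), strand.
#'
#' @param regions List of `located_region` objects (see
#'   [locate_binding_region()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- vapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    sprintf("%s\t%d\t%d\tregion_%d\t%.6f\t%s",
            r$interval$chrom, r$interval$start, r$interval$end, i,
            r$score, r$interval$strand)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SNP table
#'
#' Tab-separated columns: chrom, pos (0-based), ref, alt; a header line is
#' optional (detected by a non-numeric second field).
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_snp_table <- function(path) {
  abort_if(!file.exists(path), sprintf("SNP table not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  abort_if(ncol(tab) < 4L, "SNP table requires 4 columns: chrom pos ref alt")
  if (is.na(suppressWarnings(as.numeric(tab[[2L]][1L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  data.frame(chrom = as.character(tab[[1L]]),
             pos = as.integer(tab[[2L]]),
             ref = toupper(as.character(tab[[3L]])),
             alt = toupper(as.character(tab[[4L]])),
             stringsAsFactors = FALSE)
}
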