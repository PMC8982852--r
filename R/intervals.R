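# Genomic coordinate records. All coordinates are BED-style: 0-based,
# half-open [start, end). Summits are offsets from `start`.

#' Create a genomic interval
#'
#' A lightweight record for a located genomic region using BED conventions
#' (0-based, half-open).
#'
#' @param chrom Chromosome / contig name.
#' @param start 0-based start (inclusive).
#' @param end End (exclusive); must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `genomic_interval` with fields `chrom`,
#'   `start`, `end`, `strand`.
#' @examples
#' gi <- genomic_interval("chr1", 10, 20)
#' interval_length(gi) # 10
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  abort_if(is.na(start) || is.na(end), "non-integer interval coordinates")
  abort_if(start < 0L, "interval start must be >= 0")
  abort_if(start >= end, sprintf(
    "empty or inverted interval: %s:%d-%d", chrom, start, end
  ))
  abort_if(!strand %in% c("+", "-", "."), "strand must be '+', '-' or '.'")
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         strand = strand),
    class = "genomic_interval"
  )
}

#' Length of a genomic interval in bp
#' @param interval A `genomic_interval`.
#' @return Integer width `end - start`.
#' @export
interval_length <- function(interval) interval$end - interval$start

#' @exportS3Method base::format
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%d-%d(%s)", x$chrom, x$start, x$end, x$strand)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval>", format(x), "\n")
  invisible(x)
}

#' Create a peak record
#'
#' A called peak: an interval plus (optionally) the offset of its signal
#' maximum (summit) and the maximal signal value.
#'
#' @param interval A [genomic_interval()].
#' @param summit Optional integer offset of the signal maximum from
#'   `interval$start`; must lie in `[0, length)`.
#' @param max_signal Optional real, the signal value at the summit.
#' @return An object of class `peak_record`.
#' @export
peak_record <- function(interval, summit = NULL, max_signal = NULL) {
  stopifnot(inherits(interval, "genomic_interval"))
  if (!is.null(summit)) {
    summit <- as.integer(summit)
    abort_if(summit < 0L || summit >= interval_length(interval),
             "summit offset outside the peak interval")
  }
  structure(
    list(interval = interval, summit = summit, max_signal = max_signal),
    class = "peak_record"
  )
}

#' Create a per-base signal track
#'
#' @param interval The `genomic_interval` the values are aligned to.
#' @param values Numeric vector, one value per base; length must equal the
#'   interval length and values must be non-negative.
#' @param normalized Logical; `TRUE` once `log10(1 + v)` has been applied.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(interval, values, normalized = FALSE) {
  stopifnot(inherits(interval, "genomic_interval"))
  values <- as.numeric(values)
  abort_if(length(values) != interval_length(interval),
           "signal length must equal interval length")
  abort_if(any(!is.finite(values)), "signal values must be finite")
  abort_if(any(values < 0), "signal values must be >= 0")
  structure(
    list(interval = interval, values = values, normalized = normalized),
    class = "signal_track"
  )
}

#' Expand a peak to a fixed-width window
#'
#' Produces a window of exactly `target_len` bp centred on the peak summit
#' when one is recorded, otherwise on the interval midpoint (floor). Windows
#' protruding beyond `[0, chrom_len)` are shifted inward so the full width
#' fits on the chromosome.
#'
#' @param peak A [peak_record()].
#' @param target_len Window width in bp (default 1000, the width used for
#'   model input).
#' @param chrom_len Chromosome length in bp.
#' @return A `genomic_interval` of width `target_len`.
#' @examples
#' pk <- peak_record(genomic_interval("chr1", 1000, 1400), summit = 200)
#' expand_peak(pk, 1000, 1e7) # chr1:700-1700
#' @export
expand_peak <- function(peak, target_len = 1000L, chrom_len) {
  stopifnot(inherits(peak, "peak_record"))
  target_len <- as.integer(target_len)
  chrom_len <- as.integer(chrom_len)
  abort_if(target_len < 1L, "target_len must be >= 1")
  abort_if(chrom_len < target_len,
           "chromosome shorter than the requested window")
  iv <- peak$interval
  center <- if (!is.null(peak$summit)) {
    iv$start + peak$summit
  } else {
    iv$start + interval_length(iv) %/% 2L
  }
  start <- center - target_len %/% 2L
  start <- max(0L, min(start, chrom_len - target_len))
  genomic_interval(iv$chrom, start, start + target_len, iv$strand)
}

#' Place a negative (non-binding) window upstream of a peak
#'
#' The negative control window has the same width as the peak window and
#' ends `gap` bp before the peak start ("upstream" meaning lower
#' coordinates, strand-agnostic). When there is not enough room near the
#' chromosome start, the window is placed symmetrically downstream of the
#' peak end instead and flagged.
#'
#' @param peak_interval A `genomic_interval` (typically the expanded peak).
#' @param gap Distance in bp between the negative window and the peak
#'   (default 3000).
#' @return A `genomic_interval` with attribute `"downstream_fallback"`
#'   (logical).
#' @examples
#' make_negative(genomic_interval("chr1", 10000, 11000)) # chr1:6000-7000
#' @export
make_negative <- function(peak_interval, gap = 3000L) {
  stopifnot(inherits(peak_interval, "genomic_interval"))
  gap <- as.integer(gap)
  abort_if(gap < 0L, "gap must be >= 0")
  len <- interval_length(peak_interval)
  fallback <- peak_interval$start < gap + len
  if (fallback) {
    start <- peak_interval$end + gap
  } else {
    start <- peak_interval$start - gap - len
  }
  out <- genomic_interval(peak_interval$chrom, start, start + len,
                          peak_interval$strand)
  attr(out, "downstream_fallback") <- fallback
  out
}

#' Count reads overlapping a region and log-scale the count (openness)
#'
#' The openness degree of a region is `log10(1 + n)` where `n` is the number
#' of reads overlapping the region by at least one bp (any-overlap counting,
#' as `bedtools multicov` does). Reads on other chromosomes are ignored.
#'
#' @param peak A `genomic_interval`.
#' @param reads A list of `genomic_interval` read alignments.
#' @return A single non-negative real.
#' @examples
#' pk <- genomic_interval("chr1", 100, 200)
#' rd <- list(genomic_interval("chr1", 150, 180),
#'            genomic_interval("chr2", 150, 180))
#' compute_openness(pk, rd) # log10(2)
#' @export
compute_openness <- function(peak, reads) {
  stopifnot(inherits(peak, "genomic_interval"))
  n <- 0L
  for (r in reads) {
    stopifnot(inherits(r, "genomic_interval"))
    if (r$chrom == peak$chrom && r$start < peak$end && r$end > peak$start) {
      n <- n + 1L
    }
  }
  log10(1 + n)
}
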