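# Motif (PFM) extraction from first-layer convolutional filters, and
# MEME-format output.

#' Select maximal-activation subsequences via first-layer filters
#'
#' For each sample the `region_width`-bp region centred on its signal argmax
#' is taken (clipped inward at the edges). Every first-layer convolutional
#' filter is slid over these regions (valid positions only); the filter with
#' the highest mean per-sample maximal activation is selected globally, and
#' each sample contributes the k-mer under that filter's maximal-activation
#' window (leftmost on ties), where k is the filter width.
#'
#' @param samples List of `binding_sample` (their `y` tracks supply the
#'   argmax; typically the positive training samples).
#' @param model A trained `binding_model`.
#' @param region_width Width of the region around the signal maximum
#'   (default 100).
#' @return Character vector of k-mers, with attributes `filter` (index of
#'   the selected filter) and `scores` (per-filter mean top activation).
#' @export
select_subregions <- function(samples, model, region_width = 100L) {
  abort_if(length(samples) == 0L, "empty sample list")
  stopifnot(inherits(model, "binding_model"))
  k <- model$config$kernel_sizes[1L]
  W <- model$params[["enc1.W"]] # C_out x (4*k), offset-major blocks
  n_filt <- nrow(W)
  regions <- vapply(samples, function(s) {
    L <- nchar(s$seq)
    w <- min(region_width, L)
    i <- which.max(s$y$values)
    start <- i - w %/% 2L
    start <- max(1L, min(start, L - w + 1L))
    substr(s$seq, start, start + w - 1L)
  }, character(1))
  n_pos_max <- nchar(regions[[1L]]) - k + 1L
  abort_if(n_pos_max < 1L, "region narrower than the first-layer filters")
  best_pos <- matrix(0L, nrow = length(regions), ncol = n_filt)
  best_act <- matrix(-Inf, nrow = length(regions), ncol = n_filt)
  for (si in seq_along(regions)) {
    oh <- t(one_hot_encode(regions[[si]])) # 4 x w
    w <- ncol(oh)
    npos <- w - k + 1L
    # im2col over valid windows, then one GEMM against all filters
    M <- matrix(0, nrow = 4L * k, ncol = npos)
    for (j in seq_len(k)) {
      M[((j - 1L) * 4L + 1L):(j * 4L), ] <- oh[, j:(j + npos - 1L)]
    }
    act <- W %*% M # n_filt x npos
    best_pos[si, ] <- max.col(act, ties.method = "first")
    best_act[si, ] <- act[cbind(seq_len(n_filt), best_pos[si, ])]
  }
  filter_scores <- colMeans(best_act)
  f <- which.max(filter_scores)
  kmers <- vapply(seq_along(regions), function(si) {
    substr(regions[[si]], best_pos[si, f], best_pos[si, f] + k - 1L)
  }, character(1))
  structure(kmers, filter = f, scores = filter_scores)
}

#' Build a position frequency matrix from aligned k-mers
#'
#' K-mers containing non-ACGT symbols are dropped with a warning.
#' Probabilities are `(count + pseudocount) / (n + 4 * pseudocount)` per
#' position.
#'
#' @param kmers Character vector of equal-length DNA strings.
#' @param pseudocount Added to each base count (default 0.25).
#' @return An object of class `pf_motif` with fields `counts` (k x 4
#'   integer), `probabilities` (k x 4, rows summing to 1), `width`,
#'   `n_sequences`, `pseudocount`.
#' @export
build_pfm <- function(kmers, pseudocount = 0.25) {
  abort_if(length(kmers) == 0L, "no k-mers supplied")
  k <- nchar(kmers[[1L]])
  abort_if(any(nchar(kmers) != k), "k-mers must all have the same length")
  clean <- grepl("^[ACGT]+$", toupper(kmers))
  if (any(!clean)) {
    warning(sprintf("dropping %d k-mer(s) with non-ACGT symbols",
                    sum(!clean)), call. = FALSE)
  }
  kmers <- toupper(kmers[clean])
  abort_if(length(kmers) == 0L, "no valid k-mers after filtering")
  counts <- matrix(0L, nrow = k, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  chars <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  for (b in 1:4) {
    counts[, b] <- colSums(chars == c("A", "C", "G", "T")[b])
  }
  n <- length(kmers)
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  structure(
    list(counts = counts, probabilities = probs, width = k,
         n_sequences = n, pseudocount = pseudocount),
    class = "pf_motif"
  )
}

#' @export
print.pf_motif <- function(x, ...) {
  consensus <- paste0(c("A", "C", "G", "T")[max.col(x$probabilities)],
                      collapse = "")
  cat(sprintf("<pf_motif> width %d, %d sequences, consensus %s\n",
              x$width, x$n_sequences, consensus))
  invisible(x)
}

#' Extract a motif from high-signal regions
#'
#' Convenience wrapper: [select_subregions()] then [build_pfm()].
#'
#' @inheritParams select_subregions
#' @inheritParams build_pfm
#' @return A `pf_motif`.
#' @export
extract_motif <- function(samples, model, region_width = 100L,
                          pseudocount = 0.25) {
  build_pfm(select_subregions(samples, model, region_width), pseudocount)
}

#' Reverse complement of a PFM
#'
#' @param motif A `pf_motif`.
#' @return The reverse-complement `pf_motif`.
#' @export
pfm_reverse_complement <- function(motif) {
  stopifnot(inherits(motif, "pf_motif"))
  flip <- function(m) {
    out <- m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
    colnames(out) <- c("A", "C", "G", "T")
    out
  }
  structure(
    list(counts = flip(motif$counts), probabilities = flip(motif$probabilities),
         width = motif$width, n_sequences = motif$n_sequences,
         pseudocount = motif$pseudocount),
    class = "pf_motif"
  )
}

#' Align a PFM against a reference PWM
#'
#' Slides the shorter matrix along the longer (gapless) and reports the
#' offset maximizing the mean per-position Pearson correlation between
#' aligned probability rows.
#'
#' @param motif A `pf_motif`.
#' @param pwm A `k x 4` probability matrix.
#' @return List with `offset` (of the shorter matrix within the longer,
#'   0-based), `mean_r` (mean per-position Pearson correlation at the best
#'   offset) and `strand` (`"+"`; no reverse-complement search).
#' @export
align_pfm <- function(motif, pwm) {
  stopifnot(inherits(motif, "pf_motif"))
  a <- motif$probabilities
  b <- pwm
  swapped <- nrow(a) < nrow(b)
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  nshift <- nrow(a) - nrow(b)
  best <- list(offset = 0L, mean_r = -Inf, strand = "+")
  for (off in 0:nshift) {
    rs <- vapply(seq_len(nrow(b)), function(i) {
      x <- a[off + i, ]
      y <- b[i, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
      stats::cor(x, y)
    }, numeric(1))
    m <- mean(rs)
    if (m > best$mean_r) best <- list(offset = off, mean_r = m, strand = "+")
  }
  best
}

#' Write a motif in minimal MEME format
#'
#' Emits a version header, ACGT alphabet, uniform background, and the
#' letter-probability matrix, so the file can feed downstream motif-matching
#' tools.
#'
#' @param motif A `pf_motif`.
#' @param name Motif identifier.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(motif, name, path) {
  stopifnot(inherits(motif, "pf_motif"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25000 C 0.25000 G 0.25000 T 0.25000", "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            motif$width, motif$n_sequences)
  ), con)
  writeLines(apply(motif$probabilities, 1L, function(r) {
    sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])
  }), con)
  invisible(path)
}

#' Read a motif written in minimal MEME format
#'
#' @param path Path to a MEME motif file.
#' @return A `pf_motif` (counts reconstructed as
#'   `round(probabilities * nsites)`).
#' @export
read_meme_motif <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^letter-probability matrix:", lines)
  abort_if(length(hdr) == 0L, "no letter-probability matrix block found")
  hdr <- hdr[1L]
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
  nsites <- as.integer(sub(".*nsites= *([0-9]+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1L):(hdr + w)]
  probs <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  colnames(probs) <- c("A", "C", "G", "T")
  structure(
    list(counts = round(probs * nsites), probabilities = probs,
         width = w, n_sequences = nsites, pseudocount = NA_real_),
    class = "pf_motif"
  )
}
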