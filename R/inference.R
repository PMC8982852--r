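# Downstream tasks derived from predicted base-resolution signal.

#' Predict per-base binding signal for a sequence of arbitrary length
#'
#' The sequence is right-padded with `N` (all-zero one-hot rows) to the next
#' multiple of the model's input-length multiple, run through the network,
#' and the output trimmed back to the input length.
#'
#' @param seq DNA string of length `>= config$input_len_multiple`.
#' @param model A trained `binding_model`.
#' @return Numeric vector of `nchar(seq)` predicted signal values.
#' @export
predict_signal <- function(seq, model) {
  stopifnot(inherits(model, "binding_model"))
  L <- nchar(seq)
  mult <- model$config$input_len_multiple
  abort_if(L < mult, sprintf(
    "sequence length %d below the minimum input length %d; supply at least one full multiple",
    L, mult
  ))
  pad <- (mult - L %% mult) %% mult
  padded <- if (pad > 0L) paste0(seq, strrep("N", pad)) else seq
  model_forward(one_hot_encode(padded), model)[seq_len(L)]
}

#' Classify a sequence as binding vs non-binding
#'
#' Binding probability is the logistic sigmoid of the signal maximum:
#' `sigma(max(signal))`, mapping the unbounded predicted maximum into
#' `[0, 1]`.
#'
#' @param signal Numeric vector of (predicted) per-base signal.
#' @return A probability in `[0, 1]`.
#' @examples
#' classify_sequence(c(0, 1.5, 0.2)) # 1 / (1 + exp(-1.5))
#' @export
classify_sequence <- function(signal) {
  abort_if(length(signal) == 0L, "empty signal")
  sigmoid(max(signal))
}

#' Locate the binding region within a scored window
#'
#' The region of `width` bp surrounding the signal argmax (first position on
#' ties) is extracted, clipped inward at the window edges so the full width
#' fits.
#'
#' @param signal Predicted per-base signal over the window.
#' @param window_offset `genomic_interval` of the scanned window (gives
#'   absolute coordinates).
#' @param width Extraction width in bp (default 60).
#' @return An object of class `located_region`: fields `interval`,
#'   `peak_position` (absolute argmax), `max_signal`, and `score`
#'   (`sigma(max)`).
#' @export
locate_binding_region <- function(signal, window_offset, width = 60L) {
  stopifnot(inherits(window_offset, "genomic_interval"))
  width <- as.integer(width)
  abort_if(width > length(signal), "width exceeds the scored window")
  i <- which.max(signal)
  abs_pos <- window_offset$start + i - 1L
  start <- abs_pos - width %/% 2L
  start <- max(window_offset$start, min(start, window_offset$end - width))
  structure(
    list(interval = genomic_interval(window_offset$chrom, start,
                                     start + width),
         peak_position = abs_pos,
         max_signal = max(signal),
         score = sigmoid(max(signal))),
    class = "located_region"
  )
}

#' @export
print.located_region <- function(x, ...) {
  cat(sprintf("<located_region> %s argmax %d max %.3f score %.3f\n",
              format(x$interval), x$peak_position, x$max_signal, x$score))
  invisible(x)
}

#' Scan a chromosome for candidate binding regions
#'
#' The sequence is segmented into consecutive non-overlapping windows (the
#' final partial window is N-padded), each window's signal is predicted, and
#' windows whose maximum exceeds `threshold` yield a located region of
#' `width` bp around the argmax.
#'
#' @param chrom_seq Chromosome/contig sequence.
#' @param model A trained `binding_model`.
#' @param window Window width in bp (default 1000).
#' @param threshold Minimum predicted signal maximum (default 1.5, on the
#'   normalized `log10(1+p)` scale).
#' @param width Extracted region width (default 60).
#' @param chrom Chromosome name used in the reported intervals.
#' @param chunk Number of windows per inference batch.
#' @return List of `located_region`, in coordinate order.
#' @export
scan_chromosome <- function(chrom_seq, model, window = 1000L,
                            threshold = 1.5, width = 60L, chrom = "chr",
                            chunk = 100L) {
  stopifnot(inherits(model, "binding_model"))
  len <- nchar(chrom_seq)
  window <- as.integer(window)
  abort_if(len < window, "sequence shorter than one window")
  abort_if(window %% model$config$input_len_multiple != 0L,
           "window must be a multiple of the model input-length multiple")
  n_win <- as.integer(ceiling(len / window))
  regions <- list()
  i <- 1L
  while (i <= n_win) {
    j <- min(i + chunk - 1L, n_win)
    nb <- j - i + 1L
    xb <- array(0, dim = c(4L, window, nb))
    starts <- integer(nb)
    ends <- integer(nb)
    for (kk in seq_len(nb)) {
      w0 <- (i + kk - 2L) * window
      w1 <- min(w0 + window, len)
      starts[kk] <- w0
      ends[kk] <- w1
      sub <- substr(chrom_seq, w0 + 1L, w1)
      if (nchar(sub) < window) sub <- paste0(sub, strrep("N", window - nchar(sub)))
      xb[, , kk] <- t(one_hot_encode(sub))
    }
    pred <- forward_batch(model, xb, training = FALSE)$pred
    for (kk in seq_len(nb)) {
      plen <- ends[kk] - starts[kk]
      sig <- pred[seq_len(plen), kk]
      if (plen >= width && max(sig) > threshold) {
        win_iv <- genomic_interval(chrom, starts[kk], ends[kk])
        regions[[length(regions) + 1L]] <-
          locate_binding_region(sig, win_iv, width)
      }
    }
    i <- j + 1L
  }
  regions
}

#' Score the regulatory effect of a SNP
#'
#' A `window`-bp region is centred on the SNP (shifted inward at chromosome
#' edges), the signal is predicted for the reference and the alternate
#' sequence, and the score is the absolute signal difference at the SNP
#' position: `|y_alt[i] - y_ref[i]|`.
#'
#' @param genome Named character vector of chromosome sequences (from
#'   [read_fasta()]).
#' @param snp List or one-row data.frame with `chrom`, `pos` (0-based),
#'   `ref`, `alt` single bases.
#' @param model A trained `binding_model`.
#' @param window Window width (default 1000).
#' @return A single non-negative score.
#' @export
score_snp <- function(genome, snp, model, window = 1000L) {
  chrom_seq <- genome[[snp$chrom]]
  abort_if(is.null(chrom_seq), sprintf("chromosome %s not in genome",
                                       snp$chrom))
  len <- nchar(chrom_seq)
  pos <- as.integer(snp$pos)
  window <- as.integer(window)
  abort_if(len < window, "chromosome shorter than the scoring window")
  start <- pos - window %/% 2L
  start <- max(0L, min(start, len - window))
  offset <- pos - start
  ref_seq <- substr(chrom_seq, start + 1L, start + window)
  have <- toupper(substr(ref_seq, offset + 1L, offset + 1L))
  abort_if(have != toupper(snp$ref), sprintf(
    "reference mismatch at %s:%d: genome has %s, SNP record says %s",
    snp$chrom, pos, have, snp$ref
  ))
  alt_seq <- ref_seq
  substr(alt_seq, offset + 1L, offset + 1L) <- toupper(snp$alt)
  y_ref <- predict_signal(ref_seq, model)
  y_alt <- predict_signal(alt_seq, model)
  abs(y_alt[offset + 1L] - y_ref[offset + 1L])
}

#' Score a table of SNPs
#'
#' @param genome Named character vector of sequences.
#' @param snps Data.frame from [read_snp_table()].
#' @param model A trained `binding_model`.
#' @param window Window width (default 1000).
#' @return `snps` with an added numeric `score` column.
#' @export
score_snp_table <- function(genome, snps, model, window = 1000L) {
  snps$score <- vapply(seq_len(nrow(snps)), function(i) {
    score_snp(genome, snps[i, ], model, window)
  }, numeric(1))
  snps
}
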