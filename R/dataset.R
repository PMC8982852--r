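# Supervised sample assembly and dataset splits.
#
# A sample keeps the raw sequence string (one-hot matrices are materialized
# batch-wise by stack_samples(), so a 4000-sample dataset does not hold
# 4000 separate L x 4 matrices in memory).

#' Create a supervised sample
#'
#' @param seq DNA sequence string.
#' @param y A normalized [signal_track()] of the same length.
#' @param label 1 for a peak-derived (binding) sample, 0 for a negative.
#' @param source The originating [peak_record()] (optional for synthetic
#'   data; a `peak_record` is synthesized from the track interval).
#' @return An object of class `binding_sample` with fields `seq`, `y`,
#'   `label`, `source`.
#' @export
make_sample <- function(seq, y, label, source = NULL) {
  stopifnot(inherits(y, "signal_track"))
  abort_if(nchar(seq) != length(y$values),
           "sequence and signal lengths differ")
  abort_if(!label %in% c(0L, 1L), "label must be 0 or 1")
  if (is.null(source)) source <- peak_record(y$interval)
  structure(
    list(seq = toupper(seq), y = y, label = as.integer(label),
         source = source),
    class = "binding_sample"
  )
}

#' Stack samples into dense model inputs
#'
#' @param samples List of `binding_sample`.
#' @return List with `x` (array `4 x L x N`, one-hot channels first), `y`
#'   (matrix `L x N` of normalized signal) and `labels` (integer vector).
#' @export
stack_samples <- function(samples) {
  abort_if(length(samples) == 0L, "no samples to stack")
  L <- nchar(samples[[1L]]$seq)
  N <- length(samples)
  x <- array(0, dim = c(4L, L, N))
  y <- matrix(0, nrow = L, ncol = N)
  for (i in seq_len(N)) {
    s <- samples[[i]]
    abort_if(nchar(s$seq) != L, "samples have differing lengths")
    x[, , i] <- t(one_hot_encode(s$seq))
    y[, i] <- s$y$values
  }
  list(x = x, y = y, labels = vapply(samples, `[[`, integer(1), "label"))
}

#' Random 80/10-of-80/20 dataset split
#'
#' 20% of the samples (floor) are held out as the test set; of the remaining
#' 80%, 10% (floor) become the validation set and the rest the training set.
#' Deterministic under `seed`.
#'
#' @param samples List of `binding_sample`.
#' @param seed Integer RNG seed.
#' @return List of class `dataset_split` with elements `train`,
#'   `validation`, `test`.
#' @export
split_random <- function(samples, seed) {
  n <- length(samples)
  abort_if(n < 10L, "need at least 10 samples to split")
  n_test <- n %/% 5L
  n_val <- (n - n_test) %/% 10L
  n_train <- n - n_test - n_val
  abort_if(n_test < 1L || n_val < 1L || n_train < 1L,
           "too few samples to populate train/validation/test")
  perm <- with_seed(seed, sample.int(n))
  structure(
    list(train = samples[perm[seq_len(n_train)]],
         validation = samples[perm[n_train + seq_len(n_val)]],
         test = samples[perm[n_train + n_val + seq_len(n_test)]]),
    class = "dataset_split"
  )
}

#' Chromosome-held-out dataset split
#'
#' All samples on `test_chrom` form the test set, all on `val_chrom` the
#' validation set, and everything else the training set.
#'
#' @param samples List of `binding_sample`.
#' @param test_chrom Held-out test chromosome (default `"chr17"`).
#' @param val_chrom Held-out validation chromosome (default `"chr18"`).
#' @return A `dataset_split`.
#' @export
split_chromosomal <- function(samples, test_chrom = "chr17",
                              val_chrom = "chr18") {
  chroms <- vapply(samples, function(s) s$source$interval$chrom, character(1))
  split <- structure(
    list(train = samples[!chroms %in% c(test_chrom, val_chrom)],
         validation = samples[chroms == val_chrom],
         test = samples[chroms == test_chrom]),
    class = "dataset_split"
  )
  if (length(split$test) == 0L) {
    warning(sprintf("no samples on test chromosome %s", test_chrom),
            call. = FALSE)
  }
  if (length(split$validation) == 0L) {
    warning(sprintf("no samples on validation chromosome %s", val_chrom),
            call. = FALSE)
  }
  split
}

#' Assemble supervised samples from genome, peaks and signal
#'
#' For each peak: the per-base signal over the called interval locates the
#' summit (argmax), the peak is expanded to `target_len` bp centred on the
#' summit, and the expanded window's sequence and normalized signal become a
#' positive sample. A same-width negative window `gap` bp upstream (with its
#' real, low signal) becomes the paired negative.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param peaks List of `genomic_interval` peaks (from
#'   [read_bed_intervals()]).
#' @param signal_path Path to the bedGraph signal track.
#' @param target_len Window width (default 1000).
#' @param gap Negative-placement gap (default 3000).
#' @return List of `binding_sample` (positives followed by negatives).
#' @export
prepare_samples <- function(genome, peaks, signal_path, target_len = 1000L,
                            gap = 3000L) {
  out <- list()
  for (iv in peaks) {
    abort_if(!iv$chrom %in% names(genome),
             sprintf("chromosome %s missing from FASTA", iv$chrom))
    chrom_len <- nchar(genome[[iv$chrom]])
    raw <- read_signal_track(signal_path, iv)
    summit <- which.max(raw$values) - 1L
    pk <- peak_record(iv, summit = summit,
                      max_signal = max(raw$values))
    win <- expand_peak(pk, target_len, chrom_len)
    pos_sig <- normalize_signal(read_signal_track(signal_path, win))
    pos_seq <- substr(genome[[iv$chrom]], win$start + 1L, win$end)
    out[[length(out) + 1L]] <- make_sample(pos_seq, pos_sig, 1L, pk)

    neg <- make_negative(win, gap)
    if (neg$end <= chrom_len) {
      neg_sig <- normalize_signal(read_signal_track(signal_path, neg))
      neg_seq <- substr(genome[[iv$chrom]], neg$start + 1L, neg$end)
      out[[length(out) + 1L]] <- make_sample(neg_seq, neg_sig, 0L,
                                             peak_record(neg))
    }
  }
  out
}

#' Write a prepared dataset to a directory
#'
#' Plain-text layout: `manifest.tsv` (chrom, start, end, label, summit),
#' `sequences.txt` (one sequence per line) and `signals.tsv` (one row of
#' per-base normalized signal per sample).
#'
#' @param samples List of `binding_sample`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(
    chrom = vapply(samples, function(s) s$y$interval$chrom, character(1)),
    start = vapply(samples, function(s) s$y$interval$start, integer(1)),
    end = vapply(samples, function(s) s$y$interval$end, integer(1)),
    label = vapply(samples, `[[`, integer(1), "label"),
    summit = vapply(samples, function(s) s$source$summit %||% NA_integer_,
                    integer(1))
  )
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(vapply(samples, `[[`, character(1), "seq"),
             file.path(dir, "sequences.txt"))
  sig <- t(vapply(samples, function(s) s$y$values,
                  numeric(length(samples[[1L]]$y$values))))
  utils::write.table(format(sig, digits = 10, trim = TRUE, scientific = FALSE),
                     file.path(dir, "signals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List of `binding_sample`.
#' @export
load_dataset <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  seqs <- readLines(file.path(dir, "sequences.txt"))
  sig <- as.matrix(utils::read.table(file.path(dir, "signals.tsv"),
                                     sep = "\t", header = FALSE))
  lapply(seq_len(nrow(man)), function(i) {
    iv <- genomic_interval(man$chrom[i], man$start[i], man$end[i])
    summit <- if (is.na(man$summit[i])) NULL else man$summit[i]
    make_sample(seqs[i], signal_track(iv, sig[i, ], normalized = TRUE),
                man$label[i], peak_record(iv, summit = summit))
  })
}
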