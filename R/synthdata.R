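# Synthetic motif-planted sequences with base-resolution signal tracks.
#
# The generator emulates prepared ChIP-seq windows: 1000-bp positives carry
# one PWM instance under a localized signal bump (raw amplitude 99, so the
# log10(1+v)-normalized maximum is ~2.0), negatives are background sequence
# with |Gaussian| baseline noise. Raw tracks are produced; normalization
# happens when samples are assembled, as for real data.

#' Packaged default motif
#'
#' A 12-bp probability matrix with one dominant base per position
#' (p = 0.86, others 0.14/3 each; information content ~1.2 bits/position).
#'
#' @return A `12 x 4` probability matrix (columns A, C, G, T).
#' @export
default_pwm <- function() {
  consensus <- "TGACGTCATCGA"
  bases <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  m <- matrix(0.14 / 3, nrow = length(bases), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- 0.86
  m
}

#' Specification of the synthetic-data generator
#'
#' @param pwm Motif probability matrix (rows sum to 1).
#' @param seq_len Window length in bp (default 1000).
#' @param n_pos,n_neg Number of positive / negative samples (defaults 2000
#'   each).
#' @param bump_amplitude Raw signal bump height (default 99, giving a
#'   normalized `log10(1+99) = 2` maximum, comfortably above the 1.5
#'   scanning threshold).
#' @param bump_sd Gaussian bump width in bp (default 75).
#' @param baseline_noise_sd SD of the |Gaussian| raw baseline noise
#'   (default 0.05).
#' @param gc_content Background GC fraction (default 0.41, human-like).
#' @param seed Integer master seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(pwm = default_pwm(), seq_len = 1000L,
                           n_pos = 2000L, n_neg = 2000L,
                           bump_amplitude = 99, bump_sd = 75,
                           baseline_noise_sd = 0.05, gc_content = 0.41,
                           seed = 1L) {
  abort_if(!is.matrix(pwm) || ncol(pwm) != 4L ||
             any(abs(rowSums(pwm) - 1) > 1e-6),
           "pwm must be a k x 4 matrix with rows summing to 1")
  abort_if(gc_content <= 0 || gc_content >= 1,
           "gc_content must be in (0, 1)")
  abort_if(bump_amplitude < 0 || bump_sd <= 0 || baseline_noise_sd < 0,
           "signal parameters must be non-negative (bump_sd positive)")
  structure(
    list(pwm = pwm, seq_len = as.integer(seq_len),
         n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         bump_amplitude = bump_amplitude, bump_sd = bump_sd,
         baseline_noise_sd = baseline_noise_sd, gc_content = gc_content,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

# RNG-consuming internals (callers manage the seed).
.bg_seq <- function(spec, len = spec$seq_len) {
  p <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
         spec$gc_content / 2, (1 - spec$gc_content) / 2)
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
         collapse = "")
}

.baseline_signal <- function(spec, len = spec$seq_len) {
  abs(stats::rnorm(len, 0, spec$baseline_noise_sd))
}

.draw_motif <- function(spec) {
  paste0(apply(spec$pwm, 1L, function(p) {
    sample(c("A", "C", "G", "T"), 1L, prob = p)
  }), collapse = "")
}

.bump <- function(len, center, amplitude, sd) {
  i <- seq_len(len) - 1L
  amplitude * exp(-(i - center)^2 / (2 * sd^2))
}

#' Sample background (negative) sequences with near-flat signal
#'
#' @param spec A [generator_spec()].
#' @param n Number of sequences.
#' @param seed Seed (defaults to the spec seed).
#' @return List of `n` items, each `list(seq, signal)` with raw signal.
#' @export
sample_background <- function(spec, n, seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  abort_if(n < 1L, "n must be >= 1")
  with_seed(seed, lapply(seq_len(n), function(i) {
    list(seq = .bg_seq(spec), signal = .baseline_signal(spec))
  }))
}

#' Plant one motif instance with a localized signal bump
#'
#' One PWM draw is written into background sequence at `position` (0-based
#' offset of the motif start, or `"random"` for a uniform admissible draw),
#' and a Gaussian bump of height `bump_amplitude` centred on the instance
#' center is added to the baseline signal.
#'
#' @param spec A [generator_spec()].
#' @param position Integer offset or `"random"`.
#' @param seed Seed (defaults to the spec seed).
#' @return `list(seq, signal, truth)`; `truth` holds `position` (motif
#'   start) and `center` (bump center).
#' @export
plant_motif_with_signal <- function(spec, position = "random",
                                    seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  k <- nrow(spec$pwm)
  with_seed(seed, .plant_one(spec, position, k))
}

.plant_one <- function(spec, position, k) {
  if (identical(position, "random")) {
    position <- sample.int(spec$seq_len - k + 1L, 1L) - 1L
  }
  position <- as.integer(position)
  abort_if(position < 0L || position + k > spec$seq_len,
           "motif position out of range")
  seq <- .bg_seq(spec)
  motif <- .draw_motif(spec)
  substr(seq, position + 1L, position + k) <- motif
  center <- position + k %/% 2L
  signal <- .baseline_signal(spec) +
    .bump(spec$seq_len, center, spec$bump_amplitude, spec$bump_sd)
  list(seq = seq, signal = signal,
       truth = list(position = position, center = center))
}

#' Benchmark set with binding regions shifted to fixed centers
#'
#' Plants the motif so its signal center sits exactly at each of `centers`
#' (defaults 250, 500, 750 bp in a 1000-bp window).
#'
#' @param spec A [generator_spec()] with `seq_len` 1000.
#' @param n_per_center Items per center (default 100).
#' @param centers Target bump centers.
#' @param seed Seed.
#' @return List of items `list(seq, signal, truth)`; `truth$center` is the
#'   stated center.
#' @export
shift_experiment_set <- function(spec, n_per_center = 100L,
                                 centers = c(250L, 500L, 750L),
                                 seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  k <- nrow(spec$pwm)
  with_seed(seed, {
    out <- list()
    for (ctr in centers) {
      for (i in seq_len(n_per_center)) {
        out[[length(out) + 1L]] <- .plant_one(spec, ctr - k %/% 2L, k)
      }
    }
    out
  })
}

#' Benchmark set with a motif-bearing core inserted at random offsets
#'
#' Each item is background sequence of `seq_len - core_width` bp into which
#' a `core_width`-bp motif-bearing core (motif centred within the core) is
#' spliced at a uniformly random offset, keeping the total length at
#' `seq_len`.
#'
#' @param spec A [generator_spec()].
#' @param core_width Width of the inserted core (default 100).
#' @param n Number of items (default 100).
#' @param seed Seed.
#' @return List of items `list(seq, signal, truth)`; `truth$offset` is the
#'   0-based insertion offset and `truth$center` the motif center.
#' @export
insertion_experiment_set <- function(spec, core_width = 100L, n = 100L,
                                     seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  core_width <- as.integer(core_width)
  abort_if(core_width >= spec$seq_len, "core_width must be < seq_len")
  k <- nrow(spec$pwm)
  abort_if(k > core_width, "core narrower than the motif")
  with_seed(seed, lapply(seq_len(n), function(i) {
    core <- .bg_seq(spec, core_width)
    cpos <- (core_width - k) %/% 2L
    substr(core, cpos + 1L, cpos + k) <- .draw_motif(spec)
    offset <- sample.int(spec$seq_len - core_width + 1L, 1L) - 1L
    bg <- .bg_seq(spec, spec$seq_len - core_width)
    seq <- paste0(substr(bg, 1L, offset), core,
                  substr(bg, offset + 1L, nchar(bg)))
    center <- offset + cpos + k %/% 2L
    signal <- .baseline_signal(spec) +
      .bump(spec$seq_len, center, spec$bump_amplitude, spec$bump_sd)
    list(seq = seq, signal = signal,
         truth = list(offset = offset, center = center))
  }))
}

#' Generate a full labelled dataset
#'
#' `n_pos` positives (motif planted at a uniformly random admissible
#' position) and `n_neg` background negatives, assembled as normalized
#' `binding_sample`s on a synthetic contig (samples are tiled end to end so
#' every interval is unique).
#'
#' @param spec A [generator_spec()].
#' @param chrom Contig name for the synthetic intervals.
#' @return List with `samples` (list of `binding_sample`, positives first)
#'   and `truth` (data.frame: id, label, position, center; NA for
#'   negatives).
#' @export
simulate_dataset <- function(spec, chrom = "synth1") {
  stopifnot(inherits(spec, "generator_spec"))
  k <- nrow(spec$pwm)
  pos <- with_seed(derive_seed(spec$seed, "pos"), {
    lapply(seq_len(spec$n_pos), function(i) .plant_one(spec, "random", k))
  })
  neg <- sample_background(spec, spec$n_neg,
                           seed = derive_seed(spec$seed, "neg"))
  n <- spec$n_pos + spec$n_neg
  samples <- vector("list", n)
  truth <- data.frame(id = seq_len(n),
                      label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)),
                      position = NA_integer_, center = NA_integer_)
  for (i in seq_len(spec$n_pos)) {
    iv <- genomic_interval(chrom, (i - 1L) * spec$seq_len, i * spec$seq_len)
    samples[[i]] <- make_sample(
      pos[[i]]$seq,
      normalize_signal(signal_track(iv, pos[[i]]$signal)),
      1L, peak_record(iv, summit = pos[[i]]$truth$center)
    )
    truth$position[i] <- pos[[i]]$truth$position
    truth$center[i] <- pos[[i]]$truth$center
  }
  for (j in seq_len(spec$n_neg)) {
    i <- spec$n_pos + j
    iv <- genomic_interval(chrom, (i - 1L) * spec$seq_len, i * spec$seq_len)
    samples[[i]] <- make_sample(
      neg[[j]]$seq,
      normalize_signal(signal_track(iv, neg[[j]]$signal)),
      0L, peak_record(iv)
    )
  }
  list(samples = samples, truth = truth)
}

#' Write a simulated dataset (plus truth table) to a directory
#'
#' Uses the same layout as [write_dataset()] plus `truth.tsv`.
#'
#' @param spec A [generator_spec()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
simulate_to_dir <- function(spec, dir) {
  sim <- simulate_dataset(spec)
  write_dataset(sim$samples, dir)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
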