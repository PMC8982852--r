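# Downstream tasks: classification, localization, scanning, SNP scores,
# openness.

test_that("classify_sequence is sigmoid of the maximum and monotone in it", {
  expect_equal(classify_sequence(c(0, -1)), 0.5)
  expect_equal(classify_sequence(c(0.2, 1.5, 0.1)), 1 / (1 + exp(-1.5)),
               tolerance = 1e-12)
  expect_lt(classify_sequence(rep(-50, 5)), 1e-20)
  set.seed(91)
  maxima <- sort(rnorm(50, sd = 2))
  probs <- vapply(maxima, function(m) classify_sequence(c(m - 1, m)),
                  numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("locate_binding_region centers on the argmax with edge clipping
           and first-tie preference", {
  win <- genomic_interval("chr1", 0, 1000)
  sig <- rep(0, 1000); sig[501] <- 3 # 0-based offset 500
  r <- locate_binding_region(sig, win, width = 60)
  expect_identical(c(r$interval$start, r$interval$end), c(470L, 530L))
  expect_identical(r$peak_position, 500L)
  expect_equal(r$score, 1 / (1 + exp(-3)), tolerance = 1e-12)

  sig2 <- rep(0, 1000); sig2[11] <- 2 # offset 10 -> clipped
  r2 <- locate_binding_region(sig2, win, width = 60)
  expect_identical(c(r2$interval$start, r2$interval$end), c(0L, 60L))

  sig3 <- rep(0, 1000); sig3[c(301, 601)] <- 2 # tie -> first
  r3 <- locate_binding_region(sig3, win, width = 60)
  expect_identical(r3$peak_position, 300L)

  off <- genomic_interval("chr2", 5000, 6000)
  r4 <- locate_binding_region(sig, off, width = 60)
  expect_identical(r4$interval$start, 5470L)
})

test_that("predict_signal pads to the multiple and trims to input length", {
  m <- init_model(tiny_arch(), seed = 2)
  s <- paste0(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  y <- predict_signal(s, m)
  expect_length(y, 300L)
  # contract: prediction equals the padded forward pass, trimmed
  padded <- paste0(s, strrep("N", 75))
  expect_identical(y, model_forward(one_hot_encode(padded), m)[1:300])
  expect_error(predict_signal(strrep("A", 80), m), "minimum input length")
})

test_that("padding does not perturb the prefix for a local-receptive-field
           model", {
  # Zeroing the GRU makes the bottleneck map (and hence the broadcast
  # context) identically zero, so the network becomes purely convolutional
  # with a finite receptive field. N-padding beyond the sequence then
  # matches the convolution's own zero padding exactly, and predictions
  # over the prefix agree except within one receptive field of the join
  # (the bottleneck conv/bilinear stencil spans ~3 positions of 125 bp).
  m <- init_model(tiny_arch(), seed = 13)
  for (nm in grep("^gru", names(m$params), value = TRUE)) {
    m$params[[nm]][] <- 0
  }
  s <- paste0(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  y0 <- predict_signal(s, m)
  y1 <- predict_signal(paste0(s, strrep("N", 125)), m)[1:1000]
  margin <- 400L
  expect_lt(max(abs(y0[1:(1000 - margin)] - y1[1:(1000 - margin)])), 1e-6)
})

test_that("scan_chromosome segments, thresholds and orders regions", {
  m <- init_model(tiny_arch(), seed = 4)
  s <- paste0(sample(c("A", "C", "G", "T"), 1250, TRUE), collapse = "")
  # impossible threshold -> all windows evaluated, none reported
  expect_length(scan_chromosome(s, m, window = 250L, threshold = 1e6), 0L)
  # threshold below every maximum -> one region per full window, in order
  regions <- scan_chromosome(s, m, window = 250L, threshold = -1e6,
                             width = 20L)
  expect_length(regions, 5L)
  starts <- vapply(regions, function(r) r$interval$start, integer(1))
  expect_identical(starts, sort(starts))
  expect_true(all(vapply(regions, function(r) r$max_signal, numeric(1)) >
                    -1e6))
  widths <- vapply(regions, function(r) interval_length(r$interval),
                   integer(1))
  expect_true(all(widths == 20L))
  # partial final window is padded and scanned
  s2 <- paste0(s, strrep("C", 100))
  regions2 <- scan_chromosome(s2, m, window = 250L, threshold = -1e6,
                              width = 20L)
  expect_length(regions2, 6L)
  expect_lte(regions2[[6L]]$interval$end, nchar(s2))
})

test_that("score_snp is zero for ref==alt-like inputs and symmetric", {
  m <- init_model(tiny_arch(), seed = 6)
  set.seed(99)
  chrom <- paste0(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  genome <- c(chrA = chrom)
  pos <- 900L
  ref <- substr(chrom, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  s1 <- score_snp(genome, list(chrom = "chrA", pos = pos, ref = ref,
                               alt = alt), m, window = 250L)
  expect_gte(s1, 0)
  # swapping ref/alt roles scores the mirrored variant identically
  alt_genome <- genome
  substr(alt_genome[["chrA"]], pos + 1L, pos + 1L) <- alt
  s2 <- score_snp(alt_genome, list(chrom = "chrA", pos = pos, ref = alt,
                                   alt = ref), m, window = 250L)
  expect_equal(s1, s2, tolerance = 1e-9)
  expect_error(
    score_snp(genome, list(chrom = "chrA", pos = pos, ref = alt, alt = ref),
              m, window = 250L),
    "reference mismatch"
  )
})

test_that("score_snp is zero under an input-independent model", {
  m <- init_model(tiny_arch(), seed = 8)
  # zero conv1 weights: the network output no longer depends on sequence
  m$params[["enc1.W"]][] <- 0
  set.seed(17)
  chrom <- paste0(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  genome <- c(c1 = chrom)
  for (pos in c(100L, 500L, 900L)) {
    ref <- substr(chrom, pos + 1L, pos + 1L)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
    expect_equal(score_snp(genome, list(chrom = "c1", pos = pos, ref = ref,
                                        alt = alt), m, window = 250L), 0)
  }
})

test_that("compute_openness matches the brute-force overlap counter", {
  expect_equal(compute_openness(genomic_interval("c", 0, 10), list()), 0)
  nine <- lapply(1:9, function(i) genomic_interval("c", i, i + 5))
  expect_equal(compute_openness(genomic_interval("c", 0, 100), nine), 1)

  set.seed(23)
  for (rep in 1:200) {
    peak <- genomic_interval("c", s <- sample(0:500, 1),
                             s + sample(10:100, 1))
    reads <- lapply(seq_len(sample(0:30, 1)), function(i) {
      genomic_interval(sample(c("c", "d"), 1), r <- sample(0:600, 1),
                       r + sample(5:50, 1))
    })
    expect_equal(compute_openness(peak, reads), oracle_openness(peak, reads))
  }
})
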