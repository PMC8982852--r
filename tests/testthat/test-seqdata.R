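# Readers, encodings, window arithmetic, and dataset splits.

test_that("read_fasta parses, normalizes case and line wrapping, keeps order", {
  path <- write_tmp(c(">a desc", "ac", "gt", ">b", "TTTT"), ".fa")
  seqs <- read_fasta(path)
  expect_identical(seqs, c(a = "ACGT", b = "TTTT"))

  expect_error(read_fasta(write_tmp("ACGT", ".fa")), "malformed FASTA")
  expect_error(read_fasta(write_tmp(character(0), ".fa")), "empty FASTA")
})

test_that("read_bed_intervals handles BED3/BED6, rejects empty intervals", {
  path <- write_tmp(c("chr1\t10\t20",
                      "chr1\t10\t10",
                      "chr2\t5\t50\tx\t0\t-"))
  expect_warning(ivs <- read_bed_intervals(path), "rejecting")
  expect_length(ivs, 2L)
  expect_identical(ivs[[1L]]$start, 10L)
  expect_identical(ivs[[1L]]$strand, ".")
  expect_identical(ivs[[2L]]$strand, "-")

  expect_error(read_bed_intervals(write_tmp("chr1\t1.5\t7")), "non-integer")
})

test_that("read_signal_track fills gaps with 0 and resolves overlaps last-wins", {
  iv <- genomic_interval("chr1", 0, 8)
  path <- write_tmp(c("chr1\t0\t4\t2.0",
                      "chr1\t2\t5\t3.0",
                      "chr1\t6\t8\t1.0"))
  tr <- read_signal_track(path, iv)
  expect_equal(tr$values, c(2, 2, 3, 3, 3, 0, 1, 1))

  expect_warning(tr2 <- read_signal_track(path, genomic_interval("chrX", 0, 4)),
                 "absent")
  expect_equal(tr2$values, rep(0, 4))
})

test_that("one_hot_encode matches the stated A/C/G/T columns and N rule", {
  expect_equal(one_hot_encode("A")[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unname(one_hot_encode("ACGT")), diag(4))
  expect_equal(sum(one_hot_encode("N")), 0)
  expect_error(one_hot_encode(""), "non-empty")
})

test_that("one-hot encode/decode round-trips ACGT sequences", {
  set.seed(3)
  for (i in 1:20) {
    s <- paste0(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    expect_identical(one_hot_decode(one_hot_encode(s)), s)
  }
})

test_that("expand_peak centers on summit or midpoint and shifts inward", {
  pk <- peak_record(genomic_interval("chr1", 1000, 1400), summit = 200)
  out <- expand_peak(pk, 1000, 1e7)
  expect_identical(c(out$start, out$end), c(700L, 1700L))

  near <- peak_record(genomic_interval("chr1", 250, 350), summit = 50)
  out <- expand_peak(near, 1000, 10000) # summit at 300
  expect_identical(c(out$start, out$end), c(0L, 1000L))

  nos <- peak_record(genomic_interval("chr1", 0, 1000))
  out <- expand_peak(nos, 1000, 5000)
  expect_identical(c(out$start, out$end), c(0L, 1000L))

  expect_error(expand_peak(pk, 1000, 500), "shorter")
})

test_that("expand_peak output always has target length inside the chromosome", {
  set.seed(11)
  for (i in 1:50) {
    cl <- sample(2000:5000, 1)
    s <- sample(0:(cl - 100), 1)
    pk <- peak_record(genomic_interval("c", s, s + 100),
                      summit = sample(0:99, 1))
    out <- expand_peak(pk, 1000, cl)
    expect_identical(interval_length(out), 1000L)
    expect_gte(out$start, 0L)
    expect_lte(out$end, cl)
  }
})

test_that("make_negative places upstream windows and flags the fallback", {
  neg <- make_negative(genomic_interval("chr1", 10000, 11000))
  expect_identical(c(neg$start, neg$end), c(6000L, 7000L))
  expect_false(attr(neg, "downstream_fallback"))

  fb <- make_negative(genomic_interval("chr1", 3500, 4500))
  expect_identical(c(fb$start, fb$end), c(7500L, 8500L))
  expect_true(attr(fb, "downstream_fallback"))

  ab <- make_negative(genomic_interval("chr1", 5000, 6000), gap = 0)
  expect_identical(ab$end, 5000L)

  # upstream placement never overlaps the peak
  set.seed(4)
  for (i in 1:30) {
    s <- sample(5000:20000, 1)
    iv <- genomic_interval("c", s, s + 1000)
    ng <- make_negative(iv)
    if (!attr(ng, "downstream_fallback")) expect_lte(ng$end, iv$start)
  }
})

test_that("normalize_signal is log10(1+v), order-preserving, 0 -> 0", {
  iv <- genomic_interval("chr1", 0, 3)
  tr <- normalize_signal(signal_track(iv, c(0, 9, 99)))
  expect_equal(tr$values, c(0, 1, 2))
  expect_true(tr$normalized)
  expect_error(normalize_signal(tr), "already normalized")

  set.seed(5)
  v <- sort(runif(1000, 0, 50))
  out <- normalize_signal(signal_track(genomic_interval("c", 0, 1000), v))
  expect_true(all(diff(out$values) >= 0))
  expect_equal(out$values[v == 0], numeric(0)) # no exact zeros drawn
})

make_dummy_samples <- function(n, chroms = "chr1") {
  lapply(seq_len(n), function(i) {
    iv <- genomic_interval(sample(chroms, 1), (i - 1) * 10, i * 10)
    make_sample(strrep("A", 10),
                signal_track(iv, rep(0.1, 10), normalized = TRUE),
                label = i %% 2L, source = peak_record(iv))
  })
}

test_that("split_random uses 80/10-of-80/20 fractions and is deterministic", {
  samples <- make_dummy_samples(100)
  sp <- split_random(samples, seed = 1)
  expect_length(sp$train, 72L)
  expect_length(sp$validation, 8L)
  expect_length(sp$test, 20L)
  sp2 <- split_random(samples, seed = 1)
  expect_identical(sp, sp2)
  expect_error(split_random(samples[1:5], 1), "at least 10")
})

test_that("splits are exact partitions for random sizes", {
  set.seed(9)
  for (n in sample(12:200, 20)) {
    samples <- make_dummy_samples(n)
    sp <- split_random(samples, seed = n)
    ids <- function(part) vapply(part, function(s) s$y$interval$start,
                                 integer(1))
    all_ids <- c(ids(sp$train), ids(sp$validation), ids(sp$test))
    expect_identical(sort(all_ids), sort(ids(samples)))
    expect_identical(anyDuplicated(all_ids), 0L)
  }
})

test_that("split_chromosomal partitions by chromosome and warns when empty", {
  samples <- make_dummy_samples(60, chroms = c("chr1", "chr17", "chr18"))
  sp <- split_chromosomal(samples)
  chrom_of <- function(part) vapply(part, function(s) s$source$interval$chrom,
                                    character(1))
  expect_true(all(chrom_of(sp$test) == "chr17"))
  expect_true(all(chrom_of(sp$validation) == "chr18"))
  expect_false(any(chrom_of(sp$train) %in% c("chr17", "chr18")))
  expect_identical(length(sp$train) + length(sp$validation) + length(sp$test),
                   60L)
  expect_warning(split_chromosomal(samples, test_chrom = "chr21"),
                 "chr21")
})

test_that("prepare_samples builds paired positive/negative windows", {
  chrom <- paste0(strrep("ACGT", 3000)) # 12 kb
  fa <- write_tmp(c(">chr1", chrom), ".fa")
  genome <- read_fasta(fa)
  sig <- write_tmp(c("chr1\t9000\t9100\t5.0", "chr1\t9100\t9200\t20.0",
                     "chr1\t9200\t9300\t5.0"))
  peaks <- list(genomic_interval("chr1", 9000, 9300))
  samples <- prepare_samples(genome, peaks, sig, target_len = 1000,
                             gap = 3000)
  expect_length(samples, 2L)
  expect_identical(samples[[1L]]$label, 1L)
  expect_identical(samples[[2L]]$label, 0L)
  # positive window centered on the signal argmax (offset 100 -> abs 9100)
  expect_identical(samples[[1L]]$y$interval$start, 8600L)
  expect_true(samples[[1L]]$y$normalized)
  expect_equal(max(samples[[1L]]$y$values), log10(21))
  # negative is 3000 bp upstream of the expanded window, same width
  expect_identical(samples[[2L]]$y$interval$start, 8600L - 3000L - 1000L)
  expect_lt(max(samples[[2L]]$y$values), 1e-12)
})

test_that("write_dataset/load_dataset round-trip", {
  sim <- simulate_dataset(tiny_spec(5L, 5L))
  dir <- tempfile()
  write_dataset(sim$samples, dir)
  back <- load_dataset(dir)
  expect_length(back, 10L)
  expect_identical(back[[1L]]$seq, sim$samples[[1L]]$seq)
  expect_equal(back[[3L]]$y$values, sim$samples[[3L]]$y$values,
               tolerance = 1e-8)
  expect_identical(vapply(back, `[[`, integer(1), "label"),
                   vapply(sim$samples, `[[`, integer(1), "label"))
})
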