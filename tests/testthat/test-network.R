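# Network architecture: shape contracts, layer oracles, symmetry and
# gradient correctness.

test_that("model_config validates its invariants", {
  cfg <- model_config()
  expect_identical(cfg$input_len_multiple, 125L)
  expect_error(model_config(kernel_sizes = c(14L, 5L, 3L)), "odd")
  expect_error(model_config(gru_hidden = 32L), "gru_hidden")
  expect_error(model_config(blend_channels = c(128L, 96L, 64L, 1L)),
               "blend_channels")
})

test_that("forward preserves length for all multiples and is deterministic", {
  m <- init_model(tiny_arch(dropout = 0.2), seed = 3)
  for (L in c(125L, 250L, 1000L)) {
    x <- one_hot_encode(paste0(sample(c("A", "C", "G", "T"), L, TRUE),
                               collapse = ""))
    y1 <- model_forward(x, m)
    y2 <- model_forward(x, m)
    expect_length(y1, L)
    expect_identical(y1, y2) # dropout off at inference
  }
  expect_error(model_forward(one_hot_encode(strrep("A", 100)), m),
               "not divisible")
})

test_that("encoder block output matches the conv oracle and shape contract", {
  set.seed(21)
  C <- 3L; L <- 20L; Co <- 4L; k <- 5L
  x <- array(rnorm(C * L * 2), dim = c(C, L, 2L))
  W <- matrix(rnorm(Co * C * k), Co)
  b <- rnorm(Co)
  y <- bindsignal:::conv_forward(x, W, b, k, relu_out = TRUE)
  for (n in 1:2) {
    expect_equal(y[, , n], pmax(oracle_conv1d(x[, , n], W, b, k), 0),
                 tolerance = 1e-12)
  }
  mp <- bindsignal:::maxpool_forward(y, 5L)
  expect_identical(dim(mp$y), c(Co, 4L, 2L))
  # all-zero input with zero bias stays zero through conv+relu
  z <- bindsignal:::conv_forward(array(0, dim(x)), W, numeric(Co), k,
                                 relu_out = TRUE)
  expect_equal(max(abs(z)), 0)
})

test_that("max pooling picks in-group maxima (first on ties)", {
  x <- array(c(1, 5, 5, 2, 0, -1), dim = c(1L, 6L, 1L))
  out <- bindsignal:::maxpool_forward(x, 3L)
  expect_equal(as.numeric(out$y), c(5, 2))
  dy <- array(c(1, 1), dim = c(1L, 2L, 1L))
  dx <- bindsignal:::maxpool_backward(dy, out$cache)
  expect_equal(as.numeric(dx), c(0, 1, 0, 1, 0, 0)) # first max wins
})

test_that("GRU matches the step-by-step recurrence oracle", {
  set.seed(31)
  for (rep in 1:50) {
    C <- sample(1:3, 1); H <- sample(1:3, 1); Tn <- sample(1:5, 1)
    p <- list(Wr = matrix(rnorm(H * C, sd = 0.5), H),
              Wz = matrix(rnorm(H * C, sd = 0.5), H),
              Wc = matrix(rnorm(H * C, sd = 0.5), H),
              Ur = matrix(rnorm(H * H, sd = 0.5), H),
              Uz = matrix(rnorm(H * H, sd = 0.5), H),
              Uc = matrix(rnorm(H * H, sd = 0.5), H))
    x <- array(rnorm(C * Tn * 2), dim = c(C, Tn, 2L))
    fwd <- bindsignal:::gru_direction_forward(x, p)
    bwd <- bindsignal:::gru_direction_forward(x, p, reverse = TRUE)
    for (n in 1:2) {
      expect_equal(fwd$h[, , n], oracle_gru(matrix(x[, , n], nrow = C), p),
                   tolerance = 1e-6, ignore_attr = TRUE)
      expect_equal(bwd$h[, , n],
                   oracle_gru(matrix(x[, , n], nrow = C), p, reverse = TRUE),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("GRU degenerate cases: zero weights and T = 1 symmetry", {
  H <- 3L; C <- 2L
  zero <- list(Wr = matrix(0, H, C), Wz = matrix(0, H, C),
               Wc = matrix(0, H, C), Ur = matrix(0, H, H),
               Uz = matrix(0, H, H), Uc = matrix(0, H, H))
  x <- array(rnorm(C * 4 * 2), dim = c(C, 4L, 2L))
  out <- bindsignal:::bigru_forward(x, zero, zero)
  expect_equal(max(abs(out$h)), 0) # tanh(0) recursion stays at 0

  set.seed(5)
  p <- lapply(zero, function(w) matrix(rnorm(length(w)), nrow = H))
  x1 <- array(rnorm(C * 1 * 2), dim = c(C, 1L, 2L))
  both <- bindsignal:::bigru_forward(x1, p, p)
  one <- bindsignal:::gru_direction_forward(x1, p)
  expect_equal(both$h, 2 * one$h, tolerance = 1e-12) # fwd == bwd at T = 1
})

test_that("BiGRU output map reverses when the input is reversed", {
  set.seed(41)
  H <- 4L; C <- 4L; Tn <- 6L
  mk <- function(nc) matrix(rnorm(H * nc, sd = 0.4), H)
  pf <- list(Wr = mk(C), Wz = mk(C), Wc = mk(C), Ur = mk(H), Uz = mk(H),
             Uc = mk(H))
  pb <- list(Wr = mk(C), Wz = mk(C), Wc = mk(C), Ur = mk(H), Uz = mk(H),
             Uc = mk(H))
  x <- array(rnorm(C * Tn), dim = c(C, Tn, 1L))
  xr <- x[, rev(seq_len(Tn)), , drop = FALSE]
  # reversing input and swapping direction parameters reverses the output
  h1 <- bindsignal:::bigru_forward(x, pf, pb)$h
  h2 <- bindsignal:::bigru_forward(xr, pb, pf)$h
  expect_equal(h1, h2[, rev(seq_len(Tn)), , drop = FALSE], tolerance = 1e-12)
})

test_that("global average pooling matches direct mean and broadcast-add", {
  set.seed(51)
  h <- array(rnorm(3 * 7 * 2), dim = c(3L, 7L, 2L))
  ctx <- bindsignal:::global_average_context(h)
  for (c in 1:3) for (n in 1:2) {
    expect_equal(ctx[c, n], sum(h[c, , n]) / 7, tolerance = 1e-12)
  }
  const <- array(2.5, dim = c(3L, 4L, 1L))
  expect_equal(bindsignal:::global_average_context(const),
               matrix(2.5, 3, 1), tolerance = 1e-12)
  added <- bindsignal:::context_add_forward(h)$y
  expect_equal(added[2, 3, 1], h[2, 3, 1] + ctx[2, 1], tolerance = 1e-12)
})

test_that("bilinear upsampling matches the interpolation oracle and maps
           constants to constants", {
  set.seed(61)
  for (rep in 1:50) {
    Tn <- sample(2:8, 1); s <- sample(2:5, 1)
    v <- rnorm(Tn)
    x <- array(v, dim = c(1L, Tn, 1L))
    y <- bindsignal:::bilinear_forward(x, s)$y
    expect_equal(as.numeric(y), oracle_bilinear(v, s), tolerance = 1e-9)
  }
  for (s in 2:5) {
    const <- array(3.7, dim = c(2L, 8L, 1L))
    up <- bindsignal:::bilinear_forward(const, s)$y
    expect_equal(range(up), c(3.7, 3.7), tolerance = 1e-12)
  }
})

test_that("decoder stage preserves constants through upsample (s = 5, L = 8)", {
  x <- array(1.25, dim = c(4L, 8L, 2L))
  up <- bindsignal:::bilinear_forward(x, 5L)
  expect_identical(dim(up$y), c(4L, 40L, 2L))
  expect_equal(range(up$y), c(1.25, 1.25))
})

test_that("analytic gradients match finite differences end to end", {
  cfg <- model_config(conv_channels = c(3L, 4L, 5L),
                      kernel_sizes = c(3L, 3L, 3L),
                      pool_sizes = c(2L, 2L, 2L), dropout_rate = 0,
                      gru_hidden = 5L, blend_channels = c(4L, 3L, 2L, 1L))
  m <- init_model(cfg, seed = 7)
  set.seed(71)
  N <- 2L; L <- 16L
  x <- array(0, dim = c(4, L, N))
  for (n in 1:N) for (t in 1:L) x[sample(1:4, 1), t, n] <- 1
  y <- matrix(rnorm(L * N), L, N)
  fb <- bindsignal:::forward_batch(m, x, training = TRUE, keep_cache = TRUE)
  g <- bindsignal:::backward_batch(m, fb$cache, 2 * (fb$pred - y) / length(y))
  loss_at <- function(params) {
    mm <- m; mm$params <- params
    mean((bindsignal:::forward_batch(mm, x, training = TRUE)$pred - y)^2)
  }
  eps <- 1e-5
  for (nm in names(g)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                   ignore_attr = TRUE,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("model checkpoints round-trip through save_model/load_model", {
  m <- init_model(tiny_arch(), seed = 9)
  path <- tempfile(fileext = ".ckpt")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$params, m$params)
  expect_identical(back$config$conv_channels, m$config$conv_channels)
  x <- one_hot_encode(strrep("ACGTG", 25))
  expect_identical(model_forward(x, back), model_forward(x, m))
})
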