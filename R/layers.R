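# Layer primitives with hand-derived backward passes.
#
# Feature maps are dense arrays of dim (channels C, positions L, batch N).
# The per-element kernels (im2col convolution with fused ReLU, max pooling,
# bilinear interpolation) live in src/ops.cpp and operate on no-copy views;
# batch normalization, dropout, the GRU recurrence and the global-context
# pooling are thin enough to stay in R. All math is double precision.

# ---- 1-D convolution (same-length, symmetric zero padding) ----
#
# W is a (C_out x C_in*k) matrix: rows of the internal im2col matrix are
# ordered by kernel offset j = 1..k, each offset contributing a C_in block.
# relu_in applies ReLU to the input (decoder blending order BN->ReLU->conv),
# relu_out to the output (encoder order conv->ReLU). The backward pass
# rebuilds the im2col matrix from the cached input; dx is skipped for the
# input layer (need_dx = FALSE).

conv_forward <- function(x, W, b, k, relu_in = FALSE, relu_out = FALSE) {
  cpp_conv_forward(x, W, b, as.integer(k), relu_in, relu_out)
}

conv_backward <- function(dy, x, y, W, k, relu_in = FALSE,
                          relu_out = FALSE, need_dx = TRUE) {
  cpp_conv_backward(dy, x, y, W, as.integer(k), relu_in, relu_out, need_dx)
}

# ---- Max pooling (non-overlapping, stride == width) ----

maxpool_forward <- function(x, pool) {
  L <- dim(x)[2L]
  abort_if(L %% pool != 0L,
           sprintf("length %d not divisible by pool size %d", L, pool))
  out <- cpp_maxpool_forward(x, as.integer(pool))
  list(y = out$y, cache = list(amax = out$amax, pool = as.integer(pool)))
}

maxpool_backward <- function(dy, cache) {
  cpp_maxpool_backward(dy, cache$amax, cache$pool)
}

# ---- Inverted dropout (identity at inference) ----

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(y = x, cache = NULL))
  }
  keep <- 1 - rate
  mask <- array((stats::runif(length(x)) < keep) / keep, dim = dim(x))
  list(y = x * mask, cache = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- Bilinear upsampling (align_corners = FALSE, edge replication) ----

# Interpolation stencil for integer factor s: output position i (0-based)
# reads source coordinate (i + 0.5)/s - 0.5, clamped to the valid range.
bilinear_stencil <- function(t_in, s) {
  t_out <- t_in * s
  i <- seq_len(t_out) - 1L
  src <- (i + 0.5) / s - 0.5
  src <- pmin(pmax(src, 0), t_in - 1)
  lo <- floor(src)
  w_hi <- src - lo
  hi <- pmin(lo + 1, t_in - 1)
  list(lo = as.integer(lo), hi = as.integer(hi),
       w_lo = 1 - w_hi, w_hi = w_hi, t_out = t_out)
}

bilinear_forward <- function(x, s) {
  if (s == 1L) return(list(y = x, cache = NULL))
  t_in <- dim(x)[2L]
  st <- bilinear_stencil(t_in, s)
  y <- cpp_bilinear_forward(x, st$lo, st$hi, st$w_lo, st$w_hi)
  list(y = y, cache = list(st = st, t_in = t_in))
}

bilinear_backward <- function(dy, s, cache) {
  if (s == 1L) return(dy)
  st <- cache$st
  cpp_bilinear_backward(dy, cache$t_in, st$lo, st$hi, st$w_lo, st$w_hi)
}

# ---- Batch normalization (per channel over positions x batch) ----

batchnorm_forward <- function(x, gamma, beta, run_mean, run_var,
                              training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[1L]
  M <- d[2L] * d[3L]
  xm <- x
  dim(xm) <- c(C, M)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v <- pmax(v, 0)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * M / max(M - 1L, 1L)
  } else {
    mu <- run_mean
    v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * invstd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    training = training),
       run_mean = run_mean, run_var = run_var)
}

batchnorm_backward <- function(dy, cache) {
  d <- cache$d
  C <- d[1L]
  M <- d[2L] * d[3L]
  dim(dy) <- c(C, M)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  if (cache$training) {
    dxhat <- dy * cache$gamma
    dx <- (cache$invstd / M) *
      (M * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dx <- dy * cache$gamma * cache$invstd
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- Gated recurrent unit (no bias terms, zero initial state) ----
#
# Recurrence per step:
#   r_t = sigmoid(W_r x_t + U_r h_{t-1})
#   z_t = sigmoid(W_z x_t + U_z h_{t-1})
#   c_t = tanh(W x_t + U (r_t * h_{t-1}))
#   h_t = (1 - z_t) * h_{t-1} + z_t * c_t

gru_direction_forward <- function(x, p, reverse = FALSE) {
  d <- dim(x)
  Tn <- d[2L]; N <- d[3L]
  H <- nrow(p$Wr)
  order_t <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h <- matrix(0, nrow = H, ncol = N)
  hs <- array(0, dim = c(H, Tn, N))
  steps <- vector("list", Tn)
  for (k in seq_len(Tn)) {
    t <- order_t[k]
    xt <- matrix(x[, t, ], nrow = d[1L])
    r <- sigmoid(p$Wr %*% xt + p$Ur %*% h)
    z <- sigmoid(p$Wz %*% xt + p$Uz %*% h)
    cc <- tanh(p$Wc %*% xt + p$Uc %*% (r * h))
    h_new <- (1 - z) * h + z * cc
    steps[[k]] <- list(t = t, xt = xt, r = r, z = z, cc = cc, h_prev = h)
    h <- h_new
    hs[, t, ] <- h
  }
  list(h = hs, cache = list(steps = steps, dims = d))
}

gru_direction_backward <- function(dh_out, p, cache) {
  d <- cache$dims
  Tn <- d[2L]; N <- d[3L]
  g <- lapply(p, function(w) array(0, dim = dim(w)))
  dx <- array(0, dim = d)
  H <- nrow(p$Wr)
  dh <- matrix(0, nrow = H, ncol = N)
  for (k in rev(seq_len(Tn))) {
    st <- cache$steps[[k]]
    t <- st$t
    dh <- dh + matrix(dh_out[, t, ], nrow = H)
    dz <- dh * (st$cc - st$h_prev)
    dcc <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    dac <- dcc * (1 - st$cc^2)
    rh <- st$r * st$h_prev
    g$Wc <- g$Wc + dac %*% t(st$xt)
    g$Uc <- g$Uc + dac %*% t(rh)
    drh <- crossprod(p$Uc, dac)
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dar <- dr * st$r * (1 - st$r)
    daz <- dz * st$z * (1 - st$z)
    g$Wr <- g$Wr + dar %*% t(st$xt)
    g$Ur <- g$Ur + dar %*% t(st$h_prev)
    g$Wz <- g$Wz + daz %*% t(st$xt)
    g$Uz <- g$Uz + daz %*% t(st$h_prev)
    dh_prev <- dh_prev + crossprod(p$Ur, dar) + crossprod(p$Uz, daz)
    dx[, t, ] <- crossprod(p$Wr, dar) + crossprod(p$Wz, daz) +
      crossprod(p$Wc, dac)
    dh <- dh_prev
  }
  list(dx = dx, grads = g)
}

# Bidirectional GRU: per-position elementwise SUM of the two directions.
bigru_forward <- function(x, pf, pb) {
  abort_if(dim(x)[2L] < 1L, "empty time axis for the GRU")
  fwd <- gru_direction_forward(x, pf, reverse = FALSE)
  bwd <- gru_direction_forward(x, pb, reverse = TRUE)
  list(h = fwd$h + bwd$h, cache = list(fwd = fwd$cache, bwd = bwd$cache))
}

bigru_backward <- function(dh, pf, pb, cache) {
  bf <- gru_direction_backward(dh, pf, cache$fwd)
  bb <- gru_direction_backward(dh, pb, cache$bwd)
  list(dx = bf$dx + bb$dx, gf = bf$grads, gb = bb$grads)
}

# ---- Global average pooling over positions ----

global_average_context <- function(h) {
  d <- dim(h)
  colSums(aperm(h, c(2L, 1L, 3L))) / d[2L]
}

# Broadcast-add a (H x N) context matrix to every position of an (H, T, N)
# map; backward folds the broadcast back as a mean.
context_add_forward <- function(h) {
  d <- dim(h)
  ctx <- global_average_context(h)
  y <- h + aperm(array(ctx, dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
  list(y = y, ctx = ctx)
}

context_add_backward <- function(dy) {
  d <- dim(dy)
  s <- colSums(aperm(dy, c(2L, 1L, 3L))) / d[2L]
  dy + aperm(array(s, dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
}
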