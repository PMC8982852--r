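# The symmetric encoder-decoder signal-regression network.
#
# Encoder: three (conv -> ReLU -> maxpool -> dropout) blocks, a
# bidirectional GRU over the bottleneck, and a global-average-pooled context
# vector broadcast-added back onto the bottleneck map.
# Decoder: four stages of (bilinear upsample -> add skip -> BN -> ReLU ->
# conv), with skip lines from encoder levels 3, 2, 1 and a final 1-channel
# linear head. Output length equals input length for any length divisible
# by prod(pool_sizes).

#' Architecture hyperparameters
#'
#' The defaults are a desk-scale profile (conv 32/48/64, GRU 64) sized for
#' single-CPU training on a few thousand windows, where it generalizes
#' better than the GPU-scale profile (conv 64/96/128, GRU 128,
#' `blend_channels = c(96, 64, 32, 1)`) and trains twice as fast; pass the
#' larger channel counts explicitly to reproduce the full-scale network.
#'
#' @param conv_channels Output channels of the three encoder convolutions.
#' @param kernel_sizes Odd kernel widths of the three encoder convolutions.
#' @param pool_sizes Max-pool widths; their product is the input-length
#'   multiple (default `5*5*5 = 125`, so 1000-bp windows reach a
#'   bottleneck of 8 positions).
#' @param dropout_rate Encoder dropout rate (0.2 or 0.5 in the stated grid).
#' @param gru_hidden GRU hidden size; must equal `conv_channels[3]` so the
#'   level-3 skip can be added to the bottleneck map.
#' @param blend_channels Output channels of the four decoder blending
#'   convolutions. The first two are forced to `conv_channels[2]` and
#'   `conv_channels[1]` (skip-addition channel match) and the last must
#'   be 1.
#' @param blend_kernel Kernel width of the decoder blending convolutions.
#' @param bn_momentum,bn_eps Batch-normalization running-statistics momentum
#'   and variance floor.
#' @return An object of class `model_config`.
#' @export
model_config <- function(conv_channels = c(32L, 48L, 64L),
                         kernel_sizes = c(15L, 5L, 3L),
                         pool_sizes = c(5L, 5L, 5L),
                         dropout_rate = 0.2,
                         gru_hidden = conv_channels[3L],
                         blend_channels = c(conv_channels[2L],
                                            conv_channels[1L],
                                            max(conv_channels[1L] %/% 2L, 1L),
                                            1L),
                         blend_kernel = 3L,
                         bn_momentum = 0.1,
                         bn_eps = 1e-5) {
  conv_channels <- as.integer(conv_channels)
  kernel_sizes <- as.integer(kernel_sizes)
  pool_sizes <- as.integer(pool_sizes)
  abort_if(length(conv_channels) != 3L || length(kernel_sizes) != 3L ||
             length(pool_sizes) != 3L,
           "need exactly 3 encoder conv/kernel/pool entries")
  abort_if(any(kernel_sizes %% 2L == 0L) || blend_kernel %% 2L == 0L,
           "kernel sizes must be odd (same-length padding)")
  abort_if(gru_hidden != conv_channels[3L],
           "gru_hidden must equal conv_channels[3] (level-3 skip addition)")
  abort_if(length(blend_channels) != 4L || blend_channels[4L] != 1L,
           "blend_channels must have 4 entries ending in 1")
  abort_if(blend_channels[1L] != conv_channels[2L] ||
             blend_channels[2L] != conv_channels[1L],
           "blend_channels[1:2] must match conv_channels[2:1] (skip addition)")
  structure(
    list(conv_channels = conv_channels, kernel_sizes = kernel_sizes,
         pool_sizes = pool_sizes,
         input_len_multiple = as.integer(prod(pool_sizes)),
         dropout_rate = dropout_rate,
         gru_hidden = as.integer(gru_hidden),
         blend_channels = as.integer(blend_channels),
         blend_kernel = as.integer(blend_kernel),
         bn_momentum = bn_momentum, bn_eps = bn_eps),
    class = "model_config"
  )
}

glorot_uniform <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

#' Initialize an untrained model
#'
#' Weights use Glorot (uniform) initialization; biases start at zero, batch
#' norm at identity.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `binding_model` with fields `config`, `params`
#'   (flat named list of weight arrays), `state` (batch-norm running
#'   statistics) and `meta`.
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    params <- list()
    in_ch <- 4L
    for (i in 1:3) {
      k <- config$kernel_sizes[i]
      out_ch <- config$conv_channels[i]
      params[[sprintf("enc%d.W", i)]] <-
        glorot_uniform(out_ch, in_ch * k, in_ch * k, out_ch)
      params[[sprintf("enc%d.b", i)]] <- numeric(out_ch)
      in_ch <- out_ch
    }
    H <- config$gru_hidden
    C <- config$conv_channels[3L]
    for (dir in c("f", "b")) {
      for (m in c("Wr", "Wz", "Wc")) {
        params[[sprintf("gru.%s.%s", dir, m)]] <-
          glorot_uniform(H, C, C, H)
      }
      for (m in c("Ur", "Uz", "Uc")) {
        params[[sprintf("gru.%s.%s", dir, m)]] <-
          glorot_uniform(H, H, H, H)
      }
    }
    in_ch <- H
    kb <- config$blend_kernel
    state <- list()
    for (i in 1:4) {
      out_ch <- config$blend_channels[i]
      params[[sprintf("dec%d.W", i)]] <-
        glorot_uniform(out_ch, in_ch * kb, in_ch * kb, out_ch)
      params[[sprintf("dec%d.b", i)]] <- numeric(out_ch)
      params[[sprintf("dec%d.gamma", i)]] <- rep(1, in_ch)
      params[[sprintf("dec%d.beta", i)]] <- numeric(in_ch)
      state[[sprintf("dec%d.mean", i)]] <- numeric(in_ch)
      state[[sprintf("dec%d.var", i)]] <- rep(1, in_ch)
      in_ch <- out_ch
    }
    structure(
      list(config = config, params = params, state = state,
           meta = list(schema_version = 1L, init_seed = as.integer(seed),
                       trained = FALSE)),
      class = "binding_model"
    )
  })
}

#' @export
print.binding_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<binding_model> conv %s | GRU %d | blend %s | %s | %d parameters\n",
    paste(x$config$conv_channels, collapse = "/"), x$config$gru_hidden,
    paste(x$config$blend_channels, collapse = "/"),
    if (isTRUE(x$meta$trained)) "trained" else "untrained", np
  ))
  invisible(x)
}

# Parameter names carrying the L2 (Eq-style) penalty: all conv and GRU
# weight matrices; biases and batch-norm affine terms are exempt.
weight_param_names <- function(params) {
  nm <- names(params)
  nm[grepl("\\.W$|gru\\.[fb]\\.(W|U)[rzc]$", nm)]
}

#' Sum of squared weights of a model
#'
#' The `||w||^2` term entering the penalized training loss.
#' @param model A `binding_model`.
#' @return A non-negative scalar.
#' @export
weights_norm_sq <- function(model) {
  sum(vapply(weight_param_names(model$params),
             function(nm) sum(model$params[[nm]]^2), numeric(1)))
}

# Full forward pass over a batch.
# x: array (4, L, N); returns pred (L x N) and, when keep_cache, everything
# the backward pass needs. Batch-norm running stats are updated in the
# returned `state` when training.
forward_batch <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  L <- dim(x)[2L]
  abort_if(L %% cfg$input_len_multiple != 0L, sprintf(
    "input length %d not divisible by %d", L, cfg$input_len_multiple
  ))
  cache <- if (keep_cache) list() else NULL
  h <- x
  skips <- vector("list", 3L)
  for (i in 1:3) {
    # block = conv -> ReLU (fused) -> maxpool -> dropout
    cy <- conv_forward(h, p[[sprintf("enc%d.W", i)]],
                       p[[sprintf("enc%d.b", i)]], cfg$kernel_sizes[i],
                       relu_out = TRUE)
    mp <- maxpool_forward(cy, cfg$pool_sizes[i])
    dp <- dropout_forward(mp$y, cfg$dropout_rate, training)
    if (keep_cache) {
      cache[[sprintf("enc%d", i)]] <-
        list(x_in = h, y_conv = cy, pool = mp$cache, drop = dp$cache)
    }
    h <- dp$y
    skips[[i]] <- h
  }
  gru <- bigru_forward(h, gru_dir_params(p, "f"), gru_dir_params(p, "b"))
  ctx <- context_add_forward(gru$h)
  z <- ctx$y
  if (keep_cache) cache$gru <- gru$cache
  scales <- c(1L, cfg$pool_sizes[3L], cfg$pool_sizes[2L], cfg$pool_sizes[1L])
  skip_of_stage <- list(skips[[3L]], skips[[2L]], skips[[1L]], NULL)
  for (i in 1:4) {
    # stage = bilinear upsample -> add skip -> BN -> ReLU -> conv (fused)
    up <- bilinear_forward(z, scales[i])
    z <- up$y
    if (!is.null(skip_of_stage[[i]])) z <- z + skip_of_stage[[i]]
    bn <- batchnorm_forward(z, p[[sprintf("dec%d.gamma", i)]],
                            p[[sprintf("dec%d.beta", i)]],
                            st[[sprintf("dec%d.mean", i)]],
                            st[[sprintf("dec%d.var", i)]],
                            training, cfg$bn_momentum, cfg$bn_eps)
    st[[sprintf("dec%d.mean", i)]] <- bn$run_mean
    st[[sprintf("dec%d.var", i)]] <- bn$run_var
    cy <- conv_forward(bn$y, p[[sprintf("dec%d.W", i)]],
                       p[[sprintf("dec%d.b", i)]], cfg$blend_kernel,
                       relu_in = TRUE)
    if (keep_cache) {
      cache[[sprintf("dec%d", i)]] <-
        list(up = up$cache, bn = bn$cache, a = bn$y,
             scale = scales[i], has_skip = !is.null(skip_of_stage[[i]]))
    }
    z <- cy
  }
  pred <- z
  dim(pred) <- c(L, dim(x)[3L])
  list(pred = pred, cache = cache, state = st)
}

gru_dir_params <- function(p, dir) {
  list(Wr = p[[sprintf("gru.%s.Wr", dir)]],
       Wz = p[[sprintf("gru.%s.Wz", dir)]],
       Wc = p[[sprintf("gru.%s.Wc", dir)]],
       Ur = p[[sprintf("gru.%s.Ur", dir)]],
       Uz = p[[sprintf("gru.%s.Uz", dir)]],
       Uc = p[[sprintf("gru.%s.Uc", dir)]])
}

# Backward pass matching forward_batch(keep_cache = TRUE).
# dpred: (L x N) gradient of the loss w.r.t. predictions.
# Returns a flat named list of gradients aligned with model$params.
backward_batch <- function(model, cache, dpred) {
  cfg <- model$config
  p <- model$params
  g <- list()
  dz <- dpred
  dim(dz) <- c(1L, dim(dpred))
  dskip <- vector("list", 3L)
  skip_src <- c(3L, 2L, 1L, NA)
  for (i in 4:1) {
    cc <- cache[[sprintf("dec%d", i)]]
    cb <- conv_backward(dz, cc$a, cc$a, p[[sprintf("dec%d.W", i)]],
                        cfg$blend_kernel, relu_in = TRUE)
    g[[sprintf("dec%d.W", i)]] <- cb$dW
    g[[sprintf("dec%d.b", i)]] <- cb$db
    bb <- batchnorm_backward(cb$dx, cc$bn)
    g[[sprintf("dec%d.gamma", i)]] <- bb$dgamma
    g[[sprintf("dec%d.beta", i)]] <- bb$dbeta
    dz <- bb$dx
    if (cc$has_skip) dskip[[skip_src[i]]] <- dz
    dz <- bilinear_backward(dz, cc$scale, cc$up)
  }
  dz <- context_add_backward(dz)
  gb <- bigru_backward(dz, gru_dir_params(p, "f"), gru_dir_params(p, "b"),
                       cache$gru)
  for (m in names(gb$gf)) g[[sprintf("gru.f.%s", m)]] <- gb$gf[[m]]
  for (m in names(gb$gb)) g[[sprintf("gru.b.%s", m)]] <- gb$gb[[m]]
  dh <- gb$dx
  for (i in 3:1) {
    if (!is.null(dskip[[i]])) dh <- dh + dskip[[i]]
    cc <- cache[[sprintf("enc%d", i)]]
    dh <- dropout_backward(dh, cc$drop)
    dh <- maxpool_backward(dh, cc$pool)
    cb <- conv_backward(dh, cc$x_in, cc$y_conv, p[[sprintf("enc%d.W", i)]],
                        cfg$kernel_sizes[i], relu_out = TRUE,
                        need_dx = i > 1L)
    g[[sprintf("enc%d.W", i)]] <- cb$dW
    g[[sprintf("enc%d.b", i)]] <- cb$db
    dh <- cb$dx
  }
  g
}

#' Forward pass on a single one-hot sequence
#'
#' @param x An `L x 4` one-hot matrix (from [one_hot_encode()]); `L` must be
#'   divisible by `config$input_len_multiple` (use [predict_signal()] for
#'   automatic padding).
#' @param model A `binding_model`.
#' @param training Logical; `TRUE` activates dropout and batch statistics
#'   (inference is deterministic).
#' @return Numeric vector of length `L`: the predicted per-base signal.
#' @export
model_forward <- function(x, model, training = FALSE) {
  stopifnot(inherits(model, "binding_model"), is.matrix(x), ncol(x) == 4L)
  xb <- array(t(x), dim = c(4L, nrow(x), 1L))
  as.numeric(forward_batch(model, xb, training = training)$pred)
}

# Chunked inference over an (4, L, N) array; returns (L x N).
predict_batch <- function(model, x, chunk = 200L) {
  N <- dim(x)[3L]
  out <- matrix(0, nrow = dim(x)[2L], ncol = N)
  i <- 1L
  while (i <= N) {
    j <- min(i + chunk - 1L, N)
    out[, i:j] <- forward_batch(
      model, x[, , i:j, drop = FALSE], training = FALSE
    )$pred
    i <- j + 1L
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding config, parameters, batch
#' norm state and training metadata under a versioned schema.
#'
#' @param model A `binding_model`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `binding_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "binding_model"))
  saveRDS(unclass(model), path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  abort_if(is.null(obj$meta$schema_version) || obj$meta$schema_version != 1L,
           "unsupported checkpoint schema")
  obj$config <- structure(obj$config, class = "model_config")
  structure(obj, class = "binding_model")
}
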