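# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and textbook formulas only.

# Same-padding 1-D convolution, single sample. x: C x L; W: Co x (C*k) with
# kernel-offset-major row blocks; returns Co x L.
oracle_conv1d <- function(x, W, b, k) {
  C <- nrow(x); L <- ncol(x); Co <- nrow(W)
  p <- (k - 1) %/% 2
  y <- matrix(0, Co, L)
  for (t in seq_len(L)) {
    for (co in seq_len(Co)) {
      acc <- b[co]
      for (j in seq_len(k)) {
        src <- t + j - 1 - p
        if (src >= 1 && src <= L) {
          for (c in seq_len(C)) {
            acc <- acc + W[co, (j - 1) * C + c] * x[c, src]
          }
        }
      }
      y[co, t] <- acc
    }
  }
  y
}

# GRU recurrence, single sample, step-by-step. x: C x T. Returns H x T.
oracle_gru <- function(x, p, reverse = FALSE) {
  Tn <- ncol(x); H <- nrow(p$Wr)
  sig <- function(v) 1 / (1 + exp(-v))
  h <- rep(0, H)
  out <- matrix(0, H, Tn)
  ts <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  for (t in ts) {
    xt <- x[, t]
    r <- sig(as.vector(p$Wr %*% xt) + as.vector(p$Ur %*% h))
    z <- sig(as.vector(p$Wz %*% xt) + as.vector(p$Uz %*% h))
    cc <- tanh(as.vector(p$Wc %*% xt) + as.vector(p$Uc %*% (r * h)))
    h <- (1 - z) * h + z * cc
    out[, t] <- h
  }
  out
}

# Bilinear upsampling of a single channel (align_corners = FALSE).
oracle_bilinear <- function(v, s) {
  t_in <- length(v)
  sapply(seq_len(t_in * s) - 1, function(i) {
    src <- (i + 0.5) / s - 0.5
    src <- min(max(src, 0), t_in - 1)
    lo <- floor(src)
    hi <- min(lo + 1, t_in - 1)
    w <- src - lo
    (1 - w) * v[lo + 1] + w * v[hi + 1]
  })
}

oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# AUC by exhaustive pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Average precision by threshold enumeration over distinct scores.
oracle_prauc <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  recall_prev <- 0
  for (t in th) {
    sel <- scores >= t
    precision <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  ap
}

# Any-overlap read counting by double loop.
oracle_openness <- function(peak, reads) {
  n <- 0
  for (r in reads) {
    if (r$chrom == peak$chrom) {
      if (max(r$start, peak$start) < min(r$end, peak$end)) n <- n + 1
    }
  }
  log10(1 + n)
}
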