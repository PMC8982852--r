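# Evaluation metrics: MSE, Pearson r, AUROC, AUPRC.

#' Mean squared error
#'
#' @param pred,target Equal-length numeric vectors (or arrays).
#' @return Mean of squared differences.
#' @export
mse_metric <- function(pred, target) {
  abort_if(length(pred) != length(target) || length(pred) == 0L,
           "pred and target lengths differ or are empty")
  mean((as.numeric(pred) - as.numeric(target))^2)
}

#' Sample Pearson correlation
#'
#' @param a,b Equal-length numeric vectors of length >= 2.
#' @return Correlation in `[-1, 1]`; `NA` with a warning when either input
#'   is constant (undefined).
#' @export
pearsonr <- function(a, b) {
  abort_if(length(a) != length(b) || length(a) < 2L,
           "need two equal-length vectors of length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("Pearson correlation undefined for constant input",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney statistic via midranks:
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, which handles ties exactly.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  abort_if(length(scores) != length(labels), "scores/labels length mismatch")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  abort_if(n_pos == 0L || n_neg == 0L, "both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over score thresholds, with tied scores
#' grouped (all items sharing a score enter together).
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1) with at least one positive.
#' @return AUPRC in `(0, 1]`.
#' @export
prauc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  abort_if(length(scores) != length(labels), "scores/labels length mismatch")
  n_pos <- sum(labels == 1L)
  abort_if(n_pos == 0L, "need at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  groups <- cumsum(!duplicated(s))
  tp_g <- tapply(l, groups, sum)
  n_g <- tapply(rep(1L, length(l)), groups, sum)
  tp <- cumsum(tp_g)
  tot <- cumsum(n_g)
  precision <- tp / tot
  dtp <- diff(c(0, tp))
  sum(precision * dtp) / n_pos
}

#' Full metric report
#'
#' Regression metrics (MSE, Pearson r) over flattened per-base predictions
#' and classification metrics (AUROC, AUPRC) over per-sequence scores.
#'
#' @param pred,target Per-base predicted and true signal (vectors or
#'   matrices of equal shape).
#' @param scores Per-sequence classification scores.
#' @param labels Per-sequence binary labels.
#' @return An object of class `metric_report`: list with `mse`, `pearsonr`,
#'   `auc`, `prauc`, `n`.
#' @export
metric_report <- function(pred, target, scores, labels) {
  structure(
    list(mse = mse_metric(pred, target),
         pearsonr = pearsonr(as.numeric(pred), as.numeric(target)),
         auc = auc_score(scores, labels),
         prauc = prauc_score(scores, labels),
         n = length(labels)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n=%d  MSE %.5f  Pearson r %.4f  AUC %.4f  PRAUC %.4f\n",
    x$n, x$mse, x$pearsonr, x$auc, x$prauc
  ))
  invisible(x)
}
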