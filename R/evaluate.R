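# Model evaluation: classification at a favorability threshold,
# rank-based AUC, Hosmer-Lemeshow calibration.

#' Classification metrics at a favorability threshold
#'
#' Cells with `F >= threshold` are predicted present.  Besides the usual
#' CCR/sensitivity/specificity and Cohen's kappa, reports the
#' under-prediction rate UPR = FN / (TP + FN), the share of presences the
#' model misses, and the over-prediction rate OPR = FP / (TP + FP), the
#' share of predicted presences lacking a record.  With no predicted
#' presences OPR is undefined and reported as `NA`, not 0.
#'
#' @param f favorability (or any score) per cell.
#' @param presence 0/1 observed presence per cell.
#' @param threshold classification threshold on `f` (default 0.5, the
#'   prevalence anchor of the favorability scale).
#' @return list with the 2x2 counts (`tp`, `tn`, `fp`, `fn`) and `ccr`,
#'   `sensitivity`, `specificity`, `upr`, `opr`, `kappa`, `threshold`.
#' @export
#' @examples
#' confusion_metrics(c(0.9, 0.9, 0.1, 0.2), c(1, 1, 0, 0))$ccr  # 1
confusion_metrics <- function(f, presence, threshold = 0.5) {
  stopifnot(length(f) == length(presence))
  ok <- !is.na(f) & !is.na(presence)
  f <- f[ok]; y <- as.integer(presence[ok])
  if (!any(y == 1) || !any(y == 0))
    stop("both classes must be present")
  pred <- as.integer(f >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       ccr = po,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       upr = fn / (tp + fn),
       opr = if (tp + fp == 0) NA_real_ else fp / (tp + fp),
       kappa = if (pe == 1) 0 else (po - pe) / (1 - pe),
       threshold = threshold)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' The probability that a randomly chosen presence cell outscores a
#' randomly chosen absence cell, ties counting one half — computed from
#' midranks, so it is exact and invariant to any strictly monotone
#' transform of the scores (in particular probability vs favorability).
#'
#' @param scores per-cell scores (favorability or probability).
#' @param presence 0/1 observed presence.
#' @return the AUC in \[0, 1\].
#' @export
#' @examples
#' auc_rank(c(0.9, 0.4, 0.5, 0.3), c(1, 1, 0, 0))  # 0.75
auc_rank <- function(scores, presence) {
  ok <- !is.na(scores) & !is.na(presence)
  s <- scores[ok]; y <- as.integer(presence[ok])
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow calibration test
#'
#' Cells are sorted by predicted probability (ties broken by cell index)
#' and split into `n_bins` equal-count bins.  Per bin with `m` cells,
#' `O` observed presences and `E = sum(P)` expected,
#' `HL = sum (O - E)^2 / (E (1 - E/m))`, referred to a chi-square with
#' `n_bins - 2` degrees of freedom.  A bin with `E = 0` or `E = m` would
#' have an empty denominator; its expectation is then pulled in by 0.5
#' (continuity correction) and the result flagged.
#'
#' @param p predicted occurrence probabilities.
#' @param presence 0/1 observed presence.
#' @param n_bins number of equal-count bins (>= 2; default 10).
#' @return list: `statistic`, `p_value`, `df`, per-bin `table`, and
#'   `continuity_corrected`.
#' @export
hosmer_lemeshow <- function(p, presence, n_bins = 10L) {
  stopifnot(length(p) == length(presence))
  if (!is_count(n_bins, min = 2)) stop("n_bins must be >= 2")
  ok <- !is.na(p) & !is.na(presence)
  p <- p[ok]; y <- as.integer(presence[ok])
  n <- length(p)
  if (n < n_bins) stop("fewer cells than bins")
  ord <- order(p, seq_along(p))
  bin <- ceiling(seq_len(n) * n_bins / n)   # equal-count, deterministic
  O <- tapply(y[ord], bin, sum)
  E <- tapply(p[ord], bin, sum)
  m <- tapply(rep(1, n), bin, sum)
  corrected <- E <= 0 | E >= m
  E_adj <- E
  E_adj[corrected] <- pmin(pmax(E[corrected], 0.5), m[corrected] - 0.5)
  stat <- sum((O - E_adj)^2 / (E_adj * (1 - E_adj / m)))
  df <- n_bins - 2
  list(statistic = unname(stat),
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df,
       table = data.frame(bin = as.integer(names(O)), size = as.vector(m),
                          observed = as.vector(O), expected = as.vector(E),
                          row.names = NULL),
       continuity_corrected = any(corrected))
}

auc_class <- function(auc) {
  if (auc >= 0.9) "outstanding"
  else if (auc >= 0.8) "excellent"
  else if (auc >= 0.7) "acceptable"
  else "poor"
}

#' Evaluate a fitted favorability model
#'
#' Classification (at favorability `threshold`), discrimination (rank AUC,
#' with the conventional quality label: outstanding >= 0.9, excellent
#' 0.8-0.9, acceptable 0.7-0.8) and calibration (Hosmer-Lemeshow on the
#' probability scale; `hl_p >= 0.05` is reported as well-calibrated).
#' Evaluation is on the training cells, as is standard for descriptive
#' atlas models.
#'
#' @param model a `favorability_model` from [favorability_fit()].
#' @param threshold favorability classification threshold (default 0.5).
#' @param n_bins Hosmer-Lemeshow bin count.
#' @return an `evaluation_metrics` list: the [confusion_metrics()] fields,
#'   `auc`, `auc_class`, `hl_statistic`, `hl_p`, `well_calibrated`.
#' @export
evaluate_model <- function(model, threshold = 0.5, n_bins = 10L) {
  stopifnot(inherits(model, "favorability_model"))
  f <- model$favorability
  p <- model$fitted_probability
  if (is.null(f) || is.null(p))
    stop("model has no fitted surfaces; fit it with favorability_fit()")
  cm <- confusion_metrics(f, model$presence, threshold = threshold)
  auc <- auc_rank(f, model$presence)
  hl <- hosmer_lemeshow(p, model$presence, n_bins = n_bins)
  out <- c(cm, list(auc = auc, auc_class = auc_class(auc),
                    hl_statistic = hl$statistic, hl_p = hl$p_value,
                    well_calibrated = hl$p_value >= 0.05,
                    hl_continuity_corrected = hl$continuity_corrected))
  class(out) <- "evaluation_metrics"
  out
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf(
    "classification @ F >= %.2f: CCR %.3f, sens %.3f, spec %.3f, UPR %.3f, OPR %s, kappa %.3f\n",
    x$threshold, x$ccr, x$sensitivity, x$specificity, x$upr,
    ifelse(is.na(x$opr), "NA", sprintf("%.3f", x$opr)), x$kappa))
  cat(sprintf("discrimination: AUC %.3f (%s)\n", x$auc, x$auc_class))
  cat(sprintf("calibration: HL %.2f, p %.3f (%s)\n", x$hl_statistic,
              x$hl_p,
              if (x$well_calibrated) "well-calibrated" else "miscalibrated"))
  invisible(x)
}
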