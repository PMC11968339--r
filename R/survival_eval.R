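# Evaluation suite: confusion-matrix scores, ROC/AUC, Kaplan-Meier curves
# and the two-group log-rank test. K-M and log-rank are delegated to the
# survival package; the confusion metrics and the ROC sweep are computed
# directly from their definitions.

#' Confusion-matrix metrics
#'
#' Counts and derived proportions for binary predictions. Ratios with a zero
#' denominator are reported as `NaN` and listed in the `undefined` field.
#'
#' @param pred,truth integer vectors in {0, 1}, equal length.
#' @return object of class `MetricsReport`: list with `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `precision`, `specificity`, `recall`, `f1`, `undefined`.
#' @export
confusionMetrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  stopifnot(all(pred %in% 0:1), all(truth %in% 0:1))
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  prec <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(pred),
    precision = prec,
    specificity = ratio(tn, tn + fp),
    recall = rec,
    f1 = if (is.nan(prec) || is.nan(rec) || prec + rec == 0) NaN
         else 2 * prec * rec / (prec + rec))
  out$undefined <- names(Filter(function(v) length(v) == 1 && is.nan(v),
                                out[c("precision", "specificity", "recall", "f1")]))
  class(out) <- "MetricsReport"
  out
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.3f  precision %.3f  specificity %.3f  recall %.3f  F1 %.3f\n",
              x$accuracy, x$precision, x$specificity, x$recall, x$f1))
  if (length(x$undefined))
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (positive class = label 1, scores
#' are class-1 probabilities); AUC by the trapezoid rule, which equals the
#' normalized Mann-Whitney U statistic.
#'
#' @param scores numeric vector of class-1 scores.
#' @param truth integer vector in {0, 1}.
#' @return list with `roc` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
rocAuc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  if (length(unique(truth)) < 2L)
    stop("both classes must be present to compute a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(truth == 1); Ng <- sum(truth == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0) / Ng, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative times (months).
#' @param events 1 = death observed, 0 = censored.
#' @return object of class `KMCurve`: list with `time` (ascending distinct
#'   event times), `surv` (non-increasing step values), `at_risk`, `n_event`,
#'   plus the full `fit` table including censoring times.
#' @export
kmEstimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0))
  if (length(times) == 0L) stop("empty input")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  step <- fit$n.event > 0
  out <- list(time = fit$time[step], surv = fit$surv[step],
              at_risk = fit$n.risk[step], n_event = fit$n.event[step],
              fit = data.frame(time = fit$time, at_risk = fit$n.risk,
                               n_event = fit$n.event, surv = fit$surv))
  class(out) <- "KMCurve"
  out
}

#' @export
print.KMCurve <- function(x, ...) {
  cat(sprintf("KMCurve: %d event time(s); S ranges %.3f..%.3f\n",
              length(x$time),
              if (length(x$surv)) max(x$surv) else 1,
              if (length(x$surv)) min(x$surv) else 1))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square with hypergeometric variance
#' at each distinct event time, df = 1. Symmetric in group order. With no
#' events at all the result is flagged degenerate (`NA` statistic).
#'
#' @param timesA,eventsA,timesB,eventsB the two groups' survival data.
#' @return object of class `LogRankResult`: list with `chi_square`,
#'   `p_value`, `df`, `degenerate`.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  stopifnot(length(timesA) > 0, length(timesB) > 0)
  if (sum(eventsA) + sum(eventsB) == 0) {
    out <- list(chi_square = NA_real_, p_value = NA_real_, df = 1L,
                degenerate = TRUE)
    class(out) <- "LogRankResult"
    return(out)
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- rep(c(0L, 1L), c(length(timesA), length(timesB)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi <- unname(sd_$chisq)
  out <- list(chi_square = chi,
              p_value = pchisq(chi, df = 1, lower.tail = FALSE),
              df = 1L, degenerate = FALSE)
  class(out) <- "LogRankResult"
  out
}

#' @export
print.LogRankResult <- function(x, ...) {
  if (x$degenerate) cat("LogRankResult: degenerate (no events)\n")
  else cat(sprintf("LogRankResult: chi-square %.3f (df=1), p = %.4g\n",
                   x$chi_square, x$p_value))
  invisible(x)
}

#' Plot Kaplan-Meier curves for predicted risk groups
#'
#' Step curves for one or more [kmEstimate()] results on a base-graphics
#' device (wrap in `pdf()`/`png()` to export).
#'
#' @param curves named list of `KMCurve` objects.
#' @param col line colours, recycled.
#' @param xlab,ylab,main usual graphical annotations.
#' @export
plotKm <- function(curves, col = seq_along(curves), xlab = "Months",
                   ylab = "Survival probability", main = "Kaplan-Meier") {
  if (inherits(curves, "KMCurve")) curves <- list(curves)
  xmax <- max(vapply(curves, function(k) max(k$fit$time, 1), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, main = main)
  col <- rep_len(col, length(curves))
  for (i in seq_along(curves)) {
    k <- curves[[i]]
    graphics::lines(stats::stepfun(k$fit$time, c(1, k$fit$surv)),
                    do.points = FALSE, col = col[i], lwd = 2)
  }
  if (!is.null(names(curves)))
    graphics::legend("bottomleft", legend = names(curves), col = col,
                     lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot a ROC curve
#'
#' @param roc a [rocAuc()] result.
#' @param main plot title (AUC is appended).
#' @export
plotRoc <- function(roc, main = "ROC") {
  graphics::plot(roc$roc$fpr, roc$roc$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s (AUC %.3f)", main, roc$auc),
                 xlim = c(0, 1), ylim = c(0, 1))
  graphics::abline(0, 1, lty = 3)
  invisible(NULL)
}
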