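#' ROC curve for a stay/leave predictor
#'
#' Builds the empirical ROC curve for predicting the *leave* decision
#' (the positive class) from a continuous predictor. Thresholds are
#' placed at the midpoints between adjacent distinct predictor values,
#' with infinite sentinels, so every achievable operating point appears.
#' Sensitivity is the proportion of leave decisions predicted correctly,
#' specificity the proportion of stay decisions predicted correctly.
#'
#' `polarity` states the direction of the leave prediction: `"below"`
#' predicts leave when the value is at or below the threshold (the
#' natural direction for organization composites and the RIAIR, which
#' drop before departure), `"above"` the opposite (mean ITD, PAO,
#' intersection rate rise as organization degrades), and `"auto"` picks
#' whichever direction yields AUC >= 0.5.
#'
#' The AUC equals the Mann-Whitney concordance probability (ties counted
#' half) and also the trapezoid area over the curve's own points.
#'
#' @param values Numeric predictor, one per decision.
#' @param labels `"stay"`/`"leave"` per decision (character or factor).
#' @param polarity `"below"`, `"above"`, or `"auto"`.
#' @param predictor Optional predictor name carried in the result.
#' @return A `roc_curve` object: `points` tibble
#'   (`threshold`, `sensitivity`, `specificity`), `polarity`, `auc`,
#'   `n_leave`, `n_stay`, and the input data (used by empirical curve
#'   combination).
#' @export
roc_curve <- function(values, labels, polarity = c("auto", "below", "above"),
                      predictor = NULL) {
  polarity <- match.arg(polarity)
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels)[keep]
  if (!all(labels %in% c("stay", "leave"))) {
    abort("labels must be 'stay' or 'leave'", class = "patchleave_domain_error")
  }
  is_leave <- labels == "leave"
  n_leave <- sum(is_leave)
  n_stay <- sum(!is_leave)
  if (n_leave == 0 || n_stay == 0) {
    abort("both decision classes must be present",
          class = "patchleave_domain_error")
  }
  if (length(unique(values)) == 1L) {
    warn("constant predictor: AUC is 0.5")
  }
  auc_above <- auc_mann_whitney(values, is_leave, direction = "above")
  if (polarity == "auto") {
    polarity <- if (auc_above >= 0.5) "above" else "below"
  }
  auc <- if (polarity == "above") auc_above else 1 - auc_above
  sv <- sort(unique(values))
  thr <- c(-Inf, (head(sv, -1) + tail(sv, -1)) / 2, Inf)
  leave_v <- values[is_leave]
  stay_v <- values[!is_leave]
  if (polarity == "below") {
    sens <- vapply(thr, function(h) mean(leave_v <= h), numeric(1))
    spec <- vapply(thr, function(h) mean(stay_v > h), numeric(1))
  } else {
    sens <- vapply(thr, function(h) mean(leave_v >= h), numeric(1))
    spec <- vapply(thr, function(h) mean(stay_v < h), numeric(1))
    ord <- rev(seq_along(thr))
    thr <- thr[ord]; sens <- sens[ord]; spec <- spec[ord]
  }
  structure(
    list(points = tibble::tibble(threshold = thr, sensitivity = sens,
                                 specificity = spec),
         polarity = polarity, auc = auc, n_leave = n_leave, n_stay = n_stay,
         predictor = predictor %||% "predictor",
         values = values, labels = labels),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", x$predictor, ": AUC = ", format(x$auc, digits = 4),
      " (leave ", if (x$polarity == "below") "below" else "above",
      " threshold; ", x$n_leave, " leave / ", x$n_stay, " stay)\n", sep = "")
  invisible(x)
}

#' Mann-Whitney concordance AUC
#'
#' Probability that a randomly drawn leave value exceeds (direction
#' `"above"`) a randomly drawn stay value, counting ties as one half.
#' Computed from midranks, which is exact.
#'
#' @param values Numeric predictor.
#' @param is_leave Logical, `TRUE` for leave decisions.
#' @param direction `"above"` or `"below"` (leave values expected larger
#'   or smaller).
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(values, is_leave, direction = "above") {
  nl <- sum(is_leave)
  ns <- sum(!is_leave)
  r <- rank(values)
  a <- (sum(r[is_leave]) - nl * (nl + 1) / 2) / (nl * ns)
  if (direction == "above") a else 1 - a
}

#' Youden-optimal operating point
#'
#' The point of a ROC curve maximizing Youden's
#' `J = sensitivity + specificity - 1` (the vertical distance from the
#' identity line). Ties are broken toward the more sensitive point, then
#' by curve order, which makes the choice stable under input reordering.
#'
#' @param curve A `roc_curve` (or any list with a `points` tibble).
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_optimal <- function(curve) {
  pts <- curve$points
  if (nrow(pts) == 0) {
    abort("empty ROC curve", class = "patchleave_domain_error")
  }
  j <- pts$sensitivity + pts$specificity - 1
  best <- order(-j, -pts$sensitivity)[1]
  tibble::tibble(threshold = pts$threshold[best],
                 sensitivity = pts$sensitivity[best],
                 specificity = pts$specificity[best],
                 youden_j = j[best])
}

#' Trapezoid AUC from operating points
#'
#' Plots the points in (1 - specificity, sensitivity) space, augments
#' them with the corners (0, 0) and (1, 1), sorts by false-positive rate,
#' and sums trapezoid areas.
#'
#' @param sensitivity,specificity Numeric vectors of equal length.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(sensitivity, specificity) {
  fpr <- c(0, 1 - specificity, 1)
  sens <- c(0, sensitivity, 1)
  ord <- order(fpr, sens)
  fpr <- fpr[ord]; sens <- sens[ord]
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

#' DeLong confidence interval for an empirical AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from placement values
#' (the DeLong estimator), with a normal-approximation interval truncated
#' to `[0, 1]`.
#'
#' @param values Numeric predictor.
#' @param labels `"stay"`/`"leave"` per decision.
#' @param direction `"above"` if leave values are expected larger.
#' @param level Confidence level (default 0.95).
#' @return List: `auc`, `se`, `ci` (length-2), `level`.
#' @export
delong_ci <- function(values, labels, direction = "above", level = 0.95) {
  is_leave <- as.character(labels) == "leave"
  x <- if (direction == "above") values else -values
  lx <- x[is_leave]
  sx <- x[!is_leave]
  m <- length(lx); n <- length(sx)
  if (m < 2 || n < 2) {
    abort("DeLong CI needs >= 2 decisions in each class",
          class = "patchleave_domain_error")
  }
  # placement of each leave value among stays and vice versa
  v10 <- vapply(lx, function(xi) mean((xi > sx) + 0.5 * (xi == sx)),
                numeric(1))
  v01 <- vapply(sx, function(yj) mean((lx > yj) + 0.5 * (lx == yj)),
                numeric(1))
  a <- mean(v10)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = a, se = se,
       ci = pmin(pmax(c(a - z * se, a + z * se), 0), 1), level = level)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Parametric standard error of an AUC from the class sizes alone:
#' `SE^2 = [A(1-A) + (nL-1)(Q1-A^2) + (nS-1)(Q2-A^2)] / (nL * nS)` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`. Used for combined ROC curves,
#' where no per-observation predictor exists.
#'
#' @param auc Area under the curve, in `(0, 1)` (degenerate 0/1 gives a
#'   zero-width interval with a warning).
#' @param n_leave,n_stay Class sizes (>= 1).
#' @param level Confidence level.
#' @return List: `auc`, `se`, `ci`, `level`.
#' @export
hanley_mcneil_ci <- function(auc, n_leave, n_stay, level = 0.95) {
  if (n_leave < 1 || n_stay < 1) {
    abort("class sizes must be >= 1", class = "patchleave_domain_error")
  }
  if (auc <= 0 || auc >= 1) {
    warn("AUC at 0 or 1: Hanley-McNeil SE is degenerate (0)")
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se2 <- (auc * (1 - auc) + (n_leave - 1) * (q1 - auc^2) +
            (n_stay - 1) * (q2 - auc^2)) / (n_leave * n_stay)
  se <- sqrt(max(se2, 0))
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc, se = se,
       ci = pmin(pmax(c(auc - z * se, auc + z * se), 0), 1), level = level)
}
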