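#' Combine two ROC curves into a compound leaving criterion
#'
#' Combines the curves of two predictors of the same decision set into a
#' single ROC curve by the maximum-likelihood rule. In `"independence"`
#' mode, every pair of operating points (one per curve) defines four
#' joint test outcomes whose class-conditional probabilities follow from
#' the two sensitivities and specificities under class-conditional
#' independence; sweeping the likelihood-ratio threshold over those
#' outcomes yields the achievable compound points, which are always of
#' the form single-predictor, AND, or OR rules. The combined curve is the
#' upper-left Pareto envelope of all achievable points. In `"empirical"`
#' mode, AND/OR rules are evaluated directly on the stored predictor
#' values over a threshold grid (no independence assumption) and the
#' envelope is taken the same way.
#'
#' The combined AUC uses the trapezoid rule over the envelope and its
#' confidence interval the Hanley-McNeil standard error, since compound
#' points have no per-observation predictor.
#'
#' @param curve_a,curve_b `roc_curve` objects built on the same decisions
#'   (identical label vectors).
#' @param mode `"independence"` or `"empirical"`.
#' @param grid_max Operating points are thinned to at most this many
#'   thresholds per curve before pairing (default 201), bounding the pair
#'   sweep; raise it for full resolution.
#' @param level Confidence level for the AUC interval.
#' @return A `combined_roc` object: envelope `points` tibble
#'   (`sensitivity`, `specificity`, `connective`, `thr_a`, `thr_b`,
#'   `dir_a`, `dir_b`), `auc`, `ci`, `n_leave`, `n_stay`, `mode`, and the
#'   two predictor names.
#' @export
combine_roc_ml <- function(curve_a, curve_b,
                           mode = c("independence", "empirical"),
                           grid_max = 201L, level = 0.95) {
  mode <- match.arg(mode)
  if (curve_a$n_leave != curve_b$n_leave ||
      curve_a$n_stay != curve_b$n_stay ||
      !identical(curve_a$labels, curve_b$labels)) {
    abort("curves must be built on the same decision set",
          class = "patchleave_domain_error")
  }
  dir_a <- if (curve_a$polarity == "below") "<" else ">"
  dir_b <- if (curve_b$polarity == "below") "<" else ">"
  pa <- .thin_points(curve_a$points, grid_max)
  pb <- .thin_points(curve_b$points, grid_max)

  if (mode == "independence") {
    g <- expand.grid(i = seq_len(nrow(pa)), j = seq_len(nrow(pb)))
    se1 <- pa$sensitivity[g$i]; sp1 <- pa$specificity[g$i]
    se2 <- pb$sensitivity[g$j]; sp2 <- pb$specificity[g$j]
    cand <- dplyr::bind_rows(
      tibble::tibble(sens = se1 * se2,
                     fpr = (1 - sp1) * (1 - sp2),
                     connective = "AND",
                     thr_a = pa$threshold[g$i], thr_b = pb$threshold[g$j]),
      tibble::tibble(sens = 1 - (1 - se1) * (1 - se2),
                     fpr = 1 - sp1 * sp2,
                     connective = "OR",
                     thr_a = pa$threshold[g$i], thr_b = pb$threshold[g$j])
    )
  } else {
    cand <- .empirical_pairs(curve_a, curve_b, pa, pb)
  }
  singles <- dplyr::bind_rows(
    tibble::tibble(sens = pa$sensitivity, fpr = 1 - pa$specificity,
                   connective = "A", thr_a = pa$threshold, thr_b = NA_real_),
    tibble::tibble(sens = pb$sensitivity, fpr = 1 - pb$specificity,
                   connective = "B", thr_a = NA_real_, thr_b = pb$threshold)
  )
  cand <- dplyr::bind_rows(cand, singles,
                           tibble::tibble(sens = c(0, 1), fpr = c(0, 1),
                                          connective = c("A", "A"),
                                          thr_a = c(-Inf, Inf) *
                                            (if (dir_a == "<") 1 else -1),
                                          thr_b = NA_real_))
  env <- .pareto_envelope(cand)
  # trapezoid rule over the staircase: explicit step corners make the
  # trapezoid sum equal the area of the achievable step function, with
  # no interpolation above points no rule can reach
  corners <- .with_step_corners(env$fpr, env$sens)
  auc <- auc_trapezoid(corners$sens, 1 - corners$fpr)
  ci <- hanley_mcneil_ci(auc, curve_a$n_leave, curve_a$n_stay, level = level)
  structure(
    list(points = tibble::tibble(
           threshold = NA_real_, sensitivity = env$sens,
           specificity = 1 - env$fpr, connective = env$connective,
           thr_a = env$thr_a, thr_b = env$thr_b,
           dir_a = dir_a, dir_b = dir_b),
         auc = auc, ci = ci$ci, se = ci$se, level = level,
         n_leave = curve_a$n_leave, n_stay = curve_a$n_stay, mode = mode,
         predictor_a = curve_a$predictor, predictor_b = curve_b$predictor),
    class = "combined_roc"
  )
}

#' @export
print.combined_roc <- function(x, ...) {
  cat("<combined_roc> ", x$predictor_a, " x ", x$predictor_b, " (", x$mode,
      "): AUC = ", format(x$auc, digits = 4), " [",
      format(x$ci[1], digits = 3), ", ", format(x$ci[2], digits = 3),
      "]\n", sep = "")
  invisible(x)
}

.thin_points <- function(points, grid_max) {
  if (nrow(points) <= grid_max) return(points)
  idx <- unique(round(seq(1, nrow(points), length.out = grid_max)))
  points[idx, , drop = FALSE]
}

.empirical_pairs <- function(curve_a, curve_b, pa, pb) {
  is_leave <- curve_a$labels == "leave"
  flag <- function(values, thr, polarity) {
    # decisions x thresholds indicator matrix for the leave prediction
    if (polarity == "below") {
      outer(values, thr, `<=`)
    } else {
      outer(values, thr, `>=`)
    }
  }
  fa <- flag(curve_a$values, pa$threshold, curve_a$polarity)
  fb <- flag(curve_b$values, pb$threshold, curve_b$polarity)
  nl <- sum(is_leave); ns <- sum(!is_leave)
  and_l <- crossprod(fa[is_leave, , drop = FALSE] + 0,
                     fb[is_leave, , drop = FALSE] + 0) / nl
  and_s <- crossprod(fa[!is_leave, , drop = FALSE] + 0,
                     fb[!is_leave, , drop = FALSE] + 0) / ns
  or_l <- 1 - crossprod(1 - (fa[is_leave, , drop = FALSE] + 0),
                        1 - (fb[is_leave, , drop = FALSE] + 0)) / nl
  or_s <- 1 - crossprod(1 - (fa[!is_leave, , drop = FALSE] + 0),
                        1 - (fb[!is_leave, , drop = FALSE] + 0)) / ns
  g <- expand.grid(i = seq_len(nrow(pa)), j = seq_len(nrow(pb)))
  dplyr::bind_rows(
    tibble::tibble(sens = and_l[cbind(g$i, g$j)],
                   fpr = and_s[cbind(g$i, g$j)], connective = "AND",
                   thr_a = pa$threshold[g$i], thr_b = pb$threshold[g$j]),
    tibble::tibble(sens = or_l[cbind(g$i, g$j)],
                   fpr = or_s[cbind(g$i, g$j)], connective = "OR",
                   thr_a = pa$threshold[g$i], thr_b = pb$threshold[g$j])
  )
}

# Upper-left Pareto envelope in (fpr, sens) space: at each distinct fpr
# only the most sensitive achievable point survives, and points weakly
# dominated by one at lower fpr are dropped.
.pareto_envelope <- function(cand) {
  cand <- cand[is.finite(cand$sens) & is.finite(cand$fpr), , drop = FALSE]
  cand <- cand[order(cand$fpr, -cand$sens), , drop = FALSE]
  cand <- cand[!duplicated(cand$fpr), , drop = FALSE]
  keep <- cand$sens > cummax(c(-Inf, head(cand$sens, -1))) - 1e-12
  cand[keep, , drop = FALSE]
}

# Insert the step corner (f_{k+1}, s_k) between consecutive envelope
# points so a trapezoid sum integrates the staircase exactly.
.with_step_corners <- function(fpr, sens) {
  ord <- order(fpr, sens)
  fpr <- fpr[ord]; sens <- sens[ord]
  m <- length(fpr)
  if (m < 2) return(list(fpr = fpr, sens = sens))
  list(fpr = c(rbind(fpr, c(fpr[-1], 1))),
       sens = c(rbind(sens, sens)))
}

#' Format a compound leaving rule
#'
#' Renders one envelope point of a [combine_roc_ml] curve as a rule
#' string such as `"composite < -0.1 OR riair < 0.5"`.
#'
#' @param combined A `combined_roc` object.
#' @param point One row of `combined$points` (e.g. the Youden-optimal
#'   row).
#' @return A character scalar.
#' @export
format_compound_rule <- function(combined, point) {
  a <- paste(combined$predictor_a, point$dir_a, signif(point$thr_a, 4))
  b <- paste(combined$predictor_b, point$dir_b, signif(point$thr_b, 4))
  switch(point$connective,
         AND = paste(a, "AND", b),
         OR = paste(a, "OR", b),
         A = a,
         B = b)
}
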