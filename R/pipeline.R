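default_polarity <- c(
  best_r = "below", mean_itd_px = "above", pao_pct = "above",
  intersection_rate = "above", composite_weighted = "below",
  composite_unweighted = "below", riair = "below"
)

#' Build the labeled decision table for an event log
#'
#' Joins, per trial, the stay/leave decision records with the
#' trial-so-far organization indicators and the RIAIR series, yielding
#' one row per decision (n >= `min_picks`) ready for standardization and
#' ROC analysis.
#'
#' @param log A validated `forage_log`.
#' @param min_picks First decision ordinal (default 3).
#' @param value_mode Passed to [riair_series].
#' @param method,exact_cap,per_target,anchor_first Passed to
#'   [indicator_series].
#' @return Tibble with trial keys, `n`, `label`, the four indicators,
#'   `flag_degenerate`, and `riair`.
#' @export
decision_table <- function(log, min_picks = 3L, value_mode = "items",
                           method = "auto", exact_cap = 13L,
                           per_target = FALSE, anchor_first = FALSE) {
  trials <- as_trials(log)
  keys <- c("participant_id", "condition", "trial_id", "age_group", "n")
  purrr::map_dfr(trials, function(tr) {
    dec <- extract_decisions(tr, min_picks = min_picks)
    if (nrow(dec) == 0) return(dec)
    ind <- indicator_series(tr, method = method, exact_cap = exact_cap,
                            per_target = per_target,
                            anchor_first = anchor_first)
    ri <- riair_series(tr, value_mode = value_mode)
    dec |>
      dplyr::left_join(ind, by = keys) |>
      dplyr::left_join(ri[, c(keys, "riair")], by = keys)
  })
}

#' Fit composites within one analysis stratum
#'
#' Standardizes the four indicators over all trial-so-far instances in
#' the stratum, runs Horn's parallel analysis and PCA on the end-of-trial
#' rows only (one independent observation per trial), and appends the
#' weighted and unweighted composite scores to every decision row.
#'
#' @param decisions A stratum's rows from [decision_table].
#' @param stratum Label for provenance.
#' @param reps,seed Passed to [parallel_analysis].
#' @return List: `decisions` (with `z_*`, `composite_weighted`,
#'   `composite_unweighted` columns), `stats`, `parallel`, `pca`,
#'   `weights`.
#' @export
fit_composites <- function(decisions, stratum = "pooled", reps = 500L,
                           seed = 1L) {
  stats <- standardization_stats(decisions, stratum = stratum)
  z <- standardize(decisions, stats)
  end_rows <- decisions[decisions$label == "leave" & !decisions$flag_degenerate,
                        indicator_cols]
  pa <- parallel_analysis(end_rows, reps = reps, seed = seed)
  pca <- pca_first_component(end_rows)
  w <- composite_weights(pca)
  z$composite_weighted <- weighted_composite(z, w)
  z$composite_unweighted <- unweighted_composite(z)
  list(decisions = z, stats = stats, parallel = pa, pca = pca, weights = w)
}

#' Run the full patch-leaving analysis pipeline
#'
#' For each analysis stratum (by default every condition x age-group
#' cell), builds the decision set, fits standardization, parallel
#' analysis, PCA and both composites, evaluates one ROC curve per
#' predictor (DeLong confidence intervals, Youden-optimal thresholds),
#' and combines each configured predictor pair into a compound AND/OR
#' rule (Hanley-McNeil confidence intervals). Strata whose decisions
#' contain a single class, or no decisions at all, are skipped with a
#' logged reason. Results are deterministic given the seed.
#'
#' @param log A validated `forage_log` (e.g. from [read_event_log] or
#'   [simulate_session]).
#' @param strata Character vector of stratification columns (default
#'   `"condition"`; add `"age_group"` for developmental splits).
#' @param predictors Predictors to evaluate (defaults to the four
#'   indicators, both composites, and the RIAIR).
#' @param polarity Named polarity overrides (`"below"`/`"above"` per
#'   predictor); unnamed predictors use the built-in defaults.
#' @param combine_pairs List of 2-vectors of predictor names to combine
#'   (default: each composite with the RIAIR).
#' @param combine_mode `"independence"` or `"empirical"` (see
#'   [combine_roc_ml]).
#' @param min_picks,value_mode,method,exact_cap,per_target,anchor_first
#'   Passed to [decision_table].
#' @param reps Parallel-analysis repetitions.
#' @param seed RNG seed for the parallel analysis.
#' @param level Confidence level for AUC intervals.
#' @return A `patchleave_result` list: `results` (the per-stratum
#'   predictor table: AUC, CI, threshold or compound rule, sensitivity,
#'   specificity, class counts), `curves`, `composites` (per-stratum PCA
#'   and parallel-analysis fits), `skipped`, `provenance`.
#' @export
run_pipeline <- function(log, strata = "condition",
                         predictors = names(default_polarity),
                         polarity = character(), combine_pairs = list(
                           c("composite_weighted", "riair"),
                           c("composite_unweighted", "riair")),
                         combine_mode = "independence", min_picks = 3L,
                         value_mode = "items", method = "auto",
                         exact_cap = 13L, per_target = FALSE,
                         anchor_first = FALSE, reps = 500L, seed = 1L,
                         level = 0.95) {
  pol <- default_polarity
  pol[names(polarity)] <- polarity
  dec <- decision_table(log, min_picks = min_picks, value_mode = value_mode,
                        method = method, exact_cap = exact_cap,
                        per_target = per_target, anchor_first = anchor_first)
  if (nrow(dec) == 0) {
    abort("no decisions: every trial has fewer than min_picks targets",
          class = "patchleave_domain_error")
  }
  dec$stratum <- do.call(paste, c(dec[strata], sep = "/"))
  all_strata <- unique(do.call(paste, c(as.data.frame(log)[strata],
                                        sep = "/")))
  results <- list()
  curves <- list()
  fits <- list()
  skipped <- character()
  for (s in all_strata) {
    d <- dec[dec$stratum == s, , drop = FALSE]
    if (nrow(d) == 0) {
      inform(paste0("stratum '", s,
                    "' skipped: no trials with >= ", min_picks,
                    " collected targets"))
      skipped <- c(skipped, s)
      next
    }
    if (length(unique(d$label)) < 2) {
      inform(paste0("stratum '", s,
                    "' skipped: fewer than two decision classes"))
      skipped <- c(skipped, s)
      next
    }
    fit <- tryCatch(
      fit_composites(d, stratum = s, reps = reps, seed = seed),
      error = function(e) {
        inform(paste0("stratum '", s, "' skipped: ", conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) {
      skipped <- c(skipped, s)
      next
    }
    d <- fit$decisions
    fits[[s]] <- fit[c("stats", "parallel", "pca", "weights")]
    stratum_curves <- list()
    rows <- list()
    for (p in predictors) {
      cv <- roc_curve(d[[p]], d$label, polarity = pol[[p]], predictor = p)
      ci <- delong_ci(cv$values, cv$labels,
                      direction = if (cv$polarity == "above") "above"
                                  else "below",
                      level = level)
      yo <- youden_optimal(cv)
      stratum_curves[[p]] <- cv
      rows[[p]] <- tibble::tibble(
        stratum = s, predictor = p, auc = cv$auc,
        ci_low = ci$ci[1], ci_high = ci$ci[2],
        rule = paste(p, if (pol[[p]] == "below") "<" else ">",
                     signif(yo$threshold, 4)),
        threshold = yo$threshold, sensitivity = yo$sensitivity,
        specificity = yo$specificity, n_leave = cv$n_leave,
        n_stay = cv$n_stay
      )
    }
    for (pair in combine_pairs) {
      cmb <- combine_roc_ml(stratum_curves[[pair[1]]],
                            stratum_curves[[pair[2]]],
                            mode = combine_mode, level = level)
      yo <- youden_optimal(cmb)
      best_row <- cmb$points[order(-(cmb$points$sensitivity +
                                       cmb$points$specificity)), ][1, ]
      lab <- paste0("combined ", pair[1], " + ", pair[2])
      stratum_curves[[lab]] <- cmb
      rows[[lab]] <- tibble::tibble(
        stratum = s, predictor = lab, auc = cmb$auc,
        ci_low = cmb$ci[1], ci_high = cmb$ci[2],
        rule = format_compound_rule(cmb, best_row),
        threshold = NA_real_, sensitivity = yo$sensitivity,
        specificity = yo$specificity, n_leave = cmb$n_leave,
        n_stay = cmb$n_stay
      )
    }
    curves[[s]] <- stratum_curves
    results[[s]] <- dplyr::bind_rows(rows)
  }
  structure(
    list(results = dplyr::bind_rows(results), curves = curves,
         composites = fits, decisions = dec, skipped = skipped,
         provenance = list(seed = seed, strata = strata,
                           predictors = predictors, polarity = as.list(pol),
                           combine_mode = combine_mode,
                           min_picks = min_picks, value_mode = value_mode,
                           reps = reps, level = level,
                           package_version =
                             as.character(utils::packageVersion("patchleave")))),
    class = "patchleave_result"
  )
}

#' @export
print.patchleave_result <- function(x, ...) {
  cat("<patchleave_result> ", length(x$curves), " strata, ",
      nrow(x$results), " predictor rows", sep = "")
  if (length(x$skipped) > 0) {
    cat(" (skipped: ", paste(x$skipped, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  print(x$results[, c("stratum", "predictor", "auc", "sensitivity",
                      "specificity")], n = 20)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `results.csv` (the per-stratum predictor table), one
#' `curve_<stratum>_<predictor>.csv` dump per ROC curve, and
#' `provenance.json` (seeds and configuration).
#'
#' @param result A `patchleave_result` from [run_pipeline].
#' @param dir Output directory (created if needed).
#' @param curves Also dump every curve's operating points (default
#'   `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, curves = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$results, file.path(dir, "results.csv"),
                   progress = FALSE)
  if (curves) {
    for (s in names(result$curves)) {
      for (p in names(result$curves[[s]])) {
        pts <- result$curves[[s]][[p]]$points
        fn <- paste0("curve_", gsub("[^A-Za-z0-9_-]", "_", s), "_",
                     gsub("[^A-Za-z0-9_-]", "_", p), ".csv")
        readr::write_csv(pts, file.path(dir, fn), progress = FALSE)
      }
    }
  }
  jsonlite::write_json(result$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
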