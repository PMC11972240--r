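indicator_cols <- c("best_r", "mean_itd_px", "pao_pct", "intersection_rate")
z_cols <- c("z_best_r", "z_mean_itd", "z_pao", "z_intersection")

#' Standardization statistics for the indicator population
#'
#' The composites are built from z-scores whose reference population is
#' *all* trial-so-far instances within an analysis stratum (every value
#' computed from the third pick of every trial onward), not just
#' end-of-trial values. This function records that population's mean and
#' standard deviation per indicator so the transform is auditable.
#'
#' @param series Indicator table with columns `best_r`, `mean_itd_px`,
#'   `pao_pct`, `intersection_rate` (flagged-degenerate rows are
#'   excluded if a `flag_degenerate` column is present).
#' @param stratum Label recorded with the statistics.
#' @return A `standardization_stats` tibble: indicator, mean, sd, n,
#'   stratum.
#' @export
standardization_stats <- function(series, stratum = "pooled") {
  if ("flag_degenerate" %in% names(series)) {
    series <- series[!series$flag_degenerate, , drop = FALSE]
  }
  stats <- purrr::map_dfr(indicator_cols, function(col) {
    v <- series[[col]]
    v <- v[is.finite(v)]
    tibble::tibble(indicator = col, mean = mean(v), sd = sd(v),
                   n = length(v), stratum = stratum)
  })
  bad <- stats$indicator[!is.finite(stats$sd) | stats$sd <= 0]
  if (length(bad) > 0) {
    abort(paste0("zero or undefined standard deviation for ",
                 paste(bad, collapse = ", "), " in stratum '", stratum, "'"),
          class = "patchleave_degenerate_error")
  }
  structure(stats, class = c("standardization_stats", class(stats)))
}

#' Z-score an indicator table
#'
#' @param series Indicator table (see [standardization_stats]).
#' @param stats A `standardization_stats` object declaring the reference
#'   population.
#' @return `series` with added columns `z_best_r`, `z_mean_itd`, `z_pao`,
#'   `z_intersection`.
#' @export
standardize <- function(series, stats) {
  for (i in seq_along(indicator_cols)) {
    row <- stats[stats$indicator == indicator_cols[i], ]
    series[[z_cols[i]]] <- (series[[indicator_cols[i]]] - row$mean) / row$sd
  }
  series
}

#' Horn's parallel analysis for component retention
#'
#' Compares the eigenvalues of the observed 4x4 correlation matrix with
#' those of random standard-normal data of identical shape: each observed
#' eigenvalue is adjusted by subtracting the mean random eigenvalue's
#' excess over 1, and components with adjusted eigenvalue > 1 are
#' retained. The input should contain one row per trial (end-of-trial
#' indicator values) so rows are independent.
#'
#' @param tbl Table whose four indicator columns enter the analysis
#'   (columns `best_r`, `mean_itd_px`, `pao_pct`, `intersection_rate`, or
#'   any all-numeric 4-column table).
#' @param reps Number of random datasets (>= 100; default 500).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return List with `eigenvalues`, `random_means`, `adjusted`,
#'   `retained`, `reps`, `seed`.
#' @export
parallel_analysis <- function(tbl, reps = 500L, seed = 1L) {
  m <- .indicator_matrix(tbl)
  if (nrow(m) <= ncol(m)) {
    abort("parallel analysis needs more rows than columns",
          class = "patchleave_domain_error")
  }
  if (reps < 100L) {
    abort("reps must be >= 100", class = "patchleave_config_error")
  }
  obs <- eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values
  k <- ncol(m)
  rand <- matrix(0, reps, k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (r in seq_len(reps)) {
    sim <- matrix(rnorm(nrow(m) * k), nrow(m), k)
    rand[r, ] <- eigen(cor(sim), symmetric = TRUE, only.values = TRUE)$values
  }
  rmeans <- colMeans(rand)
  adjusted <- obs - (rmeans - 1)
  # retain the leading run of components whose adjusted eigenvalue
  # exceeds 1 (stopping at the first failure, as in Horn's procedure)
  retained <- match(FALSE, adjusted > 1, nomatch = k + 1L) - 1L
  list(eigenvalues = obs, random_means = rmeans, adjusted = adjusted,
       retained = retained, reps = reps, seed = seed)
}

.indicator_matrix <- function(tbl) {
  if (all(indicator_cols %in% names(tbl))) {
    tbl <- tbl[, indicator_cols]
  }
  m <- as.matrix(tbl)
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  const <- apply(m, 2, sd) == 0
  if (any(const)) {
    abort(paste0("constant column(s): ",
                 paste(colnames(m)[const], collapse = ", ")),
          class = "patchleave_degenerate_error")
  }
  m
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' First principal component of the indicator correlation matrix
#'
#' PCA on the correlation matrix of end-of-trial indicator values (one
#' row per trial, to keep observations independent). Loadings are the
#' first eigenvector scaled by the square root of its eigenvalue, with
#' the component oriented so the best-r loading is positive (component
#' sign is otherwise arbitrary). The percentage of variance explained is
#' `100 * lambda_1 / 4`.
#'
#' @inheritParams parallel_analysis
#' @return A `pca_result` list: `eigenvalues`, `loadings` (named, first
#'   component), `variance_explained_pct`, `n`.
#' @export
pca_first_component <- function(tbl) {
  m <- .indicator_matrix(tbl)
  e <- eigen(cor(m), symmetric = TRUE)
  vec <- e$vectors[, 1]
  br_idx <- if (!is.null(colnames(m)) && indicator_cols[1] %in% colnames(m)) {
    match(indicator_cols[1], colnames(m))
  } else 1L
  if (vec[br_idx] < 0) vec <- -vec
  loadings <- vec * sqrt(e$values[1])
  names(loadings) <- colnames(m) %||% indicator_cols
  structure(
    list(eigenvalues = e$values, loadings = loadings,
         variance_explained_pct = 100 * e$values[1] / length(e$values),
         n = nrow(m)),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> first component explains ",
      format(x$variance_explained_pct, digits = 4), "% of variance (n = ",
      x$n, ")\n", sep = "")
  cat("eigenvalues:", format(x$eigenvalues, digits = 3), "\n")
  cat("loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Composite weights from PCA loadings
#'
#' The weighted composite uses the magnitudes of the first-component
#' loadings as weights; the direction of each indicator's contribution is
#' fixed by the composite's sign structure (best-r enters positively, the
#' three path/crossing indicators negatively), so signed loadings would
#' double-apply direction.
#'
#' @param pca A `pca_result`, or `NULL` for unit weights.
#' @return Named non-negative weight vector over the four indicators.
#' @export
composite_weights <- function(pca = NULL) {
  if (is.null(pca)) {
    return(setNames(rep(1, 4), indicator_cols))
  }
  w <- abs(pca$loadings)
  names(w) <- names(pca$loadings)
  w[indicator_cols]
}

#' Weighted composite organization score
#'
#' `C_w = w_br * z_br - w_itd * z_itd - w_pao * z_pao - w_int * z_int`:
#' higher values mean more organized search. Mean ITD, PAO and the
#' intersection rate carry negative signs because lower values of those
#' indicators mean higher organization, while best-r is interpreted
#' directly.
#'
#' @param z Table with z-score columns `z_best_r`, `z_mean_itd`, `z_pao`,
#'   `z_intersection` (as produced by [standardize]).
#' @param weights Named non-negative weights (see [composite_weights]).
#' @return Numeric vector of composite values (`NA` where any z-score is
#'   missing).
#' @export
weighted_composite <- function(z, weights) {
  w <- unname(weights[indicator_cols])
  w[1] * z$z_best_r - w[2] * z$z_mean_itd - w[3] * z$z_pao -
    w[4] * z$z_intersection
}

#' Unweighted composite organization score
#'
#' The weighted composite with unit weights:
#' `C_u = z_br - z_itd - z_pao - z_int`.
#'
#' @inheritParams weighted_composite
#' @return Numeric vector of composite values.
#' @export
unweighted_composite <- function(z) {
  weighted_composite(z, setNames(rep(1, 4), indicator_cols))
}
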