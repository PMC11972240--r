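make_indicator_table <- function(n, seed = 1, latent = FALSE,
                                 loading = 0.9) {
  set.seed(seed)
  if (latent) {
    f <- rnorm(n)
    noise <- sqrt(1 - loading^2)
    tibble::tibble(
      best_r = loading * f + noise * rnorm(n),
      mean_itd_px = -loading * f + noise * rnorm(n),
      pao_pct = -loading * f + noise * rnorm(n),
      intersection_rate = -loading * f + noise * rnorm(n),
      latent = f
    )
  } else {
    tibble::tibble(
      best_r = rnorm(n), mean_itd_px = rnorm(n), pao_pct = rnorm(n),
      intersection_rate = rnorm(n)
    )
  }
}

test_that("standardized columns have mean 0 and sd 1 over their population", {
  tbl <- make_indicator_table(400, seed = 31)
  tbl$flag_degenerate <- FALSE
  stats <- standardization_stats(tbl, stratum = "test")
  z <- standardize(tbl, stats)
  for (col in c("z_best_r", "z_mean_itd", "z_pao", "z_intersection")) {
    expect_equal(mean(z[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(z[[col]]), 1, tolerance = 1e-12)
  }
  # a value at the population mean maps to z = 0
  row <- tibble::tibble(best_r = stats$mean[1], mean_itd_px = stats$mean[2],
                        pao_pct = stats$mean[3],
                        intersection_rate = stats$mean[4])
  z0 <- standardize(row, stats)
  expect_equal(unlist(z0[, c("z_best_r", "z_mean_itd", "z_pao",
                             "z_intersection")], use.names = FALSE),
               rep(0, 4))
})

test_that("zero-variance indicators are rejected with the indicator named", {
  tbl <- make_indicator_table(50, seed = 32)
  tbl$pao_pct <- 7
  expect_error(standardization_stats(tbl, stratum = "flat"), "pao_pct",
               class = "patchleave_degenerate_error")
})

test_that("parallel analysis finds no real structure in independent noise", {
  tbl <- make_indicator_table(5000, seed = 33)
  pa <- parallel_analysis(tbl, reps = 500, seed = 9)
  # the leading adjusted eigenvalue sits at the retention boundary (~1),
  # so at most one spurious component can survive, and only marginally
  expect_lte(pa$retained, 1)
  expect_lt(abs(pa$adjusted[1] - 1), 0.05)
  expect_lt(abs(sum(pa$eigenvalues) - 4), 1e-8)
})

test_that("parallel analysis recovers a single strong factor", {
  tbl <- make_indicator_table(5000, seed = 34, latent = TRUE, loading = 0.99)
  pa <- parallel_analysis(tbl[, 1:4], reps = 200, seed = 9)
  expect_equal(pa$retained, 1)
  expect_gt(pa$adjusted[1], 3.5)
})

test_that("parallel analysis is deterministic given its seed", {
  tbl <- make_indicator_table(300, seed = 35)
  a <- parallel_analysis(tbl, reps = 100, seed = 4)
  b <- parallel_analysis(tbl, reps = 100, seed = 4)
  expect_identical(a$adjusted, b$adjusted)
})

test_that("PCA variance explained spans the rank-1 and independent extremes", {
  f <- rnorm(500)
  rank1 <- tibble::tibble(best_r = f, mean_itd_px = 2 * f, pao_pct = -f,
                          intersection_rate = 0.5 * f)
  res <- pca_first_component(rank1)
  expect_equal(res$variance_explained_pct, 100, tolerance = 1e-8)
  expect_equal(sum(res$eigenvalues), 4, tolerance = 1e-8)

  indep <- make_indicator_table(20000, seed = 36)
  res2 <- pca_first_component(indep)
  expect_equal(res2$variance_explained_pct, 25, tolerance = 2)
})

test_that("loadings orient best_r positive and respond to column negation", {
  tbl <- make_indicator_table(1000, seed = 37, latent = TRUE)[, 1:4]
  res <- pca_first_component(tbl)
  expect_gt(res$loadings[["best_r"]], 0)
  flipped <- tbl
  flipped$pao_pct <- -flipped$pao_pct
  res2 <- pca_first_component(flipped)
  expect_equal(res2$loadings[["pao_pct"]], -res$loadings[["pao_pct"]],
               tolerance = 1e-8)
  expect_equal(abs(res2$loadings), abs(res$loadings), tolerance = 1e-8)
})

test_that("composite arithmetic follows the signed weighted sum", {
  z <- tibble::tibble(z_best_r = 1, z_mean_itd = 1, z_pao = 1,
                      z_intersection = 1)
  w <- setNames(rep(0.5, 4),
                c("best_r", "mean_itd_px", "pao_pct", "intersection_rate"))
  expect_equal(weighted_composite(z, w), -1.0)
  expect_equal(weighted_composite(z, setNames(rep(1, 4), names(w))),
               unweighted_composite(z))
  z2 <- tibble::tibble(z_best_r = 2, z_mean_itd = 1, z_pao = 1,
                       z_intersection = 1)
  expect_equal(unweighted_composite(z2), -1)
  z0 <- tibble::tibble(z_best_r = 0, z_mean_itd = 0, z_pao = 0,
                       z_intersection = 0)
  expect_equal(weighted_composite(z0, w), 0)
})

test_that("composites average zero over the standardization population", {
  tbl <- make_indicator_table(800, seed = 38, latent = TRUE)[, 1:4]
  tbl$flag_degenerate <- FALSE
  stats <- standardization_stats(tbl)
  z <- standardize(tbl, stats)
  w <- composite_weights(pca_first_component(tbl))
  expect_equal(mean(weighted_composite(z, w)), 0, tolerance = 1e-10)
  expect_equal(mean(unweighted_composite(z)), 0, tolerance = 1e-10)
})

test_that("composites are invariant to affine rescaling of raw indicators", {
  tbl <- make_indicator_table(500, seed = 39, latent = TRUE)[, 1:4]
  tbl$flag_degenerate <- FALSE
  fit <- function(x) {
    stats <- standardization_stats(x)
    z <- standardize(x, stats)
    w <- composite_weights(pca_first_component(x))
    weighted_composite(z, w)
  }
  scaled <- tbl
  scaled$mean_itd_px <- 100 * scaled$mean_itd_px + 7
  expect_equal(fit(scaled), fit(tbl), tolerance = 1e-8)
})
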