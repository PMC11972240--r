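test_that("best_r matches scanner and hand-computed cases", {
  # order perfectly linear in x
  expect_equal(best_r(c(10, 20, 30, 40), c(3, 1, 4, 1)), 1.0)
  # Pearson of (1,2,3) vs (0,2,1) is 0.5; y is constant and contributes 0
  expect_equal(best_r(c(0, 2, 1), c(0, 0, 0)), 0.5)
  # translation invariance
  set.seed(11)
  x <- runif(8, 0, 100); y <- runif(8, 0, 100)
  expect_equal(best_r(x + 37, y - 12), best_r(x, y))
  # fully degenerate path flagged
  br <- best_r(rep(1, 3), rep(1, 3))
  expect_equal(as.numeric(br), 0)
  expect_true(attr(br, "degenerate"))
  expect_error(best_r(c(0, 1), c(0, 1)), class = "patchleave_domain_error")
})

test_that("mean inter-target distance is the mean consecutive Euclidean step", {
  expect_equal(mean_itd(c(0, 3), c(0, 4)), 5.0)
  expect_equal(mean_itd(c(0, 3, 3), c(0, 4, 4)), 2.5)
  set.seed(12)
  x <- runif(6); y <- runif(6)
  expect_equal(mean_itd(3 * x, 3 * y), 3 * mean_itd(x, y))
})

test_that("optimal path length matches a brute-force permutation oracle", {
  expect_equal(optimal_path_length(c(1, 0, 2), c(0, 0, 0)), 2.0)
  expect_equal(optimal_path_length(c(0, 1, 1, 0), c(0, 0, 1, 1)), 3.0)
  set.seed(13)
  for (rep in 1:5) {
    x <- runif(8, 0, 100); y <- runif(8, 0, 100)
    oracle <- brute_force_path(x, y)
    expect_equal(optimal_path_length(x, y, method = "exact"), oracle)
    expect_gte(optimal_path_length(x, y, method = "heuristic"),
               oracle - 1e-9)
  }
  expect_error(optimal_path_length(runif(20), runif(20), method = "exact"),
               class = "patchleave_capacity_error")
})

test_that("PAO is zero on optimal orders, matches hand case, never negative", {
  # collection order already optimal
  expect_equal(pao(c(0, 1, 2), c(0, 0, 0)), 0.0)
  # actual 3 vs optimal 2 (verified against all 6 orders by the oracle)
  expect_equal(brute_force_path(c(0, 2, 1), c(0, 0, 0)), 2)
  expect_equal(pao(c(0, 2, 1), c(0, 0, 0)), 50.0)
  set.seed(14)
  for (rep in 1:10) {
    x <- runif(7, 0, 50); y <- runif(7, 0, 50)
    expect_gte(pao(x, y), -1e-9)
  }
  dg <- pao(rep(2, 4), rep(2, 4))
  expect_true(is.na(dg))
  expect_true(attr(dg, "degenerate"))
})

test_that("intersection rate counts non-adjacent crossing pairs per segment", {
  # segments (0,0)-(1,1) and (1,0)-(0,1) cross at (0.5, 0.5): 1 of 3 segments
  expect_equal(intersection_rate(c(0, 1, 1, 0), c(0, 1, 0, 1)), 1 / 3)
  # monotone staircase never crosses itself
  expect_equal(intersection_rate(c(0, 1, 1, 2), c(0, 0, 1, 1)), 0)
  # per-target denominator option
  expect_equal(intersection_rate(c(0, 1, 1, 0), c(0, 1, 0, 1),
                                 per_target = TRUE), 1 / 4)
  # isometry invariance under rotation
  set.seed(15)
  x <- runif(9, -50, 50); y <- runif(9, -50, 50)
  th <- 0.83
  xr <- x * cos(th) - y * sin(th)
  yr <- x * sin(th) + y * cos(th)
  expect_equal(intersection_rate(xr, yr), intersection_rate(x, y))
})

test_that("trial-so-far series has one row per n >= 3 and the prefix property", {
  set.seed(16)
  x <- runif(10, 0, 1000); y <- runif(10, 0, 1000)
  tr <- make_trial(x, y)
  ser <- indicator_series(tr)
  expect_equal(nrow(ser), 8)
  expect_equal(ser$n, 3:10)
  # element 3 equals the full-trial value of the 3-pick prefix
  pre <- indicator_series(make_trial(x[1:3], y[1:3]))
  expect_equal(ser$best_r[1], pre$best_r[1])
  expect_equal(ser$pao_pct[1], pre$pao_pct[1])
  # appending a pick never changes earlier elements
  tr11 <- make_trial(c(x, 512), c(y, 777), t = 1:11)
  ser11 <- indicator_series(tr11)
  expect_equal(ser11[1:8, c("best_r", "mean_itd_px", "pao_pct",
                            "intersection_rate")],
               ser[, c("best_r", "mean_itd_px", "pao_pct",
                       "intersection_rate")])
})

test_that("indicator invariances hold under translation and scaling", {
  set.seed(17)
  x <- runif(8, 0, 500); y <- runif(8, 0, 500)
  expect_equal(pao(x + 100, y - 40), pao(x, y))
  expect_equal(pao(2.5 * x, 2.5 * y), pao(x, y))
  expect_equal(intersection_rate(x + 9, y + 9), intersection_rate(x, y))
  expect_equal(best_r(x * 4, y * 0.25), best_r(x, y))
})

test_that("organized scanners beat random agents on the organization indicators", {
  set.seed(18)
  arena <- arena_config(set_size = 80, speed = 0)
  run_agents <- function(agent, n = 25) {
    purrr::map_dfr(seq_len(n), function(i) {
      tr <- simulate_trial(arena, agent, trial_id = paste0("t", i))$trial
      picks <- target_picks(tr)
      tibble::tibble(
        best_r = as.numeric(best_r(picks$x_px, picks$y_px)),
        pao = as.numeric(pao(picks$x_px, picks$y_px)),
        xrate = intersection_rate(picks$x_px, picks$y_px)
      )
    })
  }
  scan <- run_agents(agent_config("scanner", disorder = 0.05,
                                  leave_rule = rule_fixed_count(10)))
  rand <- run_agents(agent_config("random", disorder = 1,
                                  leave_rule = rule_fixed_count(10)))
  expect_gt(mean(scan$best_r), mean(rand$best_r))
  expect_lt(mean(scan$pao), mean(rand$pao))
  expect_lt(mean(scan$xrate), mean(rand$xrate))
})
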