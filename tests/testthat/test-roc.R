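test_that("ROC AUC equals brute-force pair counting, ties included", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    values <- sample(1:8, n, replace = TRUE) # heavy ties on purpose
    labels <- c("stay", "leave",
                sample(c("stay", "leave"), n - 2, replace = TRUE))
    cv <- roc_curve(values, labels, polarity = "above")
    expect_equal(cv$auc, brute_force_auc(values, labels == "leave"))
    # trapezoid over the curve's own points reproduces the AUC
    expect_equal(auc_trapezoid(cv$points$sensitivity,
                               cv$points$specificity), cv$auc)
  }
})

test_that("separated and permuted predictors hit the AUC landmarks", {
  leave <- runif(40, 0, 1)
  stay <- runif(60, 2, 3)
  values <- c(leave, stay)
  labels <- rep(c("leave", "stay"), c(40, 60))
  cv <- roc_curve(values, labels, polarity = "below")
  expect_equal(cv$auc, 1)

  cv2 <- roc_curve(c(2, 3, 1, 2.5), rep(c("leave", "stay"), each = 2),
                   polarity = "above")
  expect_equal(cv2$auc, 0.75)
})

test_that("auto polarity picks the direction with AUC >= 0.5", {
  set.seed(42)
  labels <- rep(c("leave", "stay"), each = 50)
  values <- c(rnorm(50, 1), rnorm(50, 0)) # leave higher
  up <- roc_curve(values, labels, polarity = "auto")
  expect_equal(up$polarity, "above")
  down <- roc_curve(-values, labels, polarity = "auto")
  expect_equal(down$polarity, "below")
  expect_equal(up$auc, down$auc)
})

test_that("ROC agrees with pROC on a random dataset", {
  skip_if_not_installed("pROC")
  set.seed(43)
  labels <- sample(c("stay", "leave"), 200, replace = TRUE)
  values <- rnorm(200) + (labels == "leave") * 0.8
  cv <- roc_curve(values, labels, polarity = "above")
  ref <- pROC::roc(response = labels, predictor = values,
                   levels = c("stay", "leave"), direction = "<",
                   quiet = TRUE)
  expect_equal(cv$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Youden optimum maximizes J with ties broken toward sensitivity", {
  curve <- list(points = tibble::tibble(
    threshold = c(1, 2), sensitivity = c(0.9, 0.7),
    specificity = c(0.6, 0.75)))
  yo <- youden_optimal(curve)
  expect_equal(yo$youden_j, 0.5)
  expect_equal(yo$sensitivity, 0.9)

  tie <- list(points = tibble::tibble(
    threshold = c(1, 2), sensitivity = c(0.4, 0.8),
    specificity = c(0.8, 0.4)))
  expect_equal(youden_optimal(tie)$sensitivity, 0.8)

  perfect <- list(points = tibble::tibble(
    threshold = 0, sensitivity = 1, specificity = 1))
  expect_equal(youden_optimal(perfect)$youden_j, 1)
})

test_that("trapezoid AUC matches hand computations", {
  expect_equal(auc_trapezoid(1, 1), 1.0)
  expect_equal(auc_trapezoid(0.5, 0.5), 0.5)
  # two points at FPR 0.2 and 0.4: 0.08 + 0.17 + 0.57
  expect_equal(auc_trapezoid(c(0.8, 0.9), c(0.8, 0.6)), 0.82)
})

test_that("DeLong CI matches pROC and behaves under label swap", {
  skip_if_not_installed("pROC")
  set.seed(44)
  labels <- sample(c("stay", "leave"), 150, replace = TRUE)
  values <- rnorm(150) + (labels == "leave")
  ci <- delong_ci(values, labels, direction = "above")
  ref <- pROC::roc(response = labels, predictor = values,
                   levels = c("stay", "leave"), direction = "<",
                   quiet = TRUE)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ci$ci[1], ref_ci[1], tolerance = 1e-9)
  expect_equal(ci$auc, ref_ci[2], tolerance = 1e-9)
  expect_equal(ci$ci[2], ref_ci[3], tolerance = 1e-9)

  swapped <- ifelse(labels == "leave", "stay", "leave")
  ci_sw <- delong_ci(values, swapped, direction = "above")
  expect_equal(ci_sw$ci, 1 - rev(ci$ci), tolerance = 1e-9)

  # near-perfect separation leaves almost no variance
  sep <- delong_ci(c(rnorm(50, 10), rnorm(50, -10)),
                   rep(c("leave", "stay"), each = 50))
  expect_lt(diff(sep$ci), 1e-6)
})

test_that("Hanley-McNeil SE matches the closed form and shrinks with n", {
  ci <- hanley_mcneil_ci(0.5, 10, 10)
  expect_equal(ci$se, sqrt(0.0175))
  # Q1 = Q2 = 1/3 at A = 0.5 is implied by the SE above; check monotonicity
  se_40 <- hanley_mcneil_ci(0.8, 40, 25)$se
  se_80 <- hanley_mcneil_ci(0.8, 80, 25)$se
  expect_lt(se_80, se_40)
  expect_true(all(hanley_mcneil_ci(0.9, 30, 30)$ci >= 0 &
                    hanley_mcneil_ci(0.9, 30, 30)$ci <= 1))
})

test_that("monotone transforms leave the ROC curve unchanged", {
  set.seed(45)
  labels <- sample(c("stay", "leave"), 80, replace = TRUE)
  values <- rnorm(80) + (labels == "leave") * 0.7
  a <- roc_curve(values, labels, polarity = "above")
  b <- roc_curve(exp(values), labels, polarity = "above")
  expect_equal(a$auc, b$auc)
  expect_equal(a$points$sensitivity, b$points$sensitivity)
  expect_equal(a$points$specificity, b$points$specificity)
  ya <- youden_optimal(a); yb <- youden_optimal(b)
  expect_equal(ya$youden_j, yb$youden_j)
  # thresholds sit between the same adjacent observations
  expect_equal(ya$sensitivity, yb$sensitivity)
  expect_equal(ya$specificity, yb$specificity)
})

test_that("degenerate ROC inputs are rejected or warned", {
  expect_error(roc_curve(1:5, rep("stay", 5)),
               class = "patchleave_domain_error")
  expect_warning(roc_curve(rep(1, 10), rep(c("stay", "leave"), 5)),
                 "constant")
})
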