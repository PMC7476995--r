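test_that("confusion metrics match hand arithmetic and symmetry", {
  cm <- matrix(0, 12, 12, dimnames = list(cell_classes(), cell_classes()))
  diag(cm) <- 10
  perfect <- class_metrics(cm)
  expect_true(all(perfect$per_class$accuracy == 100))
  expect_true(all(perfect$per_class$sensitivity == 100))
  expect_equal(perfect$overall_accuracy, 100)

  cm2 <- matrix(0, 12, 12, dimnames = list(cell_classes(), cell_classes()))
  cm2[1, 1] <- 8; cm2[1, 2] <- 2; cm2[2, 1] <- 1; cm2[2, 2] <- 9
  m <- class_metrics(cm2)
  expect_equal(m$per_class$sensitivity[1], 80)
  expect_equal(m$per_class$specificity[1], 90)
  expect_equal(m$overall_accuracy, 85)
  # empty truth rows are flagged, not errors
  expect_true(is.na(m$per_class$sensitivity[3]))
  # transposition swaps the two active sensitivities
  mt <- class_metrics(t(cm2))
  expect_equal(mt$per_class$sensitivity[1], 8 / 9 * 100)
  expect_equal(mt$per_class$sensitivity[2], 9 / 11 * 100)
  expect_error(class_metrics(matrix(0, 12, 12)), "non-empty")
})

test_that("overall accuracy equals the mean per-cell correctness", {
  marrowdiff:::with_local_seed(15, {
    for (i in 1:5) {
      truth <- sample(cell_classes(), 300, replace = TRUE)
      pred <- ifelse(runif(300) < 0.7, truth,
                     sample(cell_classes(), 300, replace = TRUE))
      cm <- confusion_matrix(truth, pred)
      expect_equal(class_metrics(cm)$overall_accuracy,
                   100 * mean(truth == pred))
    }
  })
})

test_that("binomial CIs: Wald and Wilson agree at large n, clip at bounds", {
  ci <- proportion_ci(27811, 30867)        # phat ~ 0.901
  cw <- proportion_ci(27811, 30867, method = "wilson")
  expect_equal(ci, cw, tolerance = 1e-3)
  expect_equal(proportion_ci(50, 50)[2], 1)
  expect_equal(proportion_ci(0, 50)[1], 0)
  expect_error(proportion_ci(51, 50))
})

test_that("ICC matches a two-way ANOVA oracle and its closed form", {
  marrowdiff:::with_local_seed(31, {
    for (i in 1:5) {
      m <- matrix(rnorm(6 * 2, sd = 2) + rep(rnorm(6, sd = 3), 2), 6, 2)
      r <- icc_consistency(m)
      df <- data.frame(y = as.vector(m), subj = factor(rep(1:6, 2)),
                       rater = factor(rep(1:2, each = 6)))
      a <- summary(stats::aov(y ~ subj + rater, df))[[1]]
      msr <- a["subj", "Mean Sq"]; mse <- a["Residuals", "Mean Sq"]
      expect_equal(r$F, msr / mse, tolerance = 1e-10)
      expect_equal(r$icc, (msr - mse) / (msr + mse), tolerance = 1e-10)
      # closed form from F alone agrees to 1e-12
      rf <- icc_from_f(r$F, 6, 2)
      expect_equal(rf$icc, r$icc, tolerance = 1e-12)
      expect_equal(rf$ci, r$ci, tolerance = 1e-12)
    }
  })
})

test_that("duplicate rater columns give ICC 1; constant data are flagged", {
  x <- c(4, 9, 2, 7, 5)
  expect_equal(icc_consistency(cbind(x, x))$icc, 1)
  r <- icc_consistency(matrix(3, 5, 2))
  expect_true(r$undefined)
  expect_true(is.na(r$icc))
})

test_that("for k = 2 the ICC is (F-1)/(F+1), matching published rows", {
  f_vals <- c(17.748, 16.063, 7.422, 2.629, 2.165)
  expected <- c(0.893, 0.883, 0.763, 0.449, 0.368)
  for (i in seq_along(f_vals)) {
    r <- icc_from_f(f_vals[i], 124, 2)
    expect_equal(r$icc, (f_vals[i] - 1) / (f_vals[i] + 1), tolerance = 1e-12)
    expect_equal(round(r$icc, 3), expected[i])
    expect_identical(r$df1, 123); expect_identical(r$df2, 123)
  }
  expect_equal(icc_from_f(1, 124, 2)$icc, 0)
  expect_error(icc_from_f(-2, 124, 2))
})

test_that("Passing-Bablok recovers exact lines and matches the brute oracle", {
  pb <- suppressWarnings(passing_bablok(1:10, 2 * (1:10) + 1))
  expect_equal(pb$slope, 2)
  expect_equal(pb$intercept, 1)
  expect_true(pb$linear)

  x <- c(1, 2, 3, 4, 5); y <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  pb2 <- suppressWarnings(passing_bablok(x, y))
  o <- pb_oracle(x, y)
  expect_equal(pb2$slope, o$slope)
  expect_equal(pb2$intercept, o$intercept)
  expect_lte(pb2$n_slopes, 10)

  # random sets against the oracle
  marrowdiff:::with_local_seed(41, {
    for (i in 1:10) {
      n <- sample(5:30, 1)
      xr <- runif(n, 0, 50)
      yr <- 0.8 * xr + 3 + rnorm(n, sd = 2)
      pbr <- suppressWarnings(passing_bablok(xr, yr))
      or <- pb_oracle(xr, yr)
      expect_equal(pbr$slope, or$slope)
      expect_equal(pbr$intercept, or$intercept)
      expect_gte(pbr$slope, pbr$slope_ci[1])
      expect_lte(pbr$slope, pbr$slope_ci[2])
    }
  })
})

test_that("Passing-Bablok is scale-equivariant and axis-swap consistent", {
  marrowdiff:::with_local_seed(43, {
    x <- runif(25, 10, 90)
    y <- 1.1 * x - 2 + rnorm(25)
  })
  pb <- suppressWarnings(passing_bablok(x, y))
  pb_scaled <- suppressWarnings(passing_bablok(x, 3 * y))
  expect_equal(pb_scaled$slope, 3 * pb$slope, tolerance = 1e-12)
  pb_swap <- suppressWarnings(passing_bablok(y, x))
  expect_equal(pb_swap$slope, 1 / pb$slope, tolerance = 5e-3)
  expect_error(passing_bablok(rep(2, 10), 1:10), "identical")
})

test_that("the cusum test flags curvature but passes straight data", {
  x <- seq(1, 20, length.out = 60)
  curved <- 0.05 * x^2 + x
  pb_c <- passing_bablok(x, curved)
  expect_false(pb_c$linear)
  marrowdiff:::with_local_seed(47, {
    straight <- 2 * x + 1 + rnorm(60, sd = 0.3)
  })
  pb_s <- passing_bablok(x, straight)
  expect_true(pb_s$linear)
})

test_that("Bland-Altman limits match hand arithmetic and antisymmetry", {
  x <- c(11, 12, 13, 14, 15); y <- rep(10, 5)   # d = 1..5
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 3)
  expect_equal(ba$sd_diff, sqrt(2.5))
  expect_equal(ba$loa_lower, 3 - 1.96 * sqrt(2.5))
  expect_equal(ba$loa_upper, 3 + 1.96 * sqrt(2.5))
  swap <- bland_altman(y, x)
  expect_equal(swap$bias, -3)
  expect_equal(swap$loa_lower, -ba$loa_upper)
  expect_equal(swap$loa_upper, -ba$loa_lower)

  same <- bland_altman(1:5, 1:5)
  expect_equal(same$bias, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))
  expect_error(bland_altman(1, 1), "at least 2")
})
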