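test_that("difference summary reproduces the printed percent differences", {
  # mean differences of 2.4, -3.0 and 1.3 kg against a 58.2 kg reference
  # mean print as 4.1%, 5.2% and 2.2%
  ref <- rep(58.2, 4)
  for (case in list(c(2.4, 4.1), c(-3.0, 5.2), c(1.3, 2.2))) {
    ds <- difference_summary(ref + case[1], ref)
    expect_equal(round(ds$pct_diff, 1), case[2])
    expect_equal(ds$mean_diff, case[1], tolerance = 1e-12)
  }
  ds0 <- difference_summary(ref, ref)
  expect_equal(unlist(ds0), c(mean_diff = 0, sd_diff = 0, pct_diff = 0))
  expect_error(difference_summary(1:3, 1:4), "equal length")
})

test_that("paired comparison handles identity, shift, and transform gating", {
  x <- rnorm(50, 58, 6) + 30
  id <- paired_comparison(x, x)
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)

  set.seed(7)
  ref <- rnorm(50, 58, 6)
  pred <- ref + 5 + rnorm(50, 0, 1)
  pc <- paired_comparison(pred, ref)
  expect_lt(pc$p_value, 0.001)
  expect_equal(pc$statistic, 35, tolerance = 0.2) # t ~ 5/(1/sqrt(50))

  # heavily skewed series trips the normality gate and sets the flag
  set.seed(8)
  skew <- exp(rnorm(100, 4, 0.6))
  pcs <- paired_comparison(skew * 1.02, skew)
  expect_true(pcs$log_transformed)
  # and the transform refuses non-positive values
  skew2 <- skew
  skew2[1] <- -skew2[1]
  expect_error(paired_comparison(skew2 * 1.02, skew2), "non-positive")
})

test_that("Lin's CCC satisfies its defining identities", {
  x <- c(55.1, 58.3, 61.2, 57.7, 60.4, 54.9, 59.8)
  res <- lin_ccc(x, x)
  expect_equal(res$ccc, 1)
  expect_equal(res$precision_rho, 1)
  expect_equal(res$accuracy_cb, 1)

  shifted <- lin_ccc(x + 2.5, x)
  expect_equal(shifted$precision_rho, 1)
  expect_lt(shifted$accuracy_cb, 1)
  expect_equal(shifted$ccc, shifted$accuracy_cb)

  set.seed(12)
  for (i in 1:25) {
    a <- rnorm(15, 58, 6)
    b <- a + rnorm(15, 1, 2)
    r1 <- lin_ccc(a, b)
    r2 <- lin_ccc(b, a)
    expect_equal(r1$ccc, r2$ccc, tolerance = 1e-12) # symmetric
    expect_equal(r1$ccc, r1$precision_rho * r1$accuracy_cb, tolerance = 1e-12)
    expect_lte(abs(r1$ccc), abs(r1$precision_rho))
  }
  expect_error(lin_ccc(rep(1, 5), rnorm(5)), "variance")
})

test_that("pure error matches brute force and its moment identity", {
  x <- c(59, 57, 60)
  y <- c(58, 58, 58)
  expect_equal(pure_error(x, y), sqrt(6 / 3), tolerance = 1e-12)
  expect_equal(pure_error(y, y), 0)
  expect_equal(pure_error(y + 2, y), 2)

  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    a <- rnorm(n, 58, 6)
    b <- a + rnorm(n, 0.5, 2)
    pe <- pure_error(a, b)
    ds <- difference_summary(a, b)
    # PE^2 = mean_diff^2 + sd_diff^2 * (n-1)/n
    expect_equal(pe^2, ds$mean_diff^2 + ds$sd_diff^2 * (n - 1) / n,
                 tolerance = 1e-12)
  }
})

test_that("calibration fit matches the normal-equations oracle", {
  pred <- c(55, 60, 65, 58, 62, 57, 61, 59, 63, 56)
  ref <- 2 * pred + 1
  cal <- suppressWarnings(calibration_fit(pred, ref)) # exact fit by design
  expect_equal(cal$r2_adj, 1, tolerance = 1e-12)
  expect_equal(cal$see, 0, tolerance = 1e-10)

  set.seed(33)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    a <- rnorm(n, 58, 6)
    b <- 0.9 * a + rnorm(n, 5, 2)
    cal <- calibration_fit(a, b)
    ora <- oracle_ols(a, b)
    expect_equal(cal$r2_adj, ora$r2_adj, tolerance = 1e-10)
    expect_equal(cal$see, ora$see, tolerance = 1e-10)
  }

  # residual SD estimates the true noise SD at large n
  set.seed(34)
  a <- rnorm(264, 58.2, 6.5)
  b <- a + rnorm(264, 0, 2.2)
  expect_gt(calibration_fit(a, b)$see, 1.9)
  expect_lt(calibration_fit(a, b)$see, 2.5)

  expect_error(calibration_fit(rep(2, 5), rnorm(5)), "variance")
})

test_that("Bland-Altman limits and trend behave as constructed", {
  # bias 0.6, sd 3.2 -> limits 0.6 +/- 1.96*3.2
  set.seed(44)
  d <- rnorm(500)
  d <- (d - mean(d)) / sd(d) * 3.2 + 0.6 # exact sample moments
  ref <- rnorm(500, 58.2, 6.5)
  ba <- bland_altman(ref + d, ref)
  expect_equal(ba$bias, 0.6, tolerance = 1e-10)
  expect_equal(ba$loa_lower, -5.672, tolerance = 1e-6)
  expect_equal(ba$loa_upper, 6.872, tolerance = 1e-6)

  x <- c(55, 58, 61, 57)
  ident <- bland_altman(x, x)
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_lower, ident$loa_upper), c(0, 0))
  expect_equal(ident$trend_r, 0)

  # planted proportional bias: differences grow with the mean
  set.seed(45)
  ref <- rnorm(200, 58.2, 6.5)
  pred <- ref + 0.15 * (ref - 58.2) + rnorm(200, 0, 1)
  expect_lt(bland_altman(pred, ref)$trend_p, 0.05)
})

test_that("technical error of measurement has its closed forms and scaling", {
  x <- c(480.2, 463.1, 502.8)
  expect_equal(technical_error(x, x)$tem, 0)
  single <- technical_error(500, 501)
  expect_equal(single$tem, sqrt(1 / 2), tolerance = 1e-12)

  set.seed(55)
  a <- rnorm(23, 480, 49)
  b <- a + rnorm(23, 0, 5)
  t1 <- technical_error(a, b)
  t3 <- technical_error(3 * a, 3 * b)
  expect_equal(t3$tem, 3 * t1$tem, tolerance = 1e-12)
  expect_equal(t3$cv_pct, t1$cv_pct, tolerance = 1e-12) # scale-free
})

test_that("a full report satisfies the cross-statistic identities", {
  set.seed(66)
  ref <- rnorm(120, 58.2, 6.5)
  pred <- ref + rnorm(120, 1.2, 2.4)
  rep1 <- build_report("demo", pred, ref)
  expect_equal(rep1$ccc, rep1$precision_rho * rep1$accuracy_cb,
               tolerance = 1e-12)
  expect_equal(rep1$loa_upper - rep1$loa_lower, 2 * 1.96 * rep1$sd_diff,
               tolerance = 1e-12)
  expect_gte(rep1$pure_error, abs(rep1$mean_diff))
  expect_equal(rep1$n, 120)

  ident <- suppressWarnings(build_report("self", ref, ref)) # exact fit
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$ccc, 1)
  expect_equal(ident$pure_error, 0)

  tab <- agreement_table(list(rep1, ident))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$ccc, tab$precision_rho * tab$accuracy_cb,
               tolerance = 1e-12)
  rtab <- agreement_table(rep1, round = TRUE)
  expect_equal(rtab$mean_diff, round(rep1$mean_diff, 1))
})

test_that("validating a cohort against the catalogue yields one report per equation", {
  cohort <- generate_cohort(cohort_config(n = 60), seed = 9)
  reports <- validate_equations(cohort)
  expect_length(reports, 9)
  expect_named(reports, names(equation_catalogue()))
  one <- validate_equations(cohort, "eq3")
  expect_length(one, 1)
  tab <- agreement_table(reports)
  expect_equal(nrow(tab), 9)
  # report columns audit: ccc always equals rho * C_b
  expect_equal(tab$ccc, tab$precision_rho * tab$accuracy_cb, tolerance = 1e-12)

  no_dxa <- cohort
  no_dxa$bmc_kg <- NULL
  no_dxa$lst_kg <- NULL
  expect_error(validate_equations(no_dxa), "DXA")
})
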