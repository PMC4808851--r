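test_that("the default configuration encodes the study conditions", {
  cfg <- cohort_config()
  # recruitment flow: 946 interested - 507 unavailable - 43 no consent
  expect_equal(cfg$n, 946 - 507 - 43)
  expect_equal(cfg$stature_mean, 175.8)
  expect_equal(cfg$ffm_mean, 58.2)
  expect_equal(cfg$fmpct_mean, 17.2)
  expect_equal(cfg$true_coef_weight, 0.508)
  expect_equal(cfg$true_coef_logindex, 39.234)
  expect_equal(cfg$true_intercept, -48.263)
  expect_equal(cfg$model_noise_sd, 2.2)
  expect_equal(cfg$bmc_fraction, 3.0 / 58.2)

  expect_error(cohort_config(stature_sd = 0), "positive")
  expect_error(cohort_config(age_min = 25), "bracket")
  expect_error(cohort_config(stature_ffm_corr = 1), "< 1")
  expect_error(cohort_config(fmpct_max = 120), "< 100")
})

test_that("generated cohorts satisfy every subject-record invariant", {
  cfg <- cohort_config(n = 396)
  for (s in c(1, 17)) {
    co <- generate_cohort(cfg, seed = s)
    expect_equal(nrow(co), 396)
    # exact mass closure by construction
    expect_equal(co$fm_kg + co$bmc_kg + co$lst_kg, co$weight_kg,
                 tolerance = 1e-12)
    expect_true(all(co$fm_kg > 0))
    expect_true(all(co$resistance_ohm >= 250 & co$resistance_ohm <= 900))
    expect_true(all(co$stature_cm >= cfg$stature_min &
                      co$stature_cm <= cfg$stature_max))
    expect_true(all(co$age >= cfg$age_min & co$age <= cfg$age_max))
    expect_true(all(co$reactance_ohm >= cfg$reactance_min &
                      co$reactance_ohm <= cfg$reactance_max))
    expect_true(all(co$sex == 1))
    expect_gte(attr(co, "redraw_count"), 0)
  }
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg <- cohort_config(n = 50)
  a <- generate_cohort(cfg, seed = 30)
  b <- generate_cohort(cfg, seed = 30)
  c <- generate_cohort(cfg, seed = 31)
  expect_identical(a$resistance_ohm, b$resistance_ohm)
  expect_false(identical(a$resistance_ohm, c$resistance_ohm))
})

test_that("sample moments recover the configured study conditions", {
  cfg <- cohort_config()
  n <- cfg$n
  se <- function(sd) sd / sqrt(n)
  # the generator's target for a truncated channel is the truncated-normal
  # mean; an asymmetric range (age's 17-24 around 19.2) shifts it away
  # from the nominal centre, so that shift is part of the target
  trunc_mean <- function(m, s, lo, hi) {
    a <- (lo - m) / s
    b <- (hi - m) / s
    m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  for (s in c(8, 21, 35)) {
    d <- derive_measures(generate_cohort(cfg, seed = s))
    expect_lt(abs(mean(d$stature_cm) -
                    trunc_mean(175.8, 6.4, cfg$stature_min, cfg$stature_max)),
              3 * se(6.4))
    expect_lt(abs(mean(d$age) -
                    trunc_mean(19.2, 1.8, cfg$age_min, cfg$age_max)),
              3 * se(1.8))
    expect_lt(abs(mean(d$reactance_ohm) -
                    trunc_mean(62.4, 7.0, cfg$reactance_min, cfg$reactance_max)),
              3 * se(7.0))
    # FFM mean within ~2 SE of the target marginal
    expect_lt(abs(mean(d$ffm_dxa_kg) - 58.2), 0.7)
    # FM% and weight are derived; allow the truncation-induced drift
    expect_lt(abs(mean(d$fm_kg / d$weight_kg * 100) - 17.2), 1.0)
    expect_lt(abs(mean(d$weight_kg) - 70.0), 1.5)
    # resistance is emergent from the model inversion
    expect_gt(mean(d$resistance_ohm), 440)
    expect_lt(mean(d$resistance_ohm), 540)
    # the predictor coupling the construction guarantees
    expect_gt(cor(d$weight_kg, d$ffm_dxa_kg), 0.80)
  }
})

test_that("a noise-free generator makes the true model exactly identifiable", {
  co <- generate_cohort(cohort_config(n = 60, model_noise_sd = 1e-12), seed = 2)
  d <- derive_measures(co)
  fit <- lm(ffm_dxa_kg ~ weight_kg + log_impedance_index, data = d)
  expect_equal(unname(coef(fit)),
               c(-48.263, 0.508, 39.234), tolerance = 1e-6)
})

test_that("retest replicates carry the configured technical error", {
  cohort <- generate_cohort(cohort_config(n = 100), seed = 5)
  rt <- generate_retest(cohort, retest_config(), seed = 9)
  expect_equal(nrow(rt), 23 * 5 * 2) # 23 pairs x 5 channels x 2 replicates
  expect_setequal(unique(rt$channel),
                  c("resistance_ohm", "reactance_ohm", "fm_kg", "bmc_kg", "lst_kg"))

  rel <- reliability_summary(rt)
  expect_equal(nrow(rel), 5)
  expect_equal(rel$n_pairs, rep(23, 5))
  # estimated resistance TEM within the chi-squared sampling interval
  # around the configured 3.54 ohm at n = 23
  tem_r <- rel$tem[rel$channel == "resistance_ohm"]
  expect_gt(tem_r, 2.4)
  expect_lt(tem_r, 4.7)

  # zero TEM collapses the replicates exactly
  rt0 <- generate_retest(cohort, retest_config(
    tem_resistance = 0, tem_reactance = 0, tem_fm = 0, tem_bmc = 0,
    tem_lst = 0
  ), seed = 9)
  rel0 <- reliability_summary(rt0)
  expect_equal(rel0$tem, rep(0, 5))

  expect_error(retest_config(tem_fm = -1), ">= 0")
  expect_error(generate_retest(cohort[1:5, ], retest_config(), seed = 1),
               "exceeds")
})

test_that("the TEM estimator is unbiased for the configured value", {
  # replicate noise SD = TEM per replicate => within-pair difference SD
  # TEM*sqrt(2) => sqrt(sum(d^2)/2n) estimates TEM; average over seeds
  cohort <- generate_cohort(cohort_config(n = 100), seed = 5)
  cfgr <- retest_config(n_pairs = 50)
  tems <- vapply(1:30, function(s) {
    rt <- generate_retest(cohort, cfgr, seed = s)
    rel <- reliability_summary(rt)
    rel$tem[rel$channel == "resistance_ohm"]
  }, numeric(1))
  expect_equal(mean(tems), 3.54, tolerance = 0.05)
})

test_that("cohort CSV round-trips to high precision and validates", {
  co <- generate_cohort(cohort_config(n = 40), seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  for (col in setdiff(names(co), "subject_id")) {
    expect_equal(back[[col]], co[[col]], tolerance = 1e-9)
  }
  expect_identical(back$subject_id, co$subject_id)

  # same seed twice gives byte-identical files
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cohort_config(n = 40), seed = 12), path2)
  expect_identical(readLines(path), readLines(path2))

  bad <- co
  bad$lst_kg[3] <- bad$lst_kg[3] + 10 # breaks mass closure
  expect_error(validate_cohort(bad), "disagree")
})

test_that("config JSON round-trips", {
  cfg <- cohort_config(n = 25, stature_ffm_corr = 0.55)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(cfg))
})
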