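#' Summary of prediction-reference differences
#'
#' @param pred Predicted values (kg).
#' @param ref Reference values (kg).
#' @return List with `mean_diff` (mean of pred - ref), `sd_diff` (sample SD,
#'   n-1 divisor), and `pct_diff` (|mean_diff| as a percent of the reference
#'   mean).
#' @export
difference_summary <- function(pred, ref) {
  check_paired(pred, ref, min_n = 2)
  d <- pred - ref
  list(
    mean_diff = mean(d),
    sd_diff = stats::sd(d),
    pct_diff = abs(mean(d)) / mean(ref) * 100
  )
}

#' Paired comparison with conditional log transform
#'
#' Paired Student's t-test of predicted against reference values. Each
#' series is first screened for normality (Shapiro-Wilk at
#' `normality_alpha`); if either fails, both series are log10-transformed
#' before the test and the returned flag is set. The transform requires
#' strictly positive values. Descriptive statistics elsewhere stay on the
#' kg scale; only the test moves to the log scale.
#'
#' Degenerate inputs are handled explicitly: identical series give
#' statistic 0 and p = 1; a constant non-zero difference gives p = 0.
#' Zero-variance series are treated as normal for the screening step.
#' Shapiro-Wilk is defined for n in 3..5000; beyond 5000 an evenly spaced
#' subsample of 5000 values (in stored order) is screened.
#'
#' @param pred,ref Paired series, length >= 3.
#' @param normality_alpha Significance level of the normality screen.
#' @return List with `statistic` (t), `p_value` (two-sided),
#'   `log_transformed` (logical), `df`.
#' @export
paired_comparison <- function(pred, ref, normality_alpha = 0.05) {
  check_paired(pred, ref, min_n = 3)
  normal_p <- function(x) {
    if (stats::sd(x) == 0) return(1)
    if (length(x) > 5000) x <- x[round(seq(1, length(x), length.out = 5000))]
    stats::shapiro.test(x)$p.value
  }
  log_transformed <- normal_p(pred) < normality_alpha ||
    normal_p(ref) < normality_alpha
  if (log_transformed) {
    if (any(pred <= 0) || any(ref <= 0)) {
      stop("log10 transform required by non-normality, but the series ",
           "contain non-positive values", call. = FALSE)
    }
    pred <- log10(pred)
    ref <- log10(ref)
  }
  d <- pred - ref
  n <- length(d)
  # a (numerically) constant difference has no within-pair variability:
  # the t statistic degenerates to 0 or +/-Inf
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + stats::sd(ref) * 1e-4)) {
    if (abs(mean(d)) <= 1e-12 * (1 + mean(abs(ref)))) {
      return(list(statistic = 0, p_value = 1, log_transformed = log_transformed,
                  df = n - 1))
    }
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0,
                log_transformed = log_transformed, df = n - 1))
  }
  tt <- stats::t.test(pred, ref, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       log_transformed = log_transformed, df = unname(tt$parameter))
}

#' Lin's concordance correlation coefficient
#'
#' Concordance between two measurement methods on the same subjects:
#' \deqn{CCC = \frac{2\,cov(x,y)}{var(x) + var(y) + (\bar x - \bar y)^2}}
#' decomposed into precision (the Pearson correlation, rho) and accuracy
#' (the bias-correction factor, C_b = CCC / rho), so that
#' CCC = rho * C_b exactly. Sample moments use the n-1 divisor throughout,
#' which cancels between numerator and denominator except in the squared
#' mean-difference term, where the conventional sample-moment form is kept.
#'
#' @param pred,ref Paired series, length >= 2, each with non-zero variance.
#' @return List with `ccc`, `precision_rho`, `accuracy_cb`.
#' @examples
#' x <- rnorm(50, 58, 6); lin_ccc(x + 1, x)
#' @export
lin_ccc <- function(pred, ref) {
  check_paired(pred, ref, min_n = 2)
  if (stats::sd(pred) == 0 || stats::sd(ref) == 0) {
    stop("lin_ccc requires non-zero variance in both series", call. = FALSE)
  }
  ccc <- 2 * stats::cov(pred, ref) /
    (stats::var(pred) + stats::var(ref) + (mean(pred) - mean(ref))^2)
  rho <- stats::cor(pred, ref)
  list(ccc = ccc, precision_rho = rho, accuracy_cb = ccc / rho)
}

#' Pure error
#'
#' Root mean squared deviation between predicted and reference values with
#' divisor n: \eqn{PE = \sqrt{\sum(\hat y - y)^2 / n}}. Unlike the SD of
#' the differences it does not remove the mean, so
#' PE^2 = mean_diff^2 + sd_diff^2 (n-1)/n.
#'
#' @param pred,ref Paired series, length >= 1.
#' @return Pure error in the units of the inputs.
#' @export
pure_error <- function(pred, ref) {
  check_paired(pred, ref, min_n = 1)
  sqrt(mean((pred - ref)^2))
}

#' Calibration regression fit quality
#'
#' Ordinary least squares of the reference on the prediction. Reports the
#' adjusted coefficient of determination and the standard error of
#' estimate (residual SD, n-2 divisor).
#'
#' @param pred,ref Paired series, length >= 3; `pred` with non-zero
#'   variance.
#' @return List with `r2_adj` and `see`.
#' @export
calibration_fit <- function(pred, ref) {
  check_paired(pred, ref, min_n = 3)
  if (stats::sd(pred) == 0) {
    stop("calibration_fit requires non-zero predictor variance", call. = FALSE)
  }
  fit <- stats::lm(ref ~ pred)
  s <- summary(fit)
  list(r2_adj = s$adj.r.squared, see = s$sigma)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of pred - ref), 95% limits of agreement
#' (bias +/- 1.96 * SD of the differences), and the proportional-bias
#' trend test: Pearson correlation of the per-subject differences against
#' the per-subject means (pred + ref)/2. Identical series return a zero
#' trend with p = 1 (no trend is detectable without variance).
#'
#' @param pred,ref Paired series, length >= 3.
#' @return List with `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `trend_r`, `trend_p`.
#' @export
bland_altman <- function(pred, ref) {
  check_paired(pred, ref, min_n = 3)
  d <- pred - ref
  m <- (pred + ref) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  if (sd_diff == 0 || stats::sd(m) == 0) {
    trend_r <- 0
    trend_p <- 1
  } else {
    ct <- stats::cor.test(d, m)
    trend_r <- unname(ct$estimate)
    trend_p <- ct$p.value
  }
  list(
    bias = bias, sd_diff = sd_diff,
    loa_lower = bias - 1.96 * sd_diff, loa_upper = bias + 1.96 * sd_diff,
    trend_r = trend_r, trend_p = trend_p
  )
}

#' Technical error of measurement and CV% from test-retest pairs
#'
#' TEM = sqrt(sum(d^2) / (2n)) over n test-retest pairs, where d is the
#' within-pair difference. The companion coefficient of variation is the
#' within-subject SD (equal to the TEM) expressed as a percent of the
#' grand mean of all 2n measurements.
#'
#' @param test,retest Paired replicate measurements, length >= 1.
#' @return List with `tem` (measurement units), `cv_pct` (%), `n_pairs`.
#' @examples
#' technical_error(c(480, 475), c(481, 474))
#' @export
technical_error <- function(test, retest) {
  check_paired(test, retest, min_n = 1)
  d <- test - retest
  n <- length(d)
  tem <- sqrt(sum(d^2) / (2 * n))
  grand_mean <- mean(c(test, retest))
  list(tem = tem, cv_pct = tem / grand_mean * 100, n_pairs = n)
}

#' Full agreement report for one prediction method
#'
#' Assembles every validation statistic for one prediction series against
#' the reference: descriptives of the predictions, difference summary,
#' paired comparison (with conditional log transform), Lin's CCC
#' decomposition, calibration R2/SEE, pure error, and Bland-Altman limits
#' with the trend test. All values are stored at full precision; rounding
#' happens only in [agreement_table()].
#'
#' @param equation_id Label for the method under test.
#' @param pred Predicted FFM series (kg).
#' @param ref Reference FFM series (kg), same length.
#' @param normality_alpha Passed to [paired_comparison()].
#' @return An object of class `agreement_report` (a named list; see
#'   [agreement_table()] for the tabular layout).
#' @export
build_report <- function(equation_id, pred, ref, normality_alpha = 0.05) {
  check_paired(pred, ref, min_n = 3)
  ds <- difference_summary(pred, ref)
  pc <- paired_comparison(pred, ref, normality_alpha)
  ccc <- lin_ccc(pred, ref)
  cal <- calibration_fit(pred, ref)
  ba <- bland_altman(pred, ref)
  structure(
    list(
      equation_id = equation_id, n = length(pred),
      mean_pred = mean(pred), sd_pred = stats::sd(pred),
      min_pred = min(pred), max_pred = max(pred),
      mean_diff = ds$mean_diff, sd_diff = ds$sd_diff, pct_diff = ds$pct_diff,
      paired_t = pc$statistic, paired_p = pc$p_value,
      log_transformed = pc$log_transformed,
      ccc = ccc$ccc, precision_rho = ccc$precision_rho,
      accuracy_cb = ccc$accuracy_cb,
      r2_adj = cal$r2_adj, see = cal$see,
      pure_error = pure_error(pred, ref),
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      trend_r = ba$trend_r, trend_p = ba$trend_p
    ),
    class = "agreement_report"
  )
}

#' Tabulate agreement reports
#'
#' Lays out one row per report in the conventional validation-table shape:
#' prediction mean +/- SD and range, difference mean +/- SD and %, a
#' significance flag for the paired test, the CCC decomposition, adjusted
#' R2, SEE and pure error, the limits of agreement and the trend test.
#'
#' @param reports A single `agreement_report` or a list of them.
#' @param round Apply report-style rounding (kg and % to 1 dp, rho and C_b
#'   to 4 dp, CCC and R2 to 2 dp, p to 3 dp). Default FALSE: full
#'   precision.
#' @param sig_alpha Threshold for the significance flag column.
#' @return A tibble, one row per report.
#' @export
agreement_table <- function(reports, round = FALSE, sig_alpha = 0.05) {
  if (inherits(reports, "agreement_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    tibble::tibble(
      equation_id = r$equation_id, n = r$n,
      mean_pred = r$mean_pred, sd_pred = r$sd_pred,
      min_pred = r$min_pred, max_pred = r$max_pred,
      mean_diff = r$mean_diff, sd_diff = r$sd_diff, pct_diff = r$pct_diff,
      paired_p = r$paired_p, significant = r$paired_p < sig_alpha,
      log_transformed = r$log_transformed,
      ccc = r$ccc, precision_rho = r$precision_rho,
      accuracy_cb = r$accuracy_cb, r2_adj = r$r2_adj, see = r$see,
      pure_error = r$pure_error,
      loa_lower = r$loa_lower, loa_upper = r$loa_upper,
      trend_r = r$trend_r, trend_p = r$trend_p
    )
  })
  out <- do.call(rbind, rows)
  if (round) {
    kg <- c("mean_pred", "sd_pred", "min_pred", "max_pred", "mean_diff",
            "sd_diff", "pct_diff", "see", "pure_error", "loa_lower",
            "loa_upper")
    out[kg] <- lapply(out[kg], function(x) round(x, 1))
    out[c("precision_rho", "accuracy_cb")] <-
      lapply(out[c("precision_rho", "accuracy_cb")], function(x) round(x, 4))
    out[c("ccc", "r2_adj", "trend_r")] <-
      lapply(out[c("ccc", "r2_adj", "trend_r")], function(x) round(x, 2))
    out[c("paired_p", "trend_p")] <-
      lapply(out[c("paired_p", "trend_p")], function(x) round(x, 3))
  }
  out
}

#' Validate catalogue equations on a cohort
#'
#' Runs every selected catalogue equation on the cohort and builds a full
#' agreement report against the DXA reference (BMC + LST).
#'
#' @param cohort Cohort data frame with DXA columns.
#' @param equations `"all"` (default) or a character vector of equation
#'   ids.
#' @return A named list of `agreement_report` objects; tabulate with
#'   [agreement_table()].
#' @export
validate_equations <- function(cohort, equations = "all") {
  cohort <- derive_measures(cohort)
  if (all(is.na(cohort$ffm_dxa_kg))) {
    stop("cohort has no DXA reference (bmc_kg/lst_kg); cannot validate",
         call. = FALSE)
  }
  ids <- if (identical(equations, "all")) names(equation_catalogue()) else equations
  reports <- lapply(ids, function(id) {
    build_report(id, predict_ffm(cohort, id), cohort$ffm_dxa_kg)
  })
  names(reports) <- ids
  reports
}

#' Bland-Altman plot
#'
#' Differences against means with the bias line, the 95% limits of
#' agreement, and the proportional-bias trend line.
#'
#' @param pred,ref Paired series.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pred, ref, title = "Bland-Altman agreement") {
  ba <- bland_altman(pred, ref)
  df <- data.frame(mean = (pred + ref) / 2, diff = pred - ref)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ba$bias, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey50") +
    ggplot2::labs(
      title = title,
      subtitle = sprintf("bias %.1f kg, 95%% LoA [%.1f, %.1f], trend r = %.2f (p = %.3f)",
                         ba$bias, ba$loa_lower, ba$loa_upper,
                         ba$trend_r, ba$trend_p),
      x = "Mean of methods (kg)", y = "Difference, prediction - reference (kg)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report: %s (n = %d)\n", x$equation_id, x$n))
  cat(sprintf("  prediction  %.1f +/- %.1f kg  [%.1f, %.1f]\n",
              x$mean_pred, x$sd_pred, x$min_pred, x$max_pred))
  cat(sprintf("  difference  %.1f +/- %.1f kg (%.1f%%), paired p = %.3g%s\n",
              x$mean_diff, x$sd_diff, x$pct_diff, x$paired_p,
              if (x$log_transformed) " (log10 scale)" else ""))
  cat(sprintf("  CCC %.2f (rho %.4f, C_b %.4f); adj R2 %.2f, SEE %.1f kg, PE %.1f kg\n",
              x$ccc, x$precision_rho, x$accuracy_cb, x$r2_adj, x$see,
              x$pure_error))
  cat(sprintf("  LoA [%.1f, %.1f] kg; trend r = %.2f (p = %.3g)\n",
              x$loa_lower, x$loa_upper, x$trend_r, x$trend_p))
  invisible(x)
}

# internal -------------------------------------------------------------

check_paired <- function(x, y, min_n) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("paired series must be numeric", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("paired series must have equal length", call. = FALSE)
  }
  if (length(x) < min_n) {
    stop(sprintf("paired series must have length >= %d", min_n), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("paired series must be finite", call. = FALSE)
  }
  invisible(NULL)
}
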