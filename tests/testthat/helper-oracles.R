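# Brute-force oracles, kept deliberately naive and independent of the
# package's implementation paths: explicit elementwise sums and
# normal-equations solves only.

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  sxx <- sum((x - mx)^2) / (n - 1)
  syy <- sum((y - my)^2) / (n - 1)
  ccc <- 2 * sxy / (sxx + syy + (mx - my)^2)
  rho <- sxy / sqrt(sxx * syy)
  list(ccc = ccc, rho = rho, cb = ccc / rho)
}

oracle_pure_error <- function(pred, ref) {
  total <- 0
  for (i in seq_along(pred)) total <- total + (pred[i] - ref[i])^2
  sqrt(total / length(pred))
}

# OLS of y on x via the 2x2 normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(
    intercept = beta[1], slope = beta[2],
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
    see = sqrt(rss / (n - 2))
  )
}

oracle_bland_altman <- function(pred, ref) {
  d <- pred - ref
  m <- (pred + ref) / 2
  n <- length(d)
  bias <- sum(d) / n
  sd_d <- sqrt(sum((d - bias)^2) / (n - 1))
  r <- sum((d - bias) * (m - mean(m))) /
    sqrt(sum((d - bias)^2) * sum((m - mean(m))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(bias = bias, lower = bias - 1.96 * sd_d, upper = bias + 1.96 * sd_d,
       trend_r = r, trend_p = p)
}

# small cohort with hand-set values for catalogue tests
fixed_cohort <- function() {
  tibble::tibble(
    subject_id = c("A", "B", "C", "D", "E"),
    age = c(18, 19, 20, 21, 22),
    sex = 1,
    weight_kg = c(60, 65, 70, 75, 80),
    stature_cm = c(168, 172, 176, 180, 184),
    resistance_ohm = c(520, 500, 480, 460, 440),
    reactance_ohm = c(58, 60, 62, 64, 66),
    fm_kg = c(10, 11, 12, 13, 14),
    bmc_kg = c(2.6, 2.8, 3.0, 3.2, 3.4),
    lst_kg = c(47.4, 51.2, 55.0, 58.8, 62.6)
  )
}
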