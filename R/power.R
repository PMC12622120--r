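#' Closed-form power of the marginal (ATE) Wald test
#'
#' Working model: the tested variant enters as a binary contrast class
#' with population frequency `f1`, so the marginal-effect estimator has
#' `SE = sigma / sqrt(n f1 (1 - f1))` and the two-sided level-`alpha` Wald
#' test has power
#' `pnorm(-z_{1-alpha/2} + |effect|/SE) + pnorm(-z_{1-alpha/2} - |effect|/SE)`.
#'
#' @param effect True marginal effect (beta), trait units; alternatively
#'   supply `effect_se`, the effect already expressed in standard-error
#'   units, and omit `f1`, `n`, `sigma`.
#' @param f1 Contrast-class frequency of the tested variant, in (0, 1).
#' @param n Sample size.
#' @param sigma Residual standard deviation of the trait.
#' @param alpha Two-sided test level (default 0.05).
#' @param effect_se Optional effect in SE units (overrides the rest).
#' @return Rejection probability in \[0, 1\].
#' @export
power_ate <- function(effect, f1, n, sigma = 1, alpha = 0.05,
                      effect_se = NULL) {
  z <- if (!is.null(effect_se)) abs(effect_se) else {
    stopifnot(f1 > 0, f1 < 1, n >= 1, sigma > 0)
    abs(effect) / (sigma / sqrt(n * f1 * (1 - f1)))
  }
  za <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-za + z) + stats::pnorm(-za - z)
}

#' Closed-form power of the interaction (AIE) Wald test
#'
#' As [power_ate()], with the interaction estimator's variance inflated by
#' the second variant's contrast-class frequency:
#' `SE = sigma / sqrt(n f1 (1 - f1) f2 (1 - f2))`. Since
#' `f2 (1 - f2) <= 1/4`, detecting an interaction of the same magnitude as
#' a marginal effect always costs power, with the gap smallest at
#' `f2 = 0.5`.
#'
#' @inheritParams power_ate
#' @param f2 Contrast-class frequency of the interacting variant.
#' @return Rejection probability in \[0, 1\].
#' @export
power_aie <- function(effect, f1, f2, n, sigma = 1, alpha = 0.05,
                      effect_se = NULL) {
  z <- if (!is.null(effect_se)) abs(effect_se) else {
    stopifnot(f1 > 0, f1 < 1, f2 > 0, f2 < 1, n >= 1, sigma > 0)
    abs(effect) / (sigma / sqrt(n * f1 * (1 - f1) * f2 * (1 - f2)))
  }
  za <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-za + z) + stats::pnorm(-za - z)
}

#' Sample-size multiplier equalizing AIE and ATE power
#'
#' The factor `1 / (f2 (1 - f2))` by which the sample size must grow for
#' the interaction test to match the power of the equal-effect marginal
#' test at every power level: 4 at `f2 = 0.5`, about 21 at `f2 = 0.05`.
#'
#' @param f2 Contrast-class frequency of the interacting variant, in
#'   (0, 1).
#' @return The sample-size ratio (>= 4).
#' @export
parity_sample_ratio <- function(f2) {
  if (any(f2 <= 0 | f2 >= 1))
    stop("f2 must lie strictly inside (0, 1)", call. = FALSE)
  1 / (f2 * (1 - f2))
}

#' Effect-size multiplier equalizing AIE and ATE power at fixed n
#'
#' The square root of [parity_sample_ratio()]: the interaction effect must
#' be `1 / sqrt(f2 (1 - f2))` times as large as the marginal effect to be
#' detected with equal power at the same sample size — 2 at `f2 = 0.5`,
#' about 4.59 at `f2 = 0.05`.
#'
#' @inheritParams parity_sample_ratio
#' @return The effect-size ratio (>= 2).
#' @export
parity_effect_factor <- function(f2) sqrt(parity_sample_ratio(f2))

#' Monte-Carlo oracle for the closed-form power expressions
#'
#' Simulates cohorts with binary contrast variables at frequencies `f1`
#' (and `f2`), a trait equal to the tested effect times the relevant
#' regressor plus Gaussian noise, and returns the empirical rejection rate
#' of the ordinary-least-squares Wald test: the slope of `Y ~ V1` for the
#' marginal (ATE) arm, the interaction coefficient of the saturated
#' `Y ~ V1 * V2` fit for the AIE arm (computed via the equivalent
#' closed-form cell-mean contrasts for speed).
#'
#' @param effect True effect size (trait units).
#' @param f1,f2 Contrast-class frequencies; `f2` ignored for the ATE arm.
#' @param n Sample size per replicate.
#' @param sigma Residual standard deviation.
#' @param alpha Test level.
#' @param estimand `"ate"` or `"aie"`.
#' @param replicates Number of simulation replicates (>= 100).
#' @param seed RNG seed.
#' @return Empirical rejection rate; attribute `"mc_se"` gives its
#'   binomial Monte-Carlo standard error.
#' @export
mc_power_oracle <- function(effect, f1, f2 = NULL, n, sigma = 1,
                            alpha = 0.05, estimand = c("aie", "ate"),
                            replicates = 2000L, seed = 1L) {
  estimand <- match.arg(estimand)
  stopifnot(replicates >= 100)
  if (estimand == "aie" && is.null(f2))
    stop("f2 is required for the AIE arm", call. = FALSE)
  set.seed(seed)
  rej <- logical(replicates)
  for (r in seq_len(replicates)) {
    v1 <- stats::rbinom(n, 1L, f1)
    if (estimand == "ate") {
      y <- effect * v1 + stats::rnorm(n, 0, sigma)
      # simple-regression slope and its t-test
      vx <- stats::var(v1)
      if (vx == 0) { rej[r] <- FALSE ; next }
      b <- stats::cov(v1, y) / vx
      res <- y - mean(y) - b * (v1 - mean(v1))
      s2 <- sum(res^2) / (n - 2)
      se <- sqrt(s2 / ((n - 1) * vx))
      rej[r] <- abs(b / se) > stats::qt(1 - alpha / 2, n - 2)
    } else {
      v2 <- stats::rbinom(n, 1L, f2)
      y <- effect * v1 * v2 + stats::rnorm(n, 0, sigma)
      cell <- 2L * v1 + v2
      ncell <- tabulate(cell + 1L, 4L)
      if (any(ncell < 2L)) { rej[r] <- FALSE ; next }
      m <- vapply(0:3, function(cc) mean(y[cell == cc]), numeric(1))
      ss <- vapply(0:3, function(cc) sum((y[cell == cc] - m[cc + 1])^2),
                   numeric(1))
      s2 <- sum(ss) / (n - 4)
      g <- m[4] - m[3] - m[2] + m[1]          # y11 - y10 - y01 + y00
      se <- sqrt(s2 * sum(1 / ncell))
      rej[r] <- abs(g / se) > stats::qt(1 - alpha / 2, n - 4)
    }
  }
  rate <- mean(rej)
  attr(rate, "mc_se") <- sqrt(rate * (1 - rate) / replicates)
  rate
}

#' Tabulate closed-form power over a grid (figure-ready)
#'
#' @param effects Vector of effect sizes (trait units).
#' @param f1 Frequency of the tested variant's contrast class.
#' @param f2 Vector of interacting-variant frequencies.
#' @param n Sample size.
#' @param sigma Residual standard deviation.
#' @param alpha Test level.
#' @return data.frame of (effect, f1, f2, n, power_ate, power_aie).
#' @export
power_table <- function(effects, f1, f2, n, sigma = 1, alpha = 0.05) {
  grid <- expand.grid(effect = effects, f1 = f1, f2 = f2, n = n)
  grid$power_ate <- power_ate(grid$effect, grid$f1, grid$n, sigma, alpha)
  grid$power_aie <- power_aie(grid$effect, grid$f1, grid$f2, grid$n,
                              sigma, alpha)
  grid
}
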