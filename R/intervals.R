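# Confidence intervals: Wald intervals for the delta-method SEs plus the
# benchmark intervals the multinomial SEs are compared against (Feldt's
# F-based interval for alpha, Fisher-Z for correlations, normal-theory SEs
# for variance/SD/covariance) and the Agresti-Coull interval for coverage
# proportions.

new_ci <- function(lower, upper, level, method) {
  tibble::tibble(lower = lower, upper = upper, level = level, method = method)
}

#' Wald confidence interval
#'
#' `estimate +/- z * SE` with the standard normal deviate; for the mean a t
#' quantile with `df = N - 1` is used instead.  Wald intervals are not
#' range-preserving and are reported unclipped by default.
#'
#' @param est A one-row coefficient-estimate tibble (as returned by the
#'   `se_*()` functions), or a numeric estimate (then supply `se`).
#' @param level Confidence level in (0, 1).
#' @param se,df Standard error and t degrees of freedom when `est` is
#'   numeric; `df = NA` uses the normal deviate.
#' @param clip Optional length-2 numeric bounds to clip to (off by default).
#' @return A one-row tibble with `lower`, `upper`, `level`, `method`.
#' @export
wald_ci <- function(est, level = 0.95, se = NULL, df = NA_real_, clip = NULL) {
  if (is.data.frame(est)) {
    se <- est$se
    df <- if (identical(est$coefficient, "mean")) est$df else NA_real_
    est <- est$estimate
  }
  if (is.null(se) || is.na(se)) abort("SE undefined; cannot build a Wald interval.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  q <- if (is.na(df)) qnorm((1 + level) / 2) else qt((1 + level) / 2, df = df)
  lo <- est - q * se
  hi <- est + q * se
  if (!is.null(clip)) {
    lo <- max(lo, clip[1])
    hi <- min(hi, clip[2])
  }
  new_ci(lo, hi, level, if (is.na(df)) "wald-z" else "wald-t")
}

#' Feldt's F-based confidence interval for Cronbach's alpha
#'
#' Under an ANOVA model for the item scores, (1 - alpha)/(1 - alpha_hat)
#' follows an F distribution with N - 1 and (N - 1)(k - 1) degrees of
#' freedom; the interval applies the F quantiles to 1 - alpha_hat.
#'
#' @param alpha_hat Sample Cronbach's alpha (< 1).
#' @param N Number of respondents (>= 3).
#' @param k Number of items (>= 2).
#' @param level Confidence level.
#' @return A one-row tibble.
#' @export
feldt_ci <- function(alpha_hat, N, k, level = 0.95) {
  if (alpha_hat >= 1) abort("`alpha_hat` must be below 1.")
  if (N < 3 || k < 2) abort("Feldt interval needs N >= 3 and k >= 2.")
  df1 <- N - 1
  df2 <- (N - 1) * (k - 1)
  a <- (1 - level) / 2
  new_ci(
    lower = 1 - (1 - alpha_hat) * qf(1 - a, df1, df2),
    upper = 1 - (1 - alpha_hat) * qf(a, df1, df2),
    level = level, method = "feldt"
  )
}

#' Fisher-Z confidence interval for a correlation
#'
#' atanh(r) +/- z / sqrt(N - 3), back-transformed by tanh; range-preserving
#' within (-1, 1).
#'
#' @param r Sample correlation with |r| < 1.
#' @param N Sample size (>= 4).
#' @param level Confidence level.
#' @return A one-row tibble.
#' @export
fisher_z_ci <- function(r, N, level = 0.95) {
  if (abs(r) >= 1) abort("|r| must be below 1 for the Fisher-Z interval.")
  if (N < 4) abort("Fisher-Z interval needs N >= 4.")
  z <- qnorm((1 + level) / 2)
  half <- z / sqrt(N - 3)
  new_ci(tanh(atanh(r) - half), tanh(atanh(r) + half), level, "fisher-z")
}

#' Normal-theory benchmark standard errors
#'
#' The SEs the multinomial delta method is benchmarked against: for normally
#' distributed scores, `SE(s^2) = s^2 sqrt(2/(N-1))` and
#' `SE(s) = s / sqrt(2(N-1))`; under a bivariate normal distribution,
#' `SE(s_xy) = sqrt((s_x^2 s_y^2 + s_xy^2) / (N - 1))`.  These formulas are
#' exact under normality but their assumptions are typically too strong for
#' bounded discrete item scores.
#'
#' @param kind `"variance"`, `"sd"`, or `"covariance"`.
#' @param N Sample size.
#' @param s Sample SD (for `"variance"`/`"sd"`).
#' @param s_x,s_y,s_xy Sample SDs and covariance (for `"covariance"`).
#' @return A one-row tibble with method tag `benchmark-normal`.
#' @export
normal_theory_se <- function(kind = c("variance", "sd", "covariance"),
                             N, s = NULL, s_x = NULL, s_y = NULL, s_xy = NULL) {
  kind <- match.arg(kind)
  if (N < 2) abort("Need N >= 2.")
  out <- switch(kind,
    variance = {
      if (is.null(s)) abort("`s` required.")
      new_estimate("variance", "x", s^2, s^2 * sqrt(2 / (N - 1)),
                   method = "benchmark-normal", n_obs = N)
    },
    sd = {
      if (is.null(s) || s <= 0) abort("`s` must be positive.")
      new_estimate("sd", "x", s, s / sqrt(2 * (N - 1)),
                   method = "benchmark-normal", n_obs = N)
    },
    covariance = {
      if (is.null(s_x) || is.null(s_y) || is.null(s_xy)) {
        abort("`s_x`, `s_y`, `s_xy` required.")
      }
      new_estimate("covariance", "x,y", s_xy,
                   sqrt((s_x^2 * s_y^2 + s_xy^2) / (N - 1)),
                   method = "benchmark-normal", n_obs = N)
    }
  )
  out
}

#' Agresti-Coull interval for a binomial proportion
#'
#' With `z` the (1 + level)/2 normal quantile, the adjusted proportion is
#' `p~ = (x + z^2/2) / (n + z^2)` and the half-width
#' `z sqrt(p~ (1 - p~) / (n + z^2))`.  Used here to judge whether a
#' simulated coverage percentage is consistent with the nominal level: for
#' a proportion of 0.95 over 2,000 replications the band, floored at one
#' decimal in percent, is [93.9%, 95.8%].
#'
#' @param successes,trials Binomial counts.
#' @param level Confidence level.
#' @return A one-row tibble (lower clipped at 0, upper at 1).
#' @export
agresti_coull <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials) {
    abort("Need 0 <= successes <= trials, trials >= 1.")
  }
  z <- qnorm((1 + level) / 2)
  nt <- trials + z^2
  pt_ <- (successes + z^2 / 2) / nt
  half <- z * sqrt(pt_ * (1 - pt_) / nt)
  new_ci(max(pt_ - half, 0), min(pt_ + half, 1), level, "agresti-coull")
}

#' Agresti-Coull coverage band in percent
#'
#' The band used to flag simulated coverage: the Agresti-Coull interval for
#' `round(level * trials)` successes, expressed in percent and floored at
#' one decimal.
#'
#' @param trials Number of (used) replications.
#' @param level Nominal coverage level.
#' @return Named numeric vector `c(lower, upper)` in percent.
#' @export
coverage_band <- function(trials, level = 0.95) {
  ci <- agresti_coull(round(level * trials), trials, level = 0.95)
  c(lower = floor(ci$lower * 1000) / 10, upper = floor(ci$upper * 1000) / 10)
}
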