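test_that("Wald intervals use the normal deviate, and t only for the mean", {
  ci <- wald_ci(0.5, level = 0.95, se = 0.1)
  expect_equal(ci$lower, 0.5 - 1.959964 * 0.1, tolerance = 1e-6)
  expect_equal(ci$upper, 0.5 + 1.959964 * 0.1, tolerance = 1e-6)
  # SE = 0 -> degenerate interval
  ci0 <- wald_ci(0.7, se = 0)
  expect_equal(c(ci0$lower, ci0$upper), c(0.7, 0.7))
  # mean with N = 5 uses t(4)
  est <- se_mean(data.frame(x = c(0, 1, 0, 1, 1)), "x")
  cim <- wald_ci(est, 0.95)
  expect_equal((cim$upper - cim$lower) / 2, qt(0.975, 4) * est$se)
  expect_equal(qt(0.975, 4), 2.776445, tolerance = 1e-6)
  # not range-preserving (documented): a proportion CI may exceed [0, 1]
  big <- wald_ci(0.98, se = 0.05)
  expect_gt(big$upper, 1)
  clip <- wald_ci(0.98, se = 0.05, clip = c(0, 1))
  expect_lte(clip$upper, 1)
  expect_error(wald_ci(0.5, level = 1.2, se = 0.1), "level")
})

test_that("Feldt interval behaves per the F construction", {
  ci <- feldt_ci(0.8, N = 101, k = 11, level = 0.95)
  # endpoints from the F quantiles applied to 1 - alpha
  expect_equal(ci$lower, 1 - 0.2 * qf(0.975, 100, 1000))
  expect_equal(ci$upper, 1 - 0.2 * qf(0.025, 100, 1000))
  expect_lt(ci$lower, 0.8)
  expect_gt(ci$upper, 0.8)
  # width shrinks to a point at alpha_hat as the level shrinks
  widths <- sapply(c(0.5, 0.1, 0.01, 0.001), function(l) {
    w <- feldt_ci(0.8, 101, 11, l)
    w$upper - w$lower
  })
  expect_true(all(diff(widths) < 0))
  tiny <- feldt_ci(0.8, 101, 11, 1e-8)
  expect_equal(tiny$lower, 0.8, tolerance = 1e-2)
  # endpoints monotone in alpha_hat
  lows <- sapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(a) feldt_ci(a, 50, 5)$lower)
  ups <- sapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(a) feldt_ci(a, 50, 5)$upper)
  expect_true(all(diff(lows) > 0) && all(diff(ups) > 0))
  expect_error(feldt_ci(1, 50, 5), "below 1")
})

test_that("Fisher-Z interval is the tanh-transformed z interval, range-preserving", {
  ci <- fisher_z_ci(0, N = 103)
  expect_equal(ci$upper, tanh(qnorm(0.975) / 10))
  expect_equal(ci$lower, -ci$upper)
  # stays inside (-1, 1) even for extreme r
  ce <- fisher_z_ci(0.999, N = 10)
  expect_true(ce$lower > -1 && ce$upper < 1)
  # asymmetric around r = 0.5 (tanh curvature)
  c5 <- fisher_z_ci(0.5, N = 50)
  expect_gt(0.5 - c5$lower, c5$upper - 0.5)
  expect_error(fisher_z_ci(1, 50), "below 1")
})

test_that("normal-theory benchmark SEs are exact under normality and scale as 1/sqrt(N-1)", {
  set.seed(21)
  N <- 30
  B <- 5000
  sds <- replicate(B, sd(rnorm(N, 0, 2)))
  bench <- normal_theory_se("sd", N, s = 2)
  mc <- sd(sds)
  expect_lt(abs(bench$se - mc), 3 * mc / sqrt(2 * (B - 1)) + 0.02 * mc)
  # structure: multiplying N-1 by 4 halves the SE
  expect_equal(normal_theory_se("sd", 4 * (N - 1) + 1, s = 2)$se, bench$se / 2)
  expect_equal(normal_theory_se("variance", N, s = 2)$se, 4 * sqrt(2 / (N - 1)))
  expect_equal(normal_theory_se("covariance", N, s_x = 1, s_y = 2, s_xy = 0.5)$se,
               sqrt((4 + 0.25) / (N - 1)))
})

test_that("on dichotomous data the normal-theory SD SE is farther from truth than the delta SE", {
  set.seed(31)
  N <- 150
  p <- 0.85
  B <- 4000
  sds <- replicate(B, sd(rbinom(N, 1, p)))
  truth <- sd(sds)
  x <- c(rep(1, round(N * p)), rep(0, N - round(N * p)))
  delta <- se_sd(score_patterns(matrix(x, ncol = 1)))$se
  bench <- normal_theory_se("sd", N, s = sd(x))$se
  expect_lt(abs(delta - truth), abs(bench - truth))
})

test_that("Agresti-Coull interval matches its closed form and the printed coverage band", {
  # 1900/2000 at 95%: endpoints floored at one decimal give 93.9% and 95.8%
  ci <- agresti_coull(1900, 2000)
  expect_equal(floor(ci$lower * 1000) / 10, 93.9)
  expect_equal(floor(ci$upper * 1000) / 10, 95.8)
  expect_equal(coverage_band(2000), c(lower = 93.9, upper = 95.8))
  # x = 0: lower endpoint clipped at 0
  expect_gte(agresti_coull(0, 50)$lower, 0)
  # x = n/2: symmetric about 1/2
  cs <- agresti_coull(25, 50)
  expect_equal(cs$lower + cs$upper, 1)
})
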