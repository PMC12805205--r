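test_that("response probabilities follow the acceleration-model form", {
  p2pl <- tibble::tibble(item = "i1", a1 = 1, a2 = 1, b1 = 0, b2 = 0,
                         gamma = 0, delta = 0, xi = 1, w1 = 1, w2 = 0)
  expect_equal(unname(drop(response_probability(p2pl, c(0, 0)))), 0.5)
  # upper asymptote 1 - delta, lower gamma
  p5 <- p2pl
  p5$gamma <- 0.1
  p5$delta <- 0.2
  expect_equal(unname(drop(response_probability(p5, c(50, 0)))), 0.8, tolerance = 1e-6)
  expect_equal(unname(drop(response_probability(p5, c(-50, 0)))), 0.1, tolerance = 1e-6)
  # acceleration: at theta = b the 2PL core is 1/2, so P = 0.5^xi
  pacc <- p2pl
  pacc$xi <- 2
  expect_equal(unname(drop(response_probability(pacc, c(0, 0)))), 0.25)
  # monotone in the loaded dimension
  th <- cbind(seq(-3, 3, 0.5), 0)
  expect_true(all(diff(response_probability(p2pl, th)) > 0))
})

test_that("item parameter sampling respects the design", {
  d2 <- sim_design(N = 100, k = 10, model = "2PLM", seed = 7)
  pars <- sample_item_params(d2)
  expect_equal(pars$gamma, rep(0, 10))
  expect_equal(pars$delta, rep(0, 10))
  expect_equal(pars$xi, rep(1, 10))
  # locations evenly spaced with extremes at the range endpoints
  expect_equal(pars$b1, seq(-2, 2, length.out = 10))
  # determinism
  expect_identical(pars, sample_item_params(d2))
  # 5PAM draws vary within the configured supports
  d5 <- sim_design(N = 100, k = 10, model = "5PAM", seed = 7)
  p5 <- sample_item_params(d5)
  expect_true(all(p5$gamma >= 0 & p5$gamma <= 0.2))
  expect_true(all(p5$xi >= 0.5 & p5$xi <= 2))
  expect_true(all(p5$gamma + p5$delta < 1))
})

test_that("data generation is deterministic, correctly shaped, and respects probabilities", {
  d <- sim_design(N = 100, k = 10, seed = 5)
  X <- simulate_responses(d)
  expect_equal(dim(X), c(100, 10))
  expect_true(all(X %in% 0:1))
  expect_identical(X, simulate_responses(d))
  # degenerate probabilities: gamma = 1 - delta = 0.5 -> fair coin flips
  dc <- sim_design(N = 400, k = 6, model = "5PAM", seed = 9,
                   gamma_range = c(0.5, 0.5), delta_range = c(0.5, 0.5))
  Xc <- simulate_responses(dc)
  se3 <- 3 * sqrt(0.25 / 400)
  expect_true(all(abs(colMeans(Xc) - 0.5) < se3 + 0.075))
  # 5PAM with neutral supports reproduces the 2PLM bit for bit
  d2 <- sim_design(N = 200, k = 5, model = "2PLM", seed = 11)
  d5 <- sim_design(N = 200, k = 5, model = "5PAM", seed = 11,
                   gamma_range = c(0, 0), delta_range = c(0, 0), xi_range = c(1, 1))
  expect_identical(simulate_responses(d2), simulate_responses(d5))
})

test_that("population values behave like Monte-Carlo estimates of a fixed population", {
  d <- sim_design(N = 100, k = 4, seed = 13)
  pars <- sample_item_params(d)
  pop1 <- population_values(d, pars, M = 2e5, seed = 100)
  pop2 <- population_values(d, pars, M = 2e5, seed = 200)
  m1 <- pop1$value[pop1$coefficient == "mean" & pop1$target == "sum"]
  m2 <- pop2$value[pop2$coefficient == "mean" & pop2$target == "sum"]
  expect_lt(abs(m1 - m2) / m1, 3 / sqrt(2e5) * 3)
  # items loading on uncorrelated separate dimensions are independent
  dd <- sim_design(N = 100, k = 4, dims = 2, rho = 0, seed = 17)
  pp <- sample_item_params(dd)
  pp$w2[pp$w1 == 1] <- 0 # odd items: dimension 1 only; even: dimension 2 only
  X <- simulate_responses(dd, pp, seed = 31, N = 2e5)
  expect_lt(abs(cor(X[, 1], X[, 2])), 3 / sqrt(2e5) + 0.01)
  # one-dimensional model with identical items: exchangeable covariances
  de <- sim_design(N = 100, k = 3, b_range = c(0, 0), seed = 23)
  pe <- sample_item_params(de)
  pe$a1 <- rep(1, 3)
  Xe <- simulate_responses(de, pe, seed = 41, N = 2e5)
  S <- cov(Xe)
  off <- S[upper.tri(S)]
  expect_lt(max(off) - min(off), 0.01)
})
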