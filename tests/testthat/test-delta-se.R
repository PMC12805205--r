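test_that("mean SEs: ML delta form, conventional form, and engine agreement", {
  x <- data.frame(x = c(0, 1, 0, 1))
  est <- se_mean(x, "x")
  expect_equal(est$estimate, 0.5)
  expect_equal(est$se, sqrt(0.25 / 4)) # = 0.25
  expect_equal(se_mean(x, "x", variant = "conventional")$se, sqrt((1 / 3) / 4))
  # constant variable -> SE 0
  expect_equal(se_mean(data.frame(x = c(2, 2, 2)), "x")$se, 0)
  # engine oracle
  pt <- score_patterns(x)
  expect_equal(est$se, se_generic(chain_mean(pt$R[, 1]), pt)$se, tolerance = 1e-12)
})

test_that("every closed-form SE equals the generic engine SE on random fixtures", {
  for (seed in 1:12) {
    X <- rand_scores(sample(20:60, 1), 4, levels = sample(2:3, 1), seed = seed + 500)
    pt <- score_patterns(X)
    pt1 <- score_patterns(X, spec_item(1))
    pt2 <- score_patterns(X, spec_pair(1, 2))
    part <- split_odd_even(4)
    pth <- score_patterns(X, spec_halves(part$half_a, part$half_b))
    agree <- function(closed, chain, table, tol = 1e-8) {
      expect_equal(closed$se, se_generic(chain, table)$se, tolerance = tol)
    }
    agree(se_mean(pt1), chain_mean(pt1$R[, 1]), pt1)
    agree(se_variance(pt1), chain_variance(pt1$R[, 1]), pt1)
    agree(se_sd(pt1), chain_sd(pt1$R[, 1]), pt1)
    agree(se_covariance(pt2), chain_covariance(pt2$R[, 1], pt2$R[, 2]), pt2)
    agree(se_correlation(pt2), chain_correlation(pt2$R[, 1], pt2$R[, 2]), pt2)
    agree(se_split_half(pth), chain_split_half(pth$R[, 1], pth$R[, 2]), pth)
    agree(se_lambda1(pt), chain_lambda1(pt$R), pt)
    agree(se_lambda2(pt), chain_lambda2(pt$R), pt)
    agree(se_lambda3(pt), chain_lambda3(pt$R), pt)
  }
})

test_that("exact and large-N covariance SEs converge as N grows at fixed proportions", {
  X <- rand_scores(40, 2, seed = 9)
  pt <- score_patterns(X, spec_pair(1, 2))
  rel <- sapply(c(1, 10, 100), function(m) {
    pts <- pt
    pts$n <- pt$n * m
    pts$N <- pt$N * m
    e <- se_covariance(pts)$se
    l <- se_covariance(pts, large_N = TRUE)$se
    abs(e - l) / e
  })
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 1e-3)
})

test_that("covariance/variance special cases: constants, Frechet boundary, near-boundary", {
  # constant variable -> SE = 0, flagged
  Xc <- cbind(a = rep(1, 10), b = rbinom(10, 1, 0.5))
  est <- se_covariance(score_patterns(Xc, spec_pair(1, 2)))
  expect_equal(est$se, 0)
  expect_true("constant-variable" %in% est$flags[[1]])
  # comonotone pair: covariance at the Frechet upper bound -> no SE
  x <- c(0, 0, 1, 1, 2, 2)
  expect_error(se_covariance(score_patterns(cbind(a = x, b = 2 * x), spec_pair(1, 2))),
               class = "deltarel_boundary_error")
  # dichotomous item with p = 1/2 exactly: variance on its boundary -> no SE
  xb <- c(0, 0, 1, 1)
  expect_error(se_variance(score_patterns(matrix(xb, ncol = 1))),
               class = "deltarel_boundary_error")
  expect_error(se_sd(score_patterns(matrix(xb, ncol = 1))),
               class = "deltarel_boundary_error")
  # near (but not at) the maximum variance: flagged, SE still returned
  xn <- c(rep(0, 99), rep(1, 101))
  estn <- se_variance(score_patterns(matrix(xn, ncol = 1)))
  expect_true("near-boundary" %in% estn$flags[[1]])
  expect_gt(estn$se, 0)
})

test_that("SE(s) = SE(s^2) / (2 s) to machine precision", {
  for (seed in 1:5) {
    X <- rand_scores(30, 1, levels = 3, seed = seed + 60)
    pt <- score_patterns(X)
    v <- se_variance(pt)
    s <- se_sd(pt)
    expect_equal(s$se, v$se / (2 * sqrt(v$estimate)))
  }
})

test_that("correlation special cases: zero variance, |r| = 1, epsilon device", {
  expect_error(se_correlation(score_patterns(cbind(a = rep(1, 5), b = c(0, 1, 0, 1, 1)),
                                             spec_pair(1, 2))), "zero variance")
  # x = y -> r = 1 -> SE 0 with boundary flag
  est <- se_correlation(score_patterns(cbind(a = c(0, 1, 2, 0), b = c(0, 1, 2, 0)),
                                       spec_pair(1, 2)))
  expect_equal(est$estimate, 1)
  expect_equal(est$se, 0)
  expect_true("boundary" %in% est$flags[[1]])
  # near-collinear data: epsilon-limit device engages and is stable
  set.seed(4)
  x <- rep(0:1, each = 1200)
  y <- x
  y[1] <- 1 # one discordant respondent: r close to but not at 1
  pt <- score_patterns(cbind(a = x, b = y), spec_pair(1, 2))
  r <- cor(x, y)
  expect_gt(r, 1 - 1e-3)
  estn <- se_correlation(pt)
  expect_true(all(c("near-boundary", "epsilon-device") %in% estn$flags[[1]]))
  expect_gt(estn$se, 0)
  # smooth variation of the device across epsilon
  sx <- sd(x)
  sy <- sd(y)
  vals <- sapply(c(1e-4, 1e-6, 1e-8), function(e) {
    deltarel:::cor_delta_se(pt$R[, 1], pt$R[, 2], pt$n, s_xy = (1 - e) * sx * sy)
  })
  expect_lt(max(abs(diff(vals))) / vals[1], 0.02)
})

test_that("split-half SE: derivative factor at r = 0 and boundary at r = -1", {
  # halves engineered to be uncorrelated: SE(SH) = 2 SE(r)
  X <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  pth <- score_patterns(X, spec_halves(1, 2))
  expect_equal(cor(X[, 1], X[, 2]), 0)
  expect_equal(se_split_half(pth)$se, 2 * se_correlation(pth)$se)
  # antithetic halves: r = -1 -> boundary error
  Xn <- cbind(a = c(0, 1, 0, 1), b = c(1, 0, 1, 0))
  expect_error(se_split_half(score_patterns(Xn, spec_halves(1, 2))),
               class = "deltarel_boundary_error")
})

test_that("lambda SE identities and the zero-covariance epsilon device", {
  for (seed in 1:6) {
    X <- rand_scores(40, sample(3:5, 1), seed = seed + 200)
    pt <- score_patterns(X)
    k <- ncol(X)
    l1 <- se_lambda1(pt)
    l3 <- se_lambda3(pt)
    expect_equal(l3$se, k / (k - 1) * l1$se)
    expect_equal(l3$estimate, k / (k - 1) * l1$estimate)
  }
  # all inter-item covariances zero: sqrt term sits at 0, epsilon device used
  X0 <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  est <- se_lambda2(score_patterns(X0))
  expect_true("epsilon-device" %in% est$flags[[1]])
  expect_true(is.finite(est$se))
})

test_that("SEs are invariant to item relabeling and location shifts", {
  X <- rand_scores(50, 4, levels = 3, seed = 313)
  perm <- c(3, 1, 4, 2)
  expect_equal(se_lambda2(score_patterns(X[, perm]))$se, se_lambda2(score_patterns(X))$se)
  # adding a constant to every score of a variable
  Xs <- X
  Xs[, 1] <- Xs[, 1] + 5
  Xs[, 2] <- Xs[, 2] - 3
  expect_equal(se_lambda2(score_patterns(Xs))$se, se_lambda2(score_patterns(X))$se)
  expect_equal(se_variance(score_patterns(Xs, spec_item(1)))$se,
               se_variance(score_patterns(X, spec_item(1)))$se)
  expect_equal(se_correlation(score_patterns(Xs, spec_pair(1, 2)))$se,
               se_correlation(score_patterns(X, spec_pair(1, 2)))$se)
})

test_that("the covariance matrix of vec(S) is consistent with scalar SEs and resampling", {
  X <- rand_scores(60, 3, seed = 41)
  pt <- score_patterns(X)
  cc <- coefficient_covariance(pt)
  expect_equal(cc$W, t(cc$W))
  expect_equal(cc$W["s11", "s11"], se_variance(score_patterns(X, spec_item(1)))$se^2)
  expect_equal(cc$W["s12", "s12"], se_covariance(score_patterns(X, spec_pair(1, 2)))$se^2)
  expect_equal(cc$W["s12", "s12"], cc$W["s21", "s21"]) # vec(S) symmetry
  # duplicated item: rows/columns respect the induced symmetry
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  ccd <- coefficient_covariance(score_patterns(Xd))
  expect_equal(ccd$W["s11", "s11"], ccd$W["s22", "s22"])
  expect_equal(ccd$W["s13", "s13"], ccd$W["s23", "s23"])
  # a dichotomous item at sample proportion 1/2 sits on the variance
  # boundary: its vec(S) entry degenerates to zero variance and is flagged
  Xb <- cbind(a = rep(0:1, each = 10), b = rep(0:1, times = 10))
  expect_true("s11" %in% coefficient_covariance(score_patterns(Xb))$flagged)

  # resampling oracle on the diagonal at expected frequencies; polytomous
  # fixture so no variance sits near its two-point boundary
  X3 <- rand_scores(60, 3, levels = 3, seed = 42)
  pt <- score_patterns(X3)
  set.seed(99)
  N <- 200
  p <- pt$n / pt$N
  pte <- pt
  pte$n <- N * p
  pte$N <- N
  W <- coefficient_covariance(pte)$W
  B <- 4000
  draws <- rmultinom(B, N, p)
  vecs <- apply(draws, 2, function(n) {
    keep <- n > 0
    as.vector(deltarel:::wmoments(pt$R[keep, , drop = FALSE], n[keep])$S)
  })
  emp <- apply(vecs, 1, var)
  for (i in seq_along(emp)) {
    # MC error of a variance estimate: sd ~ var * sqrt((kurt - 1)/B)
    z <- vecs[i, ] - mean(vecs[i, ])
    kurt <- mean(z^4) / mean(z^2)^2
    mc_se <- emp[i] * sqrt((kurt - 1) / B)
    expect_lt(abs(diag(W)[i] - emp[i]), 4 * mc_se + 1e-12)
  }
})

test_that("N = 2 samples evaluate but are flagged low-N", {
  est <- se_mean(data.frame(x = c(0, 1)), "x")
  expect_true("low-N" %in% est$flags[[1]])
  expect_equal(est$se, sqrt(0.25 / 2))
})
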