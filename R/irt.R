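# Item response theory data simulator.
#
# Population model: a two-dimensional five-parameter acceleration model
# (5PAM) for dichotomous items,
#   P(X_j = 1 | theta) = gamma_j + (1 - gamma_j - delta_j) * Psi_j(theta)^xi_j,
#   Psi_j(theta) = logistic( sum_d w_jd a_jd (theta_d - b_jd) ),
# with discrimination a, location b, lower asymptote gamma, upper asymptote
# 1 - delta, acceleration xi, and design weights w controlling which latent
# dimension each item loads on.  With gamma = delta = 0 and xi = 1 the model
# reduces to the (two-dimensional) two-parameter logistic model (2PLM).

#' Simulation design for the item response theory data generator
#'
#' @param N Sample size per replication.
#' @param k Number of items.
#' @param dims Latent dimensionality, 1 or 2.
#' @param model `"2PLM"` (asymptotes 0/1, acceleration 1) or `"5PAM"`.
#' @param rho Latent correlation of the bivariate standard normal traits.
#' @param b_range Range over which item locations are evenly spaced.
#' @param gamma_range,delta_range Uniform supports for the lower asymptote
#'   and the upper-asymptote deficit (5PAM only).
#' @param xi_range Uniform support for the acceleration parameter (5PAM only).
#' @param replications Number of replications for study runs.
#' @param seed Master seed; per-replication child seeds are derived from it.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(N = 2000, k = 10, dims = 1, model = c("2PLM", "5PAM"),
                       rho = 0.5, b_range = c(-2, 2),
                       gamma_range = c(0, 0.2), delta_range = c(0, 0.2),
                       xi_range = c(0.5, 2), replications = 500, seed = 1L) {
  model <- match.arg(model)
  stopifnot(N >= 2, k >= 2, dims %in% c(1, 2), replications >= 1)
  if (model == "2PLM") {
    gamma_range <- c(0, 0)
    delta_range <- c(0, 0)
    xi_range <- c(1, 1)
  }
  structure(list(
    N = N, k = k, dims = dims, model = model, rho = rho,
    b_range = b_range, gamma_range = gamma_range,
    delta_range = delta_range, xi_range = xi_range,
    replications = replications, seed = as.integer(seed)
  ), class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>", x$model, "| N =", x$N, ", k =", x$k,
      ", dims =", x$dims, ", rho =", x$rho,
      ", replications =", x$replications, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Sample item parameters for a design
#'
#' Discriminations are lognormal(0, 0.1) per dimension; locations are evenly
#' spaced over `b_range` (shared across dimensions); gamma, delta and xi are
#' uniform on the design's supports (degenerate at 0/0/1 for the 2PLM, so
#' the random stream is identical across models and a 5PAM with neutral
#' supports reproduces the 2PLM bit for bit).  Design weights: one
#' dimension: w = (1, 0); two dimensions: odd items load (1, 0.5), even
#' items (0, 1).
#'
#' @param design A [sim_design()].
#' @param seed Optional seed overriding the design's.
#' @return A tibble with one row per item: `a1`, `a2`, `b1`, `b2`, `gamma`,
#'   `delta`, `xi`, `w1`, `w2`.
#' @export
sample_item_params <- function(design, seed = design$seed) {
  set.seed(seed)
  k <- design$k
  b <- seq(design$b_range[1], design$b_range[2], length.out = k)
  a1 <- exp(rnorm(k, 0, 0.1))
  a2 <- exp(rnorm(k, 0, 0.1))
  gamma <- runif(k, design$gamma_range[1], design$gamma_range[2])
  delta <- runif(k, design$delta_range[1], design$delta_range[2])
  xi <- runif(k, design$xi_range[1], design$xi_range[2])
  if (design$dims == 1) {
    w1 <- rep(1, k)
    w2 <- rep(0, k)
  } else {
    odd <- seq_len(k) %% 2 == 1
    w1 <- ifelse(odd, 1, 0)
    w2 <- ifelse(odd, 0.5, 1)
  }
  tibble::tibble(
    item = paste0("item", seq_len(k)),
    a1 = a1, a2 = a2, b1 = b, b2 = b,
    gamma = gamma, delta = delta, xi = xi, w1 = w1, w2 = w2
  )
}

#' Item response probability under the 5PAM
#'
#' @param params A one-or-more-row tibble of item parameters (as from
#'   [sample_item_params()]).
#' @param theta Numeric matrix (persons x 2) or length-2 vector of latent
#'   trait values.
#' @return A persons x items matrix of success probabilities, bounded in
#'   `[gamma, 1 - delta]` and monotone in each dimension the item loads on.
#' @export
response_probability <- function(params, theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 2)
  stopifnot(ncol(theta) == 2)
  k <- nrow(params)
  P <- matrix(NA_real_, nrow(theta), k)
  for (j in seq_len(k)) {
    lin <- params$w1[j] * params$a1[j] * (theta[, 1] - params$b1[j]) +
      params$w2[j] * params$a2[j] * (theta[, 2] - params$b2[j])
    psi <- stats::plogis(lin)
    P[, j] <- params$gamma[j] + (1 - params$gamma[j] - params$delta[j]) * psi^params$xi[j]
  }
  colnames(P) <- params$item
  P
}

rbvn <- function(n, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(z1, z2)
}

#' Generate dichotomous item scores
#'
#' Latent traits are bivariate standard normal with correlation `rho`;
#' scores are 1 when a uniform draw falls below the item response
#' probability.
#'
#' @inheritParams sample_item_params
#' @param params Item parameter tibble.
#' @param N Number of respondents (defaults to the design's).
#' @return An N x k integer matrix of 0/1 scores with item-name columns.
#' @export
simulate_responses <- function(design, params = sample_item_params(design),
                               seed = design$seed, N = design$N) {
  set.seed(seed)
  theta <- rbvn(N, design$rho)
  P <- response_probability(params, theta)
  X <- matrix(as.integer(runif(length(P)) < P), nrow = N)
  colnames(X) <- params$item
  X
}

#' Population values of the reliability coefficients for a design cell
#'
#' Computed by large-sample evaluation: an `M`-respondent dataset is
#' generated from the item parameters and every coefficient of interest is
#' computed on it.  The focal items follow a positional rule: item A is the
#' first item (most extreme mean, closest to the bound), item B the middle
#' item `floor(k/2) + 1` (highest variance, mean nearest 1/2).
#'
#' @inheritParams simulate_responses
#' @param M Population sample size (>= 1e5).
#' @param partition Split-half partition (default odd/even).
#' @return A tibble with columns `coefficient`, `target`, `value`.
#' @export
population_values <- function(design, params = sample_item_params(design),
                              M = 1e6, seed = design$seed + 1L,
                              partition = split_odd_even(design$k)) {
  if (M < 1e5) abort("Population evaluation needs M >= 1e5.")
  X <- simulate_responses(design, params, seed = seed, N = M)
  cell_coefficients(X, design$k, partition)
}

# Focal items by the positional rule.
focal_items <- function(k) list(A = 1L, B = floor(k / 2) + 1L)

# All coefficient values examined in a study cell, as a tibble.
cell_coefficients <- function(X, k, partition) {
  f <- focal_items(k)
  d <- descriptives(X)
  iA <- f$A
  iB <- f$B
  restA <- rowSums(X[, -iA, drop = FALSE])
  restB <- rowSums(X[, -iB, drop = FALSE])
  sumX <- rowSums(X)
  tibble::tibble(
    coefficient = c(
      "mean", "mean", "mean",
      "variance", "variance", "variance",
      "sd", "sd", "sd",
      "covariance", "covariance", "covariance",
      "correlation", "correlation", "correlation",
      "split_half", "lambda1", "lambda2", "lambda3"
    ),
    target = c(
      "itemA", "itemB", "sum",
      "itemA", "itemB", "sum",
      "itemA", "itemB", "sum",
      "A,B", "A,restA", "B,restB",
      "A,B", "A,restA", "B,restB",
      "scale", "scale", "scale", "scale"
    ),
    value = c(
      d$items$mean[iA], d$items$mean[iB], mean(sumX),
      d$items$variance[iA], d$items$variance[iB], var(sumX),
      d$items$sd[iA], d$items$sd[iB], sd(sumX),
      d$S[iA, iB], cov_(X[, iA], restA), cov_(X[, iB], restB),
      d$correlations[iA, iB], safe_cor(X[, iA], restA), safe_cor(X[, iB], restB),
      split_half(X, partition), lambda1(X), lambda2(X), lambda3(X)
    )
  )
}

cov_ <- function(x, y) stats::cov(x, y)
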