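# Independent oracles used across the suite: brute-force coefficient
# implementations (plain loops over raw scores), a central-difference
# numeric Jacobian, random chain/fixture generators, and a cached scaled
# version of the bias/coverage study.

# --- brute force coefficients (loops; no reuse of package internals) --------

bf_mean <- function(x) sum(x) / length(x)

bf_cov <- function(x, y) {
  N <- length(x)
  mx <- bf_mean(x)
  my <- bf_mean(y)
  s <- 0
  for (i in seq_len(N)) s <- s + (x[i] - mx) * (y[i] - my)
  s / (N - 1)
}

bf_var <- function(x) bf_cov(x, x)

bf_cor <- function(x, y) bf_cov(x, y) / sqrt(bf_var(x) * bf_var(y))

bf_lambda1 <- function(X) {
  k <- ncol(X)
  tsum <- 0
  for (j in seq_len(k)) tsum <- tsum + bf_var(X[, j])
  1 - tsum / bf_var(rowSums(X))
}

bf_lambda2 <- function(X) {
  k <- ncol(X)
  c2 <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) c2 <- c2 + bf_cov(X[, i], X[, j])^2
    }
  }
  bf_lambda1(X) + sqrt(k / (k - 1) * c2) / bf_var(rowSums(X))
}

bf_lambda3 <- function(X) ncol(X) / (ncol(X) - 1) * bf_lambda1(X)

bf_split_half <- function(X, part) {
  a <- rowSums(X[, part$half_a, drop = FALSE])
  b <- rowSums(X[, part$half_b, drop = FALSE])
  r <- bf_cor(a, b)
  2 * r / (1 + r)
}

# --- numeric Jacobian --------------------------------------------------------

numeric_jacobian <- function(chain, n) {
  g0 <- chain_eval(chain, n)
  J <- matrix(NA_real_, length(g0), length(n))
  for (c in seq_along(n)) {
    h <- max(1e-6 * n[c], 1e-8)
    np <- n
    nm <- n
    np[c] <- n[c] + h
    nm[c] <- n[c] - h
    J[, c] <- (chain_eval(chain, np) - chain_eval(chain, nm)) / (2 * h)
  }
  J
}

# --- random generators -------------------------------------------------------

rand_scores <- function(N, k, levels = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(sample(0:(levels - 1), N * k, replace = TRUE), N, k)
  colnames(X) <- paste0("i", seq_len(k))
  # guarantee non-constant columns and positive sum-score variance
  for (j in seq_len(k)) {
    if (length(unique(X[, j])) == 1) X[1, j] <- (X[1, j] + 1) %% levels
  }
  X
}

# A random but always-evaluable chain on positive inputs: positive first
# design matrix under log, then exp/sqrt/square/none steps.
rand_chain <- function(C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p1 <- sample(2:4, 1)
  s1 <- explog_step(matrix(runif(p1 * C, 0.1, 2), p1, C), "log")
  p2 <- sample(2:3, 1)
  s2 <- explog_step(matrix(runif(p2 * p1, -0.5, 0.5), p2, p1), "exp")
  tr <- sample(c("none", "sqrt", "square", "reciprocal"), 1)
  s3 <- explog_step(matrix(runif(2 * p2, 0.1, 1), 2, p2), tr)
  s4 <- explog_step(matrix(runif(1 * 2, -1, 1), 1, 2), "none")
  explog_chain(s1, s2, s3, s4)
}

pt_of <- function(X, ...) score_patterns(X, ...)

# --- shared scaled-down study (expensive; computed once per run) ------------

acceptance_env <- new.env(parent = emptyenv())

get_acceptance_study <- function() {
  if (is.null(acceptance_env$study)) {
    design <- sim_design(N = 2000, k = 10, dims = 1, model = "2PLM",
                         replications = 500, seed = 1L)
    acceptance_env$study <- run_study(design, pop_M = 1e6)
  }
  acceptance_env$study
}

# --- vectorized coefficient evaluation over many multinomial draws ----------
# R: C x k pattern matrix of all item scores; draws: C x B frequency matrix.
# Returns a list of length-B vectors, one per coefficient, for the
# Monte-Carlo calibration oracle.
mc_coefficient_draws <- function(R, draws, part = split_odd_even(ncol(R))) {
  k <- ncol(R)
  N <- colSums(draws)
  S <- lapply(seq_len(k), function(j) drop(crossprod(R[, j], draws)))
  cross <- function(u, v) drop(crossprod(u * v, draws))
  covb <- function(i, j) (N * cross(R[, i], R[, j]) - S[[i]] * S[[j]]) / (N * (N - 1))
  X <- rowSums(R)
  SX <- drop(crossprod(X, draws))
  varX <- (N * cross(X, X) - SX^2) / (N * (N - 1))
  ha <- rowSums(R[, part$half_a, drop = FALSE])
  hb <- rowSums(R[, part$half_b, drop = FALSE])
  Sa <- drop(crossprod(ha, draws))
  Sb <- drop(crossprod(hb, draws))
  r_ab <- (N * cross(ha, hb) - Sa * Sb) /
    sqrt((N * cross(ha, ha) - Sa^2) * (N * cross(hb, hb) - Sb^2))
  vars <- lapply(seq_len(k), function(j) covb(j, j))
  Tsum <- Reduce(`+`, vars)
  C2 <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) C2 <- C2 + 2 * covb(i, j)^2
  }
  l1 <- 1 - Tsum / varX
  list(
    mean = S[[1]] / N,
    variance = vars[[1]],
    sd = sqrt(vars[[1]]),
    covariance = covb(1, 2),
    correlation = covb(1, 2) / sqrt(vars[[1]] * vars[[2]]),
    split_half = 2 * r_ab / (1 + r_ab),
    lambda1 = l1,
    lambda2 = l1 + sqrt(k / (k - 1) * C2) / varX,
    lambda3 = k / (k - 1) * l1
  )
}

# expected-frequency pattern table
expected_table <- function(R, p, N) {
  structure(list(R = R, n = N * p, N = N, C = length(p)), class = "score_patterns")
}
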