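# Exp-log chain constructions for each reliability coefficient.
#
# The builders take the pattern matrix R (the derived-score values of the C
# observed patterns) and return an explog_chain in the frequency vector n.
# Scores are shifted inside the chains so that every logarithm is applied to
# a sum of strictly positive quantities; shifting a variable by a constant
# leaves variances, covariances, correlations and the lambda coefficients
# unchanged, and for the mean the shift is undone by a final linear step.
# Signed quantities (covariances, numerators of correlations) are only ever
# produced by linear "none" steps; products and ratios of the positive
# ingredients are routed through log/exp pairs.

# Shift that makes all values of a column >= 1 (0 when already >= 1).
chain_shift <- function(x) max(0, 1 - min(x))

#' Exp-log chain for the mean of a single variable
#'
#' @param values Numeric vector: the variable's value at each of the C
#'   patterns (one column of a pattern table's `R`).
#' @return An `explog_chain` mapping a frequency vector of length C to the
#'   sample mean.
#' @export
chain_mean <- function(values) {
  a <- chain_shift(values)
  xs <- values + a
  if (a == 0) {
    explog_chain(
      explog_step(rbind(xs, rep(1, length(xs))), "log"),
      explog_step(cbind(1, -1), "exp")
    )
  } else {
    # mean(x) = Sx'/N - aN/N with Sx' > 0 and aN > 0
    explog_chain(
      explog_step(rbind(xs, rep(a, length(xs)), rep(1, length(xs))), "log"),
      explog_step(rbind(c(1, 0, -1), c(0, 1, -1)), "exp"),
      explog_step(cbind(1, -1), "none")
    )
  }
}

#' Exp-log chain for the unbiased covariance of two variables
#'
#' Produces s_xy = (N Sxy - Sx Sy) / (N^2 - N) from shifted scores; the
#' possibly negative difference is formed in a final linear step.
#'
#' @param x,y Numeric vectors: the two variables' values at the C patterns.
#' @return An `explog_chain` with scalar output.
#' @export
chain_covariance <- function(x, y) {
  xs <- x + chain_shift(x)
  ys <- y + chain_shift(y)
  C <- length(xs)
  one <- rep(1, C)
  explog_chain(
    explog_step(rbind(xs * ys, xs, ys, one), "log"),
    # -> (N Sxy', Sx'Sy', N^2, N), all positive
    explog_step(rbind(c(1, 0, 0, 1), c(0, 1, 1, 0), c(0, 0, 0, 2), c(0, 0, 0, 1)), "exp"),
    # -> (N Sxy', Sx'Sy', N^2 - N)
    explog_step(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, -1)), "none"),
    explog_step(diag(3), "log"),
    # -> (N Sxy'/D, Sx'Sy'/D)
    explog_step(rbind(c(1, 0, -1), c(0, 1, -1)), "exp"),
    explog_step(cbind(1, -1), "none")
  )
}

#' @rdname chain_covariance
#' @export
chain_variance <- function(x) chain_covariance(x, x)

#' Exp-log chain for the standard deviation of a variable
#'
#' @inheritParams chain_mean
#' @return An `explog_chain` with scalar output; requires a non-constant
#'   variable (the log of the variance numerator must be positive).
#' @export
chain_sd <- function(values) {
  xs <- values + chain_shift(values)
  C <- length(xs)
  one <- rep(1, C)
  explog_chain(
    explog_step(rbind(xs^2, xs, one), "log"),
    # -> (N Sxx', Sx'^2, N^2, N)
    explog_step(rbind(c(1, 0, 1), c(0, 2, 0), c(0, 0, 2), c(0, 0, 1)), "exp"),
    # -> (Q = N Sxx' - Sx'^2, D = N^2 - N), both positive for non-constant x
    explog_step(rbind(c(1, -1, 0, 0), c(0, 0, 1, -1)), "none"),
    explog_step(diag(2), "log"),
    explog_step(cbind(0.5, -0.5), "exp")
  )
}

# Shared head of the correlation/split-half chains: ends with
# (P + sqrt(Qx Qy), sqrt(Qx Qy)) where P = N Sxy' - Sx'Sy' = N(N-1) s_xy and
# Qx, Qy are the same quantities for the variances.  Both outputs are
# positive unless r = -1.
chain_corr_head <- function(x, y) {
  xs <- x + chain_shift(x)
  ys <- y + chain_shift(y)
  C <- length(xs)
  one <- rep(1, C)
  list(
    explog_step(rbind(xs * ys, xs^2, ys^2, xs, ys, one), "log"),
    # -> (N Sxy', Sx'Sy', N Sxx', Sx'^2, N Syy', Sy'^2)
    explog_step(rbind(
      c(1, 0, 0, 0, 0, 1),
      c(0, 0, 0, 1, 1, 0),
      c(0, 1, 0, 0, 0, 1),
      c(0, 0, 0, 2, 0, 0),
      c(0, 0, 1, 0, 0, 1),
      c(0, 0, 0, 0, 2, 0)
    ), "exp"),
    # -> (N Sxy', Sx'Sy', Qx, Qy)
    explog_step(rbind(
      c(1, 0, 0, 0, 0, 0),
      c(0, 1, 0, 0, 0, 0),
      c(0, 0, 1, -1, 0, 0),
      c(0, 0, 0, 0, 1, -1)
    ), "none"),
    explog_step(diag(4), "log"),
    # -> (N Sxy', Sx'Sy', sqrt(Qx Qy))
    explog_step(rbind(
      c(1, 0, 0, 0),
      c(0, 1, 0, 0),
      c(0, 0, 0.5, 0.5)
    ), "exp"),
    # -> (P + sqrt(Qx Qy), sqrt(Qx Qy))
    explog_step(rbind(c(1, -1, 1), c(0, 0, 1)), "none"),
    explog_step(diag(2), "log")
  )
}

#' Exp-log chain for the product-moment correlation
#'
#' Built as r = (P + sqrt(Qx Qy)) / sqrt(Qx Qy) - 1 so that every logarithm
#' sees a positive argument for r > -1.
#'
#' @inheritParams chain_covariance
#' @return An `explog_chain` with scalar output.
#' @export
chain_correlation <- function(x, y) {
  explog_chain(c(
    chain_corr_head(x, y),
    list(
      explog_step(rbind(c(1, -1), c(0, 0)), "exp"), # (r + 1, 1)
      explog_step(cbind(1, -1), "none")
    )
  ))
}

#' Exp-log chain for the split-half reliability coefficient
#'
#' Spearman-Brown-stepped correlation between the two half sums:
#' SH = 2 r / (1 + r) = 2 - 2 / (1 + r).
#'
#' @param half_a,half_b Numeric vectors: the two half-sum values at the C
#'   patterns.
#' @return An `explog_chain` with scalar output.
#' @export
chain_split_half <- function(half_a, half_b) {
  explog_chain(c(
    chain_corr_head(half_a, half_b),
    list(
      explog_step(rbind(c(-1, 1), c(0, 0)), "exp"), # (1/(r+1), 1)
      explog_step(cbind(-2, 2), "none")
    )
  ))
}

# Shared positive ingredients of the lambda chains, from the pattern matrix
# of all k item scores: T* = N(N-1) * sum_j s_j^2 and Qx = N(N-1) * s_X^2.
lambda_head_rows <- function(R) {
  Rs <- sweep(R, 2, vapply(seq_len(ncol(R)), function(j) chain_shift(R[, j]), numeric(1)), "+")
  X <- rowSums(Rs)
  list(Rs = Rs, X = X)
}

#' Exp-log chains for Guttman's lambda coefficients
#'
#' `chain_lambda1()` and `chain_lambda3()` build
#' lambda1 = 1 - (sum of item variances)/s_X^2 and its k/(k-1) multiple
#' (Cronbach's alpha); `chain_lambda2()` adds the sqrt(k/(k-1) C2)/s_X^2 term,
#' where C2 is the sum of squared inter-item covariances (ordered pairs).
#' All three are homogeneous of order 0.
#'
#' @param R Pattern matrix (C x k) of all item scores.
#' @return An `explog_chain` with scalar output.
#' @export
chain_lambda1 <- function(R) chain_lambda13(R, factor = 1)

#' @rdname chain_lambda1
#' @export
chain_lambda3 <- function(R) chain_lambda13(R, factor = ncol(R) / (ncol(R) - 1))

chain_lambda13 <- function(R, factor) {
  k <- ncol(R)
  if (k < 2) abort("Lambda coefficients need at least two items.")
  h <- lambda_head_rows(R)
  Rs <- h$Rs
  C <- nrow(Rs)
  one <- rep(1, C)
  # log step inputs: t2 = sum_j x_j'^2, x_1'..x_k', X'^2, X', 1
  A1 <- rbind(rowSums(Rs^2), t(Rs), h$X^2, h$X, one)
  p <- k + 4 # outputs of step 1
  # exp step: N*Tsum', S_j'^2 (k rows), N*SXX', SX'^2
  A2 <- matrix(0, k + 3, p)
  A2[1, 1] <- 1; A2[1, p] <- 1
  for (j in seq_len(k)) A2[1 + j, 1 + j] <- 2
  A2[k + 2, k + 2] <- 1; A2[k + 2, p] <- 1
  A2[k + 3, k + 3] <- 2
  # linear: T* = N Tsum' - sum_j Sj'^2 ; QX = N SXX' - SX'^2
  A3 <- rbind(
    c(1, rep(-1, k), 0, 0),
    c(0, rep(0, k), 1, -1)
  )
  explog_chain(
    explog_step(A1, "log"),
    explog_step(A2, "exp"),
    explog_step(A3, "none"),
    explog_step(diag(2), "log"),
    explog_step(rbind(c(1, -1), c(0, 0)), "exp"), # (T/s_X^2, 1)
    explog_step(cbind(-factor, factor), "none")
  )
}

#' @rdname chain_lambda1
#' @export
chain_lambda2 <- function(R) {
  k <- ncol(R)
  if (k < 2) abort("Lambda coefficients need at least two items.")
  h <- lambda_head_rows(R)
  Rs <- h$Rs
  C <- nrow(Rs)
  one <- rep(1, C)
  pairs <- utils::combn(k, 2)
  np <- ncol(pairs)
  pair_rows <- t(apply(pairs, 2, function(ij) Rs[, ij[1]] * Rs[, ij[2]]))
  # log inputs: pair products (np), t2, x_j' (k), X'^2, X', 1
  A1 <- rbind(pair_rows, rowSums(Rs^2), t(Rs), h$X^2, h$X, one)
  p <- np + k + 4
  iT <- np + 1; iS <- np + 1 + seq_len(k); iXX <- np + k + 2; iX <- np + k + 3; iN <- p
  # exp step outputs: N Sij' (np), Si'Sj' (np), N Tsum', Sj'^2 (k), N SXX', SX'^2
  A2 <- matrix(0, 2 * np + k + 3, p)
  for (m in seq_len(np)) {
    A2[m, m] <- 1; A2[m, iN] <- 1
    A2[np + m, iS[pairs[1, m]]] <- 1; A2[np + m, iS[pairs[2, m]]] <- 1
  }
  r0 <- 2 * np
  A2[r0 + 1, iT] <- 1; A2[r0 + 1, iN] <- 1
  for (j in seq_len(k)) A2[r0 + 1 + j, iS[j]] <- 2
  A2[r0 + k + 2, iXX] <- 1; A2[r0 + k + 2, iN] <- 1
  A2[r0 + k + 3, iX] <- 2
  # linear + square: (P_ij, T*, QX) -> squared elementwise
  A3 <- matrix(0, np + 2, 2 * np + k + 3)
  for (m in seq_len(np)) {
    A3[m, m] <- 1; A3[m, np + m] <- -1
  }
  A3[np + 1, r0 + 1] <- 1; A3[np + 1, r0 + 1 + seq_len(k)] <- -1
  A3[np + 2, r0 + k + 2] <- 1; A3[np + 2, r0 + k + 3] <- -1
  # linear: C2** = (2k/(k-1)) sum P_ij^2 ; T*^2 ; QX^2
  A4 <- rbind(
    c(rep(2 * k / (k - 1), np), 0, 0),
    c(rep(0, np), 1, 0),
    c(rep(0, np), 0, 1)
  )
  explog_chain(
    explog_step(A1, "log"),
    explog_step(A2, "exp"),
    explog_step(A3, "square"),
    explog_step(A4, "none"),
    explog_step(diag(3), "log"),
    # (sqrt(C2**)/QX, T*/QX, 1)
    explog_step(rbind(c(0.5, 0, -0.5), c(0, 0.5, -0.5), c(0, 0, 0)), "exp"),
    explog_step(cbind(1, -1, 1), "none")
  )
}

#' Exp-log chain for the stacked inter-item covariance matrix vec(S)
#'
#' Output is the k^2-vector of unbiased inter-item variances/covariances in
#' column-major order; feeding it through the generic delta-method engine
#' yields the full covariance matrix of vec(S).
#'
#' @inheritParams chain_lambda1
#' @return An `explog_chain` with k^2 outputs.
#' @export
chain_vec_s <- function(R) {
  k <- ncol(R)
  h <- lambda_head_rows(R)
  Rs <- h$Rs
  C <- nrow(Rs)
  one <- rep(1, C)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE) # i <= j pairs
  np <- nrow(idx)
  prod_rows <- t(apply(idx, 1, function(ij) Rs[, ij[1]] * Rs[, ij[2]]))
  A1 <- rbind(prod_rows, t(Rs), one)
  p <- np + k + 1
  iS <- np + seq_len(k); iN <- p
  # exp: N Sij' (np), Si'Sj' (np), N^2, N
  A2 <- matrix(0, 2 * np + 2, p)
  for (m in seq_len(np)) {
    A2[m, m] <- 1; A2[m, iN] <- 1
    A2[np + m, iS[idx[m, 1]]] <- A2[np + m, iS[idx[m, 1]]] + 1
    A2[np + m, iS[idx[m, 2]]] <- A2[np + m, iS[idx[m, 2]]] + 1
  }
  A2[2 * np + 1, iN] <- 2
  A2[2 * np + 2, iN] <- 1
  # linear: carry N Sij', Si'Sj', D = N^2 - N (all positive)
  A3 <- cbind(diag(2 * np), matrix(0, 2 * np, 2))
  A3 <- rbind(A3, c(rep(0, 2 * np), 1, -1))
  # log, then exp of (row_m - row_D) pairs
  A5 <- matrix(0, 2 * np, 2 * np + 1)
  for (m in seq_len(2 * np)) {
    A5[m, m] <- 1; A5[m, 2 * np + 1] <- -1
  }
  # final linear: s_ij = NSij'/D - Si'Sj'/D, mapped to the k^2 vec ordering
  A6 <- matrix(0, k * k, 2 * np)
  pair_of <- function(i, j) which(idx[, 1] == min(i, j) & idx[, 2] == max(i, j))
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      m <- pair_of(i, j)
      row <- (j - 1) * k + i
      A6[row, m] <- 1
      A6[row, np + m] <- -1
    }
  }
  explog_chain(
    explog_step(A1, "log"),
    explog_step(A2, "exp"),
    explog_step(A3, "none"),
    explog_step(diag(2 * np + 1), "log"),
    explog_step(A5, "exp"),
    explog_step(A6, "none")
  )
}
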