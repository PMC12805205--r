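# Classical-test-theory coefficients.
#
# Everything is computed from the response-pattern representation (R, n) by
# weighted moments, so the same code serves raw data (after compression),
# expected frequencies N*p, and multinomial resamples.  Unbiased (N-1)
# estimators are the default throughout; maximum-likelihood (1/N) variants
# are exposed with explicit names because the delta-method SE of the mean is
# based on the ML variance.

# Weighted moment core --------------------------------------------------------

# means, unbiased covariance matrix S, and ML covariance matrix from (R, n)
wmoments <- function(R, n) {
  N <- sum(n)
  means <- drop(crossprod(R, n)) / N
  Rc <- sweep(R, 2, means)
  M <- crossprod(Rc, Rc * n) / N # ML covariance matrix
  list(N = N, means = means, M = M, S = M * N / (N - 1))
}

pattern_of <- function(scores, spec) {
  if (inherits(scores, "score_patterns")) scores else score_patterns(scores, spec)
}

#' Item, scale and inter-item descriptive statistics
#'
#' Returns the descriptive part of a reliability analysis: per-item means,
#' variances and SDs, scale (sum-score) statistics, and the inter-item
#' covariance and correlation matrices.  Variances and covariances use the
#' unbiased N-1 denominator; `ml_variance()` gives the 1/N variant.
#'
#' @param scores Respondents x items data frame or matrix of complete
#'   numeric scores.
#' @return A list of class `descriptives`: `items` (tibble), `scale`
#'   (one-row tibble), `S`, `correlations` (matrices), `N`, `k`.  Items with
#'   zero variance yield `NA` correlations and are listed in
#'   `zero_variance_items`.
#' @export
descriptives <- function(scores) {
  scores <- as_score_matrix(scores)
  if (nrow(scores) < 2) abort("At least two respondents are required.")
  pt <- score_patterns(scores)
  w <- wmoments(pt$R, pt$n)
  k <- ncol(scores)
  vars <- diag(w$S)
  zero_var <- vars <= 0
  if (any(zero_var)) {
    warn(paste0("Zero-variance item(s): ",
                paste(colnames(scores)[zero_var], collapse = ", "),
                "; their correlations are undefined."))
  }
  sds <- sqrt(pmax(vars, 0))
  denom <- tcrossprod(ifelse(zero_var, NA_real_, sds))
  correlations <- w$S / denom
  diag(correlations) <- ifelse(zero_var, NA_real_, 1)
  X <- rowSums(pt$R)
  wx <- wmoments(matrix(X, ncol = 1), pt$n)
  structure(list(
    items = tibble::tibble(
      item = colnames(scores),
      mean = unname(w$means),
      variance = unname(vars),
      sd = unname(sds)
    ),
    scale = tibble::tibble(
      mean = unname(wx$means), variance = unname(drop(wx$S)), sd = sqrt(unname(drop(wx$S)))
    ),
    S = w$S,
    correlations = correlations,
    zero_variance_items = colnames(scores)[zero_var],
    N = pt$N, k = k
  ), class = "descriptives")
}

#' @export
print.descriptives <- function(x, ...) {
  cat("<descriptives> N =", x$N, ", k =", x$k, "\n")
  print(x$items)
  cat("scale:\n")
  print(x$scale)
  invisible(x)
}

#' Maximum-likelihood (1/N) variance of a variable
#'
#' @inheritParams descriptives
#' @param spec A [score_spec] selecting a single derived variable.
#' @return The ML variance (denominator N).
#' @export
ml_variance <- function(scores, spec = spec_item(1)) {
  pt <- pattern_of(scores, spec)
  if (ncol(pt$R) != 1) abort("`ml_variance()` needs a single derived variable.")
  w <- wmoments(pt$R, pt$n)
  drop(w$M)
}

# Lambda coefficients ---------------------------------------------------------

lambda_parts <- function(S) {
  k <- ncol(S)
  Tsum <- sum(diag(S))
  sX2 <- sum(S)
  C2 <- sum(S^2) - sum(diag(S)^2) # ordered pairs i != j
  list(k = k, Tsum = Tsum, sX2 = sX2, C2 = C2)
}

check_lambda_input <- function(S) {
  if (ncol(S) < 2) abort("Lambda coefficients need at least two items (k >= 2).")
  if (sum(S) <= 0) abort("Sum-score variance is zero; lambda coefficients are undefined.")
}

#' Guttman's lambda coefficients
#'
#' `lambda1 = 1 - sum(s_j^2)/s_X^2`;
#' `lambda2 = lambda1 + sqrt(k/(k-1) * C2)/s_X^2` with C2 the sum of squared
#' inter-item covariances over ordered pairs; and
#' `lambda3 = k/(k-1) * lambda1`, which equals Cronbach's alpha.  All three
#' are computed from the unbiased inter-item covariance matrix.
#'
#' @inheritParams descriptives
#' @return A single numeric value, or for [guttman_lambdas()] a tibble with
#'   one row per coefficient.
#' @examples
#' x <- data.frame(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1), c = c(0, 1, 1, 1))
#' lambda3(x) # Cronbach's alpha
#' @export
lambda1 <- function(scores) {
  p <- lambda_parts(score_cov(scores))
  1 - p$Tsum / p$sX2
}

#' @rdname lambda1
#' @export
lambda2 <- function(scores) {
  p <- lambda_parts(score_cov(scores))
  1 - p$Tsum / p$sX2 + sqrt(p$k / (p$k - 1) * p$C2) / p$sX2
}

#' @rdname lambda1
#' @export
lambda3 <- function(scores) {
  p <- lambda_parts(score_cov(scores))
  p$k / (p$k - 1) * (1 - p$Tsum / p$sX2)
}

#' @rdname lambda1
#' @export
guttman_lambdas <- function(scores) {
  tibble::tibble(
    coefficient = c("lambda1", "lambda2", "lambda3"),
    estimate = c(lambda1(scores), lambda2(scores), lambda3(scores))
  )
}

score_cov <- function(scores) {
  if (is.matrix(scores) && isTRUE(attr(scores, "is_cov"))) return(scores)
  pt <- pattern_of(scores, spec_items())
  S <- wmoments(pt$R, pt$n)$S
  check_lambda_input(S)
  S
}

# Split half -------------------------------------------------------------------

#' Standard split-half partitions
#'
#' `split_first_second()` puts the first half of the items against the
#' second; `split_odd_even()` alternates items.
#'
#' @param k Number of items.
#' @return A list with components `half_a` and `half_b` (item indices).
#' @export
split_first_second <- function(k) {
  a <- seq_len(floor(k / 2))
  list(half_a = a, half_b = setdiff(seq_len(k), a))
}

#' @rdname split_first_second
#' @export
split_odd_even <- function(k) {
  list(half_a = seq(1, k, by = 2), half_b = seq(2, k, by = 2))
}

#' Split-half reliability coefficient
#'
#' The Spearman-Brown-stepped correlation between the sum scores of two test
#' halves: SH = 2 r / (1 + r).
#'
#' @inheritParams descriptives
#' @param partition A list with `half_a`, `half_b` (as from
#'   [split_odd_even()]), covering all items.
#' @return The split-half coefficient.
#' @export
split_half <- function(scores, partition = split_odd_even(ncol(as_score_matrix(scores)))) {
  pt <- score_patterns(scores, spec_halves(partition$half_a, partition$half_b))
  w <- wmoments(pt$R, pt$n)
  v <- diag(w$S)
  if (any(v <= 0)) abort("A half sum has zero variance; split-half undefined.")
  r <- unname(w$S[1, 2] / sqrt(v[1] * v[2]))
  if (r <= -1) boundary_error("Half-sum correlation is -1; split-half undefined.")
  2 * r / (1 + r)
}

# Item-rest statistics ---------------------------------------------------------

#' Item-rest and item-total correlations
#'
#' The item-rest correlation (corrected item-total correlation) correlates
#' each item with the sum of the remaining items; the uncorrected item-total
#' correlation uses the full sum score and is reported alongside, flagged as
#' such.
#'
#' @inheritParams descriptives
#' @return A tibble with columns `item`, `item_rest_r`, `item_total_r`.
#' @export
item_rest_statistics <- function(scores) {
  scores <- as_score_matrix(scores)
  k <- ncol(scores)
  if (k < 2) abort("Item-rest statistics need at least two items.")
  X <- rowSums(scores)
  out <- purrr::map_dfr(seq_len(k), function(j) {
    x <- scores[, j]
    rest <- X - x
    tibble::tibble(
      item = colnames(scores)[j],
      item_rest_r = safe_cor(x, rest),
      item_total_r = safe_cor(x, X)
    )
  })
  out
}

safe_cor <- function(x, y) {
  if (var(x) <= 0 || var(y) <= 0) return(NA_real_)
  cor(x, y)
}

# Item deletion -----------------------------------------------------------------

#' Rest statistics: the scale with one item deleted
#'
#' Recomputes the scale statistics and lambda coefficients on the remaining
#' k - 1 items; "alpha if item deleted" is the lambda-3 of the reduced set.
#'
#' @inheritParams descriptives
#' @param item Column name or index of the item to delete.
#' @return A list with `scale` (tibble of rest-score mean/variance/sd),
#'   `lambda1`, `lambda2`, `lambda3`, and the reduced score matrix
#'   (`scores`).
#' @export
item_deleted <- function(scores, item) {
  scores <- as_score_matrix(scores)
  if (ncol(scores) < 3) abort("Item deletion needs at least three items (k >= 3).")
  j <- resolve_items(scores, item)
  reduced <- scores[, -j, drop = FALSE]
  d <- descriptives(reduced)
  list(
    scale = d$scale,
    lambda1 = lambda1(reduced),
    lambda2 = lambda2(reduced),
    lambda3 = lambda3(reduced),
    scores = reduced
  )
}
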