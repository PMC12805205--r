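# Delta-method standard errors under multinomial sampling.
#
# Two routes are provided for every coefficient and must agree:
#   * the generic engine: an exp-log chain, its chain-rule Jacobian G, and
#     variance G V(n) G' with V(n) = diag(n) - n n'/N (or G diag(n) G' for
#     chains homogeneous of order 0);
#   * closed forms: the analytically derived gradient of each coefficient
#     with respect to the frequency vector, with the same quadratic form.
# For a scalar coefficient with gradient g the variance is
#   sum(n g^2) - (sum(n g))^2 / N.

# Estimate container ----------------------------------------------------------

new_estimate <- function(coefficient, variable, estimate, se, method,
                         flags = character(), df = NA_real_, n_obs = NA_real_) {
  # N = 2 is the smallest sample every formula still evaluates on; flag it
  # rather than invent small-sample corrections.
  if (!is.na(n_obs) && n_obs <= 2) flags <- union(flags, "low-N")
  tibble::tibble(
    coefficient = coefficient,
    variable = variable,
    estimate = estimate,
    se = se,
    method = method,
    df = df,
    n_obs = n_obs,
    flags = list(flags)
  )
}

delta_var <- function(g, n) {
  N <- sum(n)
  sum(n * g^2) - sum(n * g)^2 / N
}

# Tolerances used for boundary detection: a coefficient is *at* the boundary
# within `atol_boundary` (relative) and *near* it within `near_boundary`.
atol_boundary <- 1e-12
near_boundary <- 1e-3

#' Iterated epsilon-limit device
#'
#' Evaluates `f(eps)` for a descending sequence of perturbations until two
#' successive values agree to `rtol` relative.  Used where an SE formula is
#' undefined exactly on a boundary (|r| = 1, all inter-item covariances
#' zero) but has a stable limit.
#'
#' @param f Function of a single positive perturbation.
#' @param eps Descending perturbation values.
#' @param rtol Relative stability tolerance.
#' @return A list with `value`, `eps` (the perturbation at convergence) and
#'   `converged`.
#' @export
eps_limit <- function(f, eps = 10^-(4:10), rtol = 1e-6) {
  prev <- NULL
  for (e in eps) {
    v <- f(e)
    if (!is.null(prev) && abs(v - prev) <= rtol * max(abs(v), 1e-300)) {
      return(list(value = v, eps = e, converged = TRUE))
    }
    prev <- v
  }
  list(value = prev, eps = eps[length(eps)], converged = FALSE)
}

# Variable resolution ---------------------------------------------------------

one_var_patterns <- function(scores, variable) {
  if (inherits(scores, "score_patterns")) {
    j <- if (is.null(variable)) 1L else variable
    list(x = scores$R[, j], n = scores$n)
  } else {
    spec <- if (inherits(variable, "score_spec")) variable else spec_item(variable %||% 1L)
    pt <- score_patterns(scores, spec)
    list(x = pt$R[, 1], n = pt$n)
  }
}

two_var_patterns <- function(scores, var1, var2) {
  if (inherits(scores, "score_patterns")) {
    if (ncol(scores$R) < 2) abort("Pattern table must have two variables.")
    list(x = scores$R[, var1 %||% 1L], y = scores$R[, var2 %||% 2L], n = scores$n)
  } else if (inherits(var1, "score_spec")) {
    pt <- score_patterns(scores, var1)
    list(x = pt$R[, 1], y = pt$R[, 2], n = pt$n)
  } else {
    pt <- score_patterns(scores, spec_pair(var1, var2))
    list(x = pt$R[, 1], y = pt$R[, 2], n = pt$n)
  }
}

wcov2 <- function(x, y, n) {
  N <- sum(n)
  mx <- sum(n * x) / N
  my <- sum(n * y) / N
  dx <- x - mx
  dy <- y - my
  s_ml <- sum(n * dx * dy) / N
  list(N = N, mx = mx, my = my, dx = dx, dy = dy,
       s_ml = s_ml, s = s_ml * N / (N - 1),
       m22 = sum(n * dx^2 * dy^2) / N)
}

# Frechet bounds of the unbiased covariance given the two margins.
frechet_cov_bounds <- function(x, y, n) {
  N <- sum(n)
  marg <- function(v) {
    agg <- rowsum(n, group = v)
    list(val = as.numeric(rownames(agg)), p = drop(agg) / N)
  }
  mx <- marg(x)
  my <- marg(y)
  exy_coupled <- function(xv, xp, yv, yp) {
    i <- 1; j <- 1; e <- 0
    while (i <= length(xv) && j <= length(yv)) {
      w <- min(xp[i], yp[j])
      e <- e + w * xv[i] * yv[j]
      xp[i] <- xp[i] - w
      yp[j] <- yp[j] - w
      if (xp[i] <= 1e-15) i <- i + 1
      if (yp[j] <= 1e-15) j <- j + 1
    }
    e
  }
  ex <- sum(mx$val * mx$p)
  ey <- sum(my$val * my$p)
  up <- exy_coupled(mx$val, mx$p, my$val, my$p) - ex * ey
  lo <- exy_coupled(mx$val, mx$p, rev(my$val), rev(my$p)) - ex * ey
  c(lower = lo * N / (N - 1), upper = up * N / (N - 1))
}

# Closed-form SEs ---------------------------------------------------------------

#' Delta-method standard error of the mean
#'
#' The multinomial delta method yields the SE of the mean based on the
#' maximum-likelihood variance, `sqrt(sigma2_ML / N)` (variant `"ml"`, the
#' default).  The conventional SE based on the unbiased variance, `s/sqrt(N)`
#' (variant `"conventional"`), is exposed as well and is the one to prefer in
#' practice, being unbiased.
#'
#' @param scores Score matrix/data frame, or a `score_patterns` table.
#' @param variable Item name/index or a [score_spec] for a derived variable
#'   (e.g. `spec_sum()`); ignored when `scores` is already a pattern table.
#' @param variant `"ml"` or `"conventional"`.
#' @return A one-row tibble (coefficient estimate with SE).
#' @examples
#' se_mean(data.frame(x = c(0, 1, 0, 1)), "x")
#' @export
se_mean <- function(scores, variable = NULL, variant = c("ml", "conventional")) {
  variant <- match.arg(variant)
  v <- one_var_patterns(scores, variable)
  w <- wcov2(v$x, v$x, v$n)
  se <- if (variant == "ml") sqrt(w$s_ml / w$N) else sqrt(w$s / w$N)
  new_estimate("mean", "x", w$mx, se,
               method = paste0("closed-form-", variant),
               df = w$N - 1, n_obs = w$N)
}

#' Delta-method standard error of the unbiased covariance
#'
#' Exact form: `Var(s_xy) = (N m22 - (N-2) s_xy^2 - s_xy^2/N) / (N-1)^2`
#' with `m22` the joint (2,2) central moment (ML); the large-sample form
#' drops the lower-order terms, `Var = (m22 - s_xy^2)/N`.  Special cases: a
#' constant variable gives SE 0; a covariance at the Frechet bound implied
#' by the margins has no SE (boundary error).
#'
#' @inheritParams se_mean
#' @param var1,var2 Item names/indices; `var1` may instead be a [score_spec]
#'   producing two derived variables (e.g. `spec_item_rest()`).
#' @param large_N Use the large-sample simplification.
#' @return A one-row tibble.
#' @export
se_covariance <- function(scores, var1 = NULL, var2 = NULL, large_N = FALSE) {
  v <- two_var_patterns(scores, var1, var2)
  w <- wcov2(v$x, v$y, v$n)
  flags <- character()
  vx <- wcov2(v$x, v$x, v$n)$s
  vy <- wcov2(v$y, v$y, v$n)$s
  if (vx <= 0 || vy <= 0) {
    return(new_estimate("covariance", "x,y", w$s, 0,
                        method = if (large_N) "closed-form-large-N" else "closed-form",
                        flags = "constant-variable", n_obs = w$N))
  }
  if (!identical(v$x, v$y)) {
    fb <- frechet_cov_bounds(v$x, v$y, v$n)
    spread <- max(fb["upper"] - fb["lower"], atol_boundary)
    if (w$s >= fb["upper"] - atol_boundary * spread ||
        w$s <= fb["lower"] + atol_boundary * spread) {
      boundary_error(
        "Covariance equals the Frechet bound implied by the margins; the SE does not exist.",
        coefficient = "covariance")
    }
    if (w$s >= fb["upper"] - near_boundary * spread ||
        w$s <= fb["lower"] + near_boundary * spread) {
      flags <- c(flags, "near-boundary")
    }
  }
  variance <- if (large_N) {
    (w$m22 - w$s^2) / w$N
  } else {
    (w$N * w$m22 - (w$N - 2) * w$s^2 - w$s^2 / w$N) / (w$N - 1)^2
  }
  new_estimate("covariance", "x,y", w$s, sqrt(max(variance, 0)),
               method = if (large_N) "closed-form-large-N" else "closed-form",
               flags = flags, n_obs = w$N)
}

#' Delta-method standard errors of the variance and standard deviation
#'
#' The variance is the covariance of a variable with itself; the SD follows
#' by the delta method for the square root, `SE(s) = SE(s^2) / (2 s)`.  A
#' variance sitting on the boundary of its parameter space (the delta
#' variance degenerates to zero while the variable is non-constant, e.g. a
#' dichotomous item with sample proportion exactly 1/2) has no SE and raises
#' a boundary error; within 0.1% of the two-point maximum
#' `N (max-min)^2 / (4(N-1))` the estimate is flagged `near-boundary`.
#'
#' @inheritParams se_mean
#' @param large_N Use the large-sample simplification.
#' @return A one-row tibble.
#' @export
se_variance <- function(scores, variable = NULL, large_N = FALSE) {
  v <- one_var_patterns(scores, variable)
  w <- wcov2(v$x, v$x, v$n)
  method <- if (large_N) "closed-form-large-N" else "closed-form"
  if (w$s <= 0) {
    return(new_estimate("variance", "x", w$s, 0, method,
                        flags = "constant-variable", n_obs = w$N))
  }
  variance <- if (large_N) {
    (w$m22 - w$s^2) / w$N
  } else {
    (w$N * w$m22 - (w$N - 2) * w$s^2 - w$s^2 / w$N) / (w$N - 1)^2
  }
  scale <- w$s^2 / w$N
  if (variance <= atol_boundary * scale) {
    boundary_error(
      "Sample variance lies on the boundary of its parameter space; the SE does not exist.",
      coefficient = "variance")
  }
  flags <- character()
  vmax <- w$N * diff(range(v$x))^2 / (4 * (w$N - 1))
  if (w$s >= (1 - near_boundary) * vmax) flags <- c(flags, "near-boundary")
  new_estimate("variance", "x", w$s, sqrt(variance), method,
               flags = flags, n_obs = w$N)
}

#' @rdname se_variance
#' @export
se_sd <- function(scores, variable = NULL, large_N = FALSE) {
  est <- se_variance(scores, variable, large_N = large_N)
  if (est$estimate <= 0) abort("Standard deviation is zero; its SE is undefined.")
  s <- sqrt(est$estimate)
  new_estimate("sd", "x", s, est$se / (2 * s), est$method,
               flags = est$flags[[1]], n_obs = est$n_obs)
}

# correlation gradient at a possibly overridden covariance (epsilon device)
cor_delta_se <- function(x, y, n, s_xy = NULL) {
  w <- wcov2(x, y, n)
  wx <- wcov2(x, x, n)
  wy <- wcov2(y, y, n)
  sxy <- s_xy %||% w$s
  sx <- sqrt(wx$s)
  sy <- sqrt(wy$s)
  r <- sxy / (sx * sy)
  N <- w$N
  g_cov <- (w$dx * w$dy - sxy) / (N - 1)
  g_vx <- (w$dx^2 - wx$s) / (N - 1)
  g_vy <- (w$dy^2 - wy$s) / (N - 1)
  g <- g_cov / (sx * sy) - (r / 2) * (g_vx / wx$s + g_vy / wy$s)
  sqrt(max(delta_var(g, n), 0))
}

#' Delta-method standard error of the product-moment correlation
#'
#' Closed form via the analytic gradient of r = s_xy/(s_x s_y) with respect
#' to the pattern frequencies.  Special cases: zero variance -> error;
#' |r| = 1 -> SE 0 with a boundary flag; |r| within 0.001 of 1 -> the SE is
#' computed by the epsilon-limit device (r replaced by sign(r)(1 - eps),
#' eps descending until the value stabilises).
#'
#' @inheritParams se_covariance
#' @return A one-row tibble.
#' @export
se_correlation <- function(scores, var1 = NULL, var2 = NULL) {
  v <- two_var_patterns(scores, var1, var2)
  w <- wcov2(v$x, v$y, v$n)
  wx <- wcov2(v$x, v$x, v$n)
  wy <- wcov2(v$y, v$y, v$n)
  if (wx$s <= 0 || wy$s <= 0) {
    abort("A variable has zero variance; the correlation and its SE are undefined.")
  }
  sx <- sqrt(wx$s)
  sy <- sqrt(wy$s)
  r <- w$s / (sx * sy)
  if (abs(r) > 1 + 1e-8) abort("Computed |r| > 1; inconsistent input.")
  if (abs(r) >= 1 - atol_boundary) {
    return(new_estimate("correlation", "x,y", sign(r), 0, "closed-form",
                        flags = "boundary", n_obs = w$N))
  }
  if (1 - abs(r) < near_boundary) {
    lim <- eps_limit(function(e) {
      cor_delta_se(v$x, v$y, v$n, s_xy = sign(r) * (1 - e) * sx * sy)
    })
    return(new_estimate("correlation", "x,y", r, lim$value, "closed-form",
                        flags = c("near-boundary", "epsilon-device"), n_obs = w$N))
  }
  new_estimate("correlation", "x,y", r, cor_delta_se(v$x, v$y, v$n),
               method = "closed-form", n_obs = w$N)
}

#' Delta-method standard error of the split-half coefficient
#'
#' SH = 2 r_AB / (1 + r_AB) for the correlation r_AB of the two half sums;
#' by the delta method SE(SH) = 2 / (1 + r_AB)^2 * SE(r_AB).
#'
#' @inheritParams se_mean
#' @param partition List with `half_a` and `half_b` item sets; ignored when
#'   `scores` is already a two-column (half-sum) pattern table.
#' @return A one-row tibble.
#' @export
se_split_half <- function(scores, partition = NULL) {
  pt <- if (inherits(scores, "score_patterns")) {
    scores
  } else {
    partition <- partition %||% split_odd_even(ncol(as_score_matrix(scores)))
    score_patterns(scores, spec_halves(partition$half_a, partition$half_b))
  }
  est_r <- se_correlation(pt)
  r <- est_r$estimate
  if (r <= -1 + atol_boundary) {
    boundary_error("Half-sum correlation is -1; split-half SE undefined.",
                   coefficient = "split_half")
  }
  sh <- 2 * r / (1 + r)
  new_estimate("split_half", "halves", sh, 2 / (1 + r)^2 * est_r$se,
               method = "closed-form", flags = est_r$flags[[1]], n_obs = est_r$n_obs)
}

# Lambda SEs --------------------------------------------------------------------

lambda_gradients <- function(pt) {
  R <- pt$R
  n <- pt$n
  N <- sum(n)
  k <- ncol(R)
  means <- drop(crossprod(R, n)) / N
  D <- sweep(R, 2, means)
  S <- crossprod(D, D * n) / N * N / (N - 1)
  dX <- rowSums(D)
  Tsum <- sum(diag(S))
  sX2 <- sum(S)
  S0 <- S
  diag(S0) <- 0
  C2 <- sum(S0^2)
  g_T <- (rowSums(D^2) - Tsum) / (N - 1)
  g_X <- (dX^2 - sX2) / (N - 1)
  g_C2 <- 2 * (rowSums((D %*% S0) * D) - C2) / (N - 1)
  list(N = N, k = k, S = S, Tsum = Tsum, sX2 = sX2, C2 = C2,
       g_T = g_T, g_X = g_X, g_C2 = g_C2)
}

#' Delta-method standard errors of Guttman's lambda coefficients
#'
#' Closed forms via the analytic gradients of lambda-1, lambda-2 and
#' lambda-3 (Cronbach's alpha) with respect to the pattern frequencies.
#' SE(lambda3) = k/(k-1) * SE(lambda1) exactly.  When all inter-item
#' covariances are zero the sqrt term of lambda-2 is not differentiable and
#' the SE is obtained by the epsilon-limit device (flagged).
#'
#' @inheritParams se_mean
#' @return A one-row tibble.
#' @export
se_lambda1 <- function(scores) se_lambda13(scores, which = "lambda1")

#' @rdname se_lambda1
#' @export
se_lambda3 <- function(scores) se_lambda13(scores, which = "lambda3")

se_lambda13 <- function(scores, which) {
  pt <- pattern_of(scores, spec_items())
  if (ncol(pt$R) < 2) abort("Lambda coefficients need at least two items.")
  L <- lambda_gradients(pt)
  if (L$sX2 <= 0) abort("Sum-score variance is zero; lambda coefficients undefined.")
  g_l1 <- (L$Tsum * L$g_X - L$sX2 * L$g_T) / L$sX2^2
  fac <- if (which == "lambda3") L$k / (L$k - 1) else 1
  est <- fac * (1 - L$Tsum / L$sX2)
  new_estimate(which, "scale", est, fac * sqrt(max(delta_var(g_l1, pt$n), 0)),
               method = "closed-form", n_obs = L$N)
}

#' @rdname se_lambda1
#' @export
se_lambda2 <- function(scores) {
  pt <- pattern_of(scores, spec_items())
  if (ncol(pt$R) < 2) abort("Lambda coefficients need at least two items.")
  L <- lambda_gradients(pt)
  if (L$sX2 <= 0) abort("Sum-score variance is zero; lambda coefficients undefined.")
  kap <- L$k / (L$k - 1)
  g_l1 <- (L$Tsum * L$g_X - L$sX2 * L$g_T) / L$sX2^2
  est <- 1 - L$Tsum / L$sX2 + sqrt(kap * L$C2) / L$sX2
  se_at <- function(C2) {
    term <- sqrt(kap * C2)
    g <- g_l1 + (kap * L$g_C2 / (2 * term)) / L$sX2 - term * L$g_X / L$sX2^2
    sqrt(max(delta_var(g, pt$n), 0))
  }
  c2_scale <- max(L$C2, (L$Tsum / L$k)^2)
  if (L$C2 <= atol_boundary * c2_scale) {
    lim <- eps_limit(function(e) se_at(e * (L$Tsum / L$k)^2))
    return(new_estimate("lambda2", "scale", est, lim$value, "closed-form",
                        flags = c("zero-covariances", "epsilon-device"), n_obs = L$N))
  }
  new_estimate("lambda2", "scale", est, se_at(L$C2), "closed-form", n_obs = L$N)
}

# Generic engine ----------------------------------------------------------------

#' Generic delta-method SE from an exp-log chain
#'
#' Evaluates a scalar coefficient chain at the observed frequencies and
#' returns the delta-method SE `sqrt(G V(n) G')`.  For chains homogeneous of
#' order 0 the simplified form `G diag(n) G'` is also computed and checked
#' to agree.
#'
#' @param chain An `explog_chain` with scalar output.
#' @param table A `score_patterns` table whose frequencies match the chain
#'   input length.
#' @return A one-row tibble; the variance under both forms is attached as
#'   attributes `var_full` and `var_homog` (the latter `NA` when the chain
#'   is not homogeneous of order 0).
#' @export
se_generic <- function(chain, table) {
  n <- if (inherits(table, "score_patterns")) table$n else as.numeric(table)
  value <- chain_eval(chain, n)
  if (length(value) != 1) abort("`se_generic()` expects a scalar chain; see `generic_delta_cov()`.")
  G <- chain_jacobian(chain, n)
  N <- sum(n)
  var_full <- drop(G %*% multinomial_cov(n) %*% t(G))
  var_homog <- NA_real_
  if (chain_homogeneous0(chain, n)) {
    var_homog <- drop((G * n) %*% t(G))
    # the two forms differ by (G n)^2 / N, which is exactly zero for
    # order-0 homogeneous chains; allow for cancellation noise in G and for
    # locally constant coefficients whose variance is numerically zero
    if (var_full > 1e-25 && abs(var_homog - var_full) > 1e-6 * var_full) {
      warn("Homogeneous-form variance differs from the full form beyond tolerance.")
    }
  }
  out <- new_estimate("chain", "chain", value, sqrt(max(var_full, 0)),
                      method = "generic-delta", n_obs = N)
  attr(out, "var_full") <- var_full
  attr(out, "var_homog") <- var_homog
  out
}

#' Delta-method covariance matrix of a vector coefficient chain
#'
#' @inheritParams se_generic
#' @return The t x t matrix `G V(n) G'`.
#' @export
generic_delta_cov <- function(chain, table) {
  n <- if (inherits(table, "score_patterns")) table$n else as.numeric(table)
  G <- chain_jacobian(chain, n)
  G %*% multinomial_cov(n) %*% t(G)
}

#' Covariance matrix of the stacked inter-item covariance estimates
#'
#' The estimated asymptotic covariance matrix W of vec(S), obtained by
#' feeding the vec(S) exp-log chain through the generic delta-method engine.
#' Its diagonal equals the squared SEs of the corresponding variances and
#' covariances.
#'
#' @inheritParams descriptives
#' @return A list of class `coefficient_covariance` with elements `W`
#'   (k^2 x k^2 matrix with pair labels), `k`, and `flagged` (entries whose
#'   variance degenerates to zero, i.e. boundary cases).
#' @export
coefficient_covariance <- function(scores) {
  pt <- pattern_of(scores, spec_items())
  k <- ncol(pt$R)
  if (k < 2) abort("Need at least two items.")
  chain <- chain_vec_s(pt$R)
  W <- generic_delta_cov(chain, pt)
  labs <- as.vector(outer(seq_len(k), seq_len(k), function(i, j) paste0("s", i, j)))
  dimnames(W) <- list(labs, labs)
  dW <- diag(W)
  flagged <- labs[dW <= atol_boundary * max(dW, 1e-300)]
  structure(list(W = W, k = k, flagged = flagged), class = "coefficient_covariance")
}

#' @export
print.coefficient_covariance <- function(x, ...) {
  cat("<coefficient_covariance> of vec(S), k =", x$k, "items\n")
  print(round(x$W, 6))
  if (length(x$flagged)) cat("flagged boundary entries:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
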