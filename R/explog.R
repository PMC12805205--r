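# Generalized exp-log chains.
#
# A coefficient g(n) is represented as a composition of steps
#   v_j = phi_j(A_j v_{j-1}),   v_0 = n,
# where A_j is a design matrix and phi_j an elementwise transform.  The
# Jacobian follows from the chain rule: G_j = D_j A_j G_{j-1} with D_j the
# diagonal of phi_j' evaluated at A_j v_{j-1}.  Chains are pure data, so the
# generic delta-method engine and the closed-form standard errors can be
# compared mechanically, and chains can be serialized to JSON.

explog_transforms <- c("none", "log", "exp", "sqrt", "reciprocal", "square")

transform_fun <- function(tag) {
  switch(tag,
    none = identity,
    log = log,
    exp = exp,
    sqrt = sqrt,
    reciprocal = function(u) 1 / u,
    square = function(u) u^2
  )
}

transform_deriv <- function(tag, u, v) {
  switch(tag,
    none = rep(1, length(u)),
    log = 1 / u,
    exp = v,
    sqrt = 1 / (2 * v),
    reciprocal = -1 / u^2,
    square = 2 * u
  )
}

#' Build a step of a generalized exp-log chain
#'
#' @param A Design matrix (rows = outputs, columns = inputs of the step).
#' @param transform Elementwise transform applied after the matrix product:
#'   one of `"none"`, `"log"`, `"exp"`, `"sqrt"`, `"reciprocal"`, `"square"`.
#' @return An object of class `explog_step`.
#' @export
explog_step <- function(A, transform = "none") {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  transform <- match.arg(transform, explog_transforms)
  structure(list(A = A, transform = transform), class = "explog_step")
}

#' Build a generalized exp-log chain
#'
#' @param ... `explog_step` objects (or a single list of them), applied in
#'   order to the frequency vector.
#' @return An object of class `explog_chain` with fields `steps`,
#'   `input_length` (C) and `output_length` (t).
#' @examples
#' # mean of a variable with values (0, 1) observed with frequencies (2, 2):
#' ch <- explog_chain(
#'   explog_step(rbind(c(0, 1), c(1, 1)), "log"),
#'   explog_step(cbind(1, -1), "exp")
#' )
#' chain_eval(ch, c(2, 2))
#' @export
explog_chain <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && !inherits(steps[[1]], "explog_step")) steps <- steps[[1]]
  if (!all(vapply(steps, inherits, logical(1), "explog_step"))) {
    abort("All chain components must be explog_step objects.")
  }
  for (j in seq_along(steps)[-1]) {
    if (ncol(steps[[j]]$A) != nrow(steps[[j - 1]]$A)) {
      abort(paste0("Step ", j, " has ", ncol(steps[[j]]$A),
                   " columns but step ", j - 1, " produces ",
                   nrow(steps[[j - 1]]$A), " outputs."))
    }
  }
  structure(
    list(
      steps = steps,
      input_length = ncol(steps[[1]]$A),
      output_length = nrow(steps[[length(steps)]]$A)
    ),
    class = "explog_chain"
  )
}

#' @export
print.explog_chain <- function(x, ...) {
  cat("<explog_chain> ", x$input_length, " -> ", x$output_length,
      " via ", length(x$steps), " step(s): ",
      paste(vapply(x$steps, function(s) {
        paste0(s$transform, "[", nrow(s$A), "x", ncol(s$A), "]")
      }, character(1)), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

check_chain_input <- function(chain, n) {
  if (!inherits(chain, "explog_chain")) abort("`chain` must be an explog_chain.")
  n <- as.numeric(n)
  if (length(n) != chain$input_length) {
    abort(paste0("`n` has length ", length(n), " but the chain expects ",
                 chain$input_length, "."))
  }
  n
}

#' Evaluate an exp-log chain at a frequency vector
#'
#' @param chain An `explog_chain`.
#' @param n Numeric vector of (positive) frequencies of length C.
#' @return Numeric vector of length t, the value of g(n).
#' @export
chain_eval <- function(chain, n) {
  n <- check_chain_input(chain, n)
  v <- n
  for (j in seq_along(chain$steps)) {
    s <- chain$steps[[j]]
    u <- drop(s$A %*% v)
    if (s$transform == "log" && any(u <= 0)) {
      boundary_error(paste0(
        "Step ", j, ": log applied to a non-positive argument (",
        "offending element(s): ", paste(which(u <= 0), collapse = ", "), ")."
      ))
    }
    if (s$transform %in% c("sqrt") && any(u < 0)) {
      boundary_error(paste0("Step ", j, ": sqrt applied to a negative argument."))
    }
    if (s$transform == "reciprocal" && any(u == 0)) {
      boundary_error(paste0("Step ", j, ": reciprocal applied to zero."))
    }
    v <- transform_fun(s$transform)(u)
  }
  v
}

#' Chain-rule Jacobian of an exp-log chain
#'
#' Returns the t x C matrix of partial derivatives of the chain output with
#' respect to the frequency vector, computed step by step: each step
#' contributes a diagonal scaling by the transform derivative times its
#' design matrix.
#'
#' @inheritParams chain_eval
#' @return A t x C numeric matrix.
#' @export
chain_jacobian <- function(chain, n) {
  n <- check_chain_input(chain, n)
  v <- n
  G <- diag(1, nrow = chain$input_length)
  for (j in seq_along(chain$steps)) {
    s <- chain$steps[[j]]
    u <- drop(s$A %*% v)
    if (s$transform == "log" && any(u <= 0)) {
      boundary_error(paste0("Step ", j, ": log applied to a non-positive argument."))
    }
    vnew <- transform_fun(s$transform)(u)
    D <- transform_deriv(s$transform, u, vnew)
    G <- (s$A %*% G) * D
    v <- vnew
  }
  G
}

#' Test whether a chain is homogeneous of order zero
#'
#' A chain is homogeneous of order 0 when g(c n) = g(n) for every positive
#' constant c, i.e. when the coefficient depends on the observed proportions
#' only.  For such chains the delta-method variance simplifies from
#' G (diag(n) - n n'/N) G' to G diag(n) G', because G n = 0.  The check
#' evaluates the chain at scaled inputs and, when scale invariance holds,
#' additionally verifies G n ~ 0.
#'
#' @inheritParams chain_eval
#' @param scales Positive constants used for the scale-invariance probe.
#' @param rtol Relative tolerance of the probe.
#' @return `TRUE` or `FALSE`.
#' @export
chain_homogeneous0 <- function(chain, n, scales = c(0.5, 2, 10), rtol = 1e-9) {
  n <- check_chain_input(chain, n)
  g0 <- chain_eval(chain, n)
  ok <- all(vapply(scales, function(cc) {
    gc <- try(chain_eval(chain, cc * n), silent = TRUE)
    if (inherits(gc, "try-error")) return(FALSE)
    all(abs(gc - g0) <= rtol * pmax(abs(g0), 1))
  }, logical(1)))
  if (!ok) return(FALSE)
  G <- chain_jacobian(chain, n)
  gn <- drop(G %*% n)
  all(abs(gn) <= 1e-8 * max(abs(G), 1))
}

# JSON serialization ---------------------------------------------------------

#' Serialize an exp-log chain to JSON (and back)
#'
#' Chains are pure data; the JSON form records each step's design matrix and
#' transform tag.  Mainly useful for debugging and for inspecting the chains
#' the closed-form standard errors are checked against.
#'
#' @param chain An `explog_chain`.
#' @param json A JSON string produced by `chain_to_json()`.
#' @return `chain_to_json()` returns a JSON string; `chain_from_json()` an
#'   `explog_chain`.
#' @export
chain_to_json <- function(chain) {
  stopifnot(inherits(chain, "explog_chain"))
  jsonlite::toJSON(
    lapply(chain$steps, function(s) list(A = s$A, transform = s$transform)),
    digits = NA, auto_unbox = TRUE
  )
}

#' @rdname chain_to_json
#' @export
chain_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  explog_chain(lapply(raw, function(s) explog_step(s$A, s$transform)))
}
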