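# Response-pattern tables: the sufficient statistic of the multinomial model.
#
# A reliability coefficient never needs the raw N x d score matrix, only the
# C unique derived-score patterns R and their frequencies n.  All standard
# errors in this package are functions of (R, n).

#' Score-derivation specifications
#'
#' A reliability analysis looks at different derived variables depending on
#' the coefficient: a single item, a pair of items, an item and its rest
#' score (sum score minus the item), the two half sums of a split, the sum
#' score, or all item scores jointly.  These helpers build a specification
#' that [score_patterns()] resolves against the columns of a score matrix.
#'
#' @param item,item1,item2 Column name or index of an item.
#' @param half_a,half_b Character or integer vectors of items forming the two
#'   halves; they must partition the full item set.
#' @return An object of class `score_spec`.
#' @examples
#' x <- data.frame(a = c(0, 1, 1), b = c(1, 1, 0), c = c(0, 0, 1))
#' score_patterns(x, spec_item_rest("a"))
#' @name score_spec
NULL

new_score_spec <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "score_spec")
}

#' @rdname score_spec
#' @export
spec_item <- function(item) new_score_spec("item", item = item)

#' @rdname score_spec
#' @export
spec_pair <- function(item1, item2) new_score_spec("pair", item1 = item1, item2 = item2)

#' @rdname score_spec
#' @export
spec_item_rest <- function(item) new_score_spec("item_rest", item = item)

#' @rdname score_spec
#' @export
spec_halves <- function(half_a, half_b) new_score_spec("halves", half_a = half_a, half_b = half_b)

#' @rdname score_spec
#' @export
spec_sum <- function() new_score_spec("sum")

#' @rdname score_spec
#' @export
spec_items <- function() new_score_spec("items")

#' @export
print.score_spec <- function(x, ...) {
  cat("<score_spec:", x$kind, ">\n")
  invisible(x)
}

resolve_items <- function(scores, items) {
  nm <- colnames(scores)
  if (is.character(items)) {
    miss <- setdiff(items, nm)
    if (length(miss) > 0) {
      abort(paste0("Unknown item(s): ", paste(miss, collapse = ", ")))
    }
    match(items, nm)
  } else {
    idx <- as.integer(items)
    if (any(idx < 1L | idx > ncol(scores))) abort("Item index out of range.")
    idx
  }
}

as_score_matrix <- function(scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores) || !is.numeric(scores)) {
    abort("`scores` must be a numeric matrix or data frame of item scores.")
  }
  if (nrow(scores) == 0 || ncol(scores) == 0) abort("`scores` is empty.")
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort("`scores` contains missing or non-finite values; complete data are required.")
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("item", seq_len(ncol(scores)))
  }
  scores
}

#' Derive the analysis variables selected by a score spec
#'
#' @param scores A numeric matrix or data frame (respondents x items).
#' @param spec A [score_spec] object.
#' @return A numeric matrix (respondents x derived variables) with labels.
#' @export
derive_scores <- function(scores, spec) {
  scores <- as_score_matrix(scores)
  if (!inherits(spec, "score_spec")) abort("`spec` must be a score_spec.")
  nm <- colnames(scores)
  switch(spec$kind,
    item = {
      j <- resolve_items(scores, spec$item)
      out <- scores[, j, drop = FALSE]
      out
    },
    pair = {
      j1 <- resolve_items(scores, spec$item1)
      j2 <- resolve_items(scores, spec$item2)
      if (j1 == j2) abort("`spec_pair()` needs two distinct items.")
      scores[, c(j1, j2), drop = FALSE]
    },
    item_rest = {
      j <- resolve_items(scores, spec$item)
      rest <- rowSums(scores[, -j, drop = FALSE])
      out <- cbind(scores[, j], rest)
      colnames(out) <- c(nm[j], paste0("rest_", nm[j]))
      out
    },
    halves = {
      a <- resolve_items(scores, spec$half_a)
      b <- resolve_items(scores, spec$half_b)
      if (length(intersect(a, b)) > 0 || length(union(a, b)) != ncol(scores) ||
          length(a) == 0 || length(b) == 0) {
        abort("Halves must be two non-empty sets that partition the items.")
      }
      out <- cbind(rowSums(scores[, a, drop = FALSE]), rowSums(scores[, b, drop = FALSE]))
      colnames(out) <- c("half_A", "half_B")
      out
    },
    sum = {
      out <- matrix(rowSums(scores), ncol = 1)
      colnames(out) <- "sum_score"
      out
    },
    items = scores,
    abort("Unknown score_spec kind.")
  )
}

#' Compress scores into a response-pattern table
#'
#' Collapses an N x d matrix of derived scores into the C unique observed
#' response patterns and their frequencies -- the sufficient statistic of the
#' multinomial model.  Patterns are sorted lexicographically with the last
#' column changing fastest, and only observed patterns (frequency >= 1) are
#' kept.  Scores may be real-valued; patterns are keyed on exact equality.
#'
#' @inheritParams derive_scores
#' @param spec A [score_spec]; defaults to all items.
#' @return An object of class `score_patterns`: a list with elements `R`
#'   (C x d pattern matrix), `n` (frequency vector), `N`, and `C`.
#' @examples
#' score_patterns(data.frame(x = c(0, 1, 0, 1, 1)))
#' @export
score_patterns <- function(scores, spec = spec_items()) {
  values <- derive_scores(scores, spec)
  if (nrow(values) < 2) abort("At least two respondents are required.")
  new_pattern_table(values)
}

# Build a pattern table from a plain matrix of derived values.
new_pattern_table <- function(values) {
  d <- ncol(values)
  # Lexicographic sort (first column slowest, last fastest), then run-length
  # detection on exact row equality.  Exact double comparison is intentional:
  # patterns are keyed on exact values, never binned.
  o <- do.call(order, lapply(seq_len(d), function(j) values[, j]))
  vs <- values[o, , drop = FALSE]
  if (nrow(vs) > 1) {
    changed <- rowSums(vs[-1, , drop = FALSE] != vs[-nrow(vs), , drop = FALSE]) > 0
    starts <- c(1L, which(changed) + 1L)
  } else {
    starts <- 1L
  }
  ends <- c(starts[-1] - 1L, nrow(vs))
  R <- vs[starts, , drop = FALSE]
  n <- as.numeric(ends - starts + 1L)
  structure(
    list(R = R, n = n, N = nrow(values), C = length(n)),
    class = "score_patterns"
  )
}

#' @export
print.score_patterns <- function(x, ...) {
  cat("<score_patterns> C =", x$C, "patterns,", ncol(x$R), "variable(s), N =", x$N, "\n")
  tab <- tibble::as_tibble(as.data.frame(x$R))
  tab$n <- x$n
  print(tab, ...)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.score_patterns <- function(x, ...) {
  tab <- tibble::as_tibble(as.data.frame(x$R))
  tab$n <- x$n
  tab
}

#' Expand a pattern table back to raw rows
#'
#' Inverse of [score_patterns()] up to row order: each pattern is repeated
#' according to its frequency.
#'
#' @param table A `score_patterns` object.
#' @return A numeric matrix with `N` rows.
#' @export
expand_patterns <- function(table) {
  stopifnot(inherits(table, "score_patterns"))
  table$R[rep(seq_len(table$C), times = table$n), , drop = FALSE]
}

#' Estimated multinomial covariance matrix of the frequency vector
#'
#' Under multinomial sampling of response patterns the estimated covariance
#' matrix of the observed frequencies is `diag(n) - n n' / N`.  Its rows sum
#' to zero and it is positive semidefinite.
#'
#' @param table A `score_patterns` object, or a numeric frequency vector.
#' @return A C x C symmetric matrix.
#' @examples
#' multinomial_cov(score_patterns(data.frame(x = c(0, 1, 0, 1))))
#' @export
multinomial_cov <- function(table) {
  n <- if (inherits(table, "score_patterns")) table$n else as.numeric(table)
  if (any(n < 0)) abort("Frequencies must be non-negative.")
  N <- sum(n)
  diag(n, nrow = length(n)) - tcrossprod(n) / N
}
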