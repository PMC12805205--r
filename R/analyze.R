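# The top-level reliability analysis: every coefficient type with its
# delta-method SE and Wald CI in one tidy table.

#' Reliability analysis with standard errors
#'
#' Computes the full set of coefficients reported in a classical
#' reliability analysis -- item statistics, scale (sum-score) statistics,
#' rest statistics (scale with one item deleted), inter-item covariances
#' and correlations, item-rest and item-total correlations, the split-half
#' coefficient and Guttman's lambda-1/2/3 -- each with its multinomial
#' delta-method SE and Wald confidence interval.
#'
#' @param scores Respondents x items data frame or matrix of complete
#'   numeric item scores (k >= 1; reliability estimates need k >= 2).
#' @param level Confidence level for the Wald intervals.
#' @param partition Split-half partition (default odd/even); `NULL` to skip.
#' @param mean_se Which SE to attach to means: `"conventional"` (s/sqrt(N),
#'   the default, to be preferred) or `"ml"` (the uncorrected delta-method
#'   form).
#' @return An object of class `reliability_analysis`.  `tidy()` returns the
#'   coefficient table (columns `type`, `coefficient`, `item`, `estimate`,
#'   `se`, `lower`, `upper`, `flags`); `glance()` a one-row summary.
#' @examples
#' x <- data.frame(a = c(0, 0, 1, 1, 1), b = c(0, 1, 0, 1, 1), c = c(0, 1, 1, 0, 1))
#' fit <- reliability_analysis(x)
#' tidy(fit)
#' glance(fit)
#' @export
reliability_analysis <- function(scores, level = 0.95,
                                 partition = NULL,
                                 mean_se = c("conventional", "ml")) {
  mean_se <- match.arg(mean_se)
  scores <- as_score_matrix(scores)
  k <- ncol(scores)
  N <- nrow(scores)
  if (N < 2) abort("At least two respondents are required.")
  partition <- partition %||% if (k >= 2) split_odd_even(k) else NULL
  nm <- colnames(scores)
  rows <- list()
  push <- function(type, coefficient, item, est) {
    if (inherits(est, "error")) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        type = type, coefficient = coefficient, item = item,
        estimate = NA_real_, se = NA_real_, lower = NA_real_, upper = NA_real_,
        flags = list(c("undefined", conditionMessage(est)))
      )
      return(invisible())
    }
    ci <- tryCatch(wald_ci(est, level), error = function(e) NULL)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      type = type, coefficient = coefficient, item = item,
      estimate = est$estimate, se = est$se,
      lower = ci$lower %||% NA_real_, upper = ci$upper %||% NA_real_,
      flags = est$flags
    )
  }
  try_est <- function(expr) tryCatch(expr, error = function(e) e)

  # item statistics
  for (j in seq_len(k)) {
    pt <- new_pattern_table(scores[, j, drop = FALSE])
    push("item", "mean", nm[j], try_est(se_mean(pt, variant = mean_se)))
    push("item", "variance", nm[j], try_est(se_variance(pt)))
    push("item", "sd", nm[j], try_est(se_sd(pt)))
  }
  # scale statistics
  pt_sum <- new_pattern_table(matrix(rowSums(scores), ncol = 1))
  push("scale", "mean", NA_character_, try_est(se_mean(pt_sum, variant = mean_se)))
  push("scale", "variance", NA_character_, try_est(se_variance(pt_sum)))
  push("scale", "sd", NA_character_, try_est(se_sd(pt_sum)))
  if (k >= 2) {
    pt_items <- new_pattern_table(scores)
    push("scale", "lambda1", NA_character_, try_est(se_lambda1(pt_items)))
    push("scale", "lambda2", NA_character_, try_est(se_lambda2(pt_items)))
    push("scale", "lambda3", NA_character_, try_est(se_lambda3(pt_items)))
    if (!is.null(partition)) {
      push("scale", "split_half", NA_character_,
           try_est(se_split_half(scores, partition)))
    }
    # inter-item statistics
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        lab <- paste(nm[i], nm[j], sep = ",")
        pt <- new_pattern_table(scores[, c(i, j)])
        push("inter-item", "covariance", lab, try_est(se_covariance(pt)))
        push("inter-item", "correlation", lab, try_est(se_correlation(pt)))
      }
    }
    # item-rest statistics
    X <- rowSums(scores)
    for (j in seq_len(k)) {
      pt <- new_pattern_table(cbind(scores[, j], X - scores[, j]))
      push("item-rest", "item_rest_r", nm[j], try_est(se_correlation(pt)))
      pt_t <- new_pattern_table(cbind(scores[, j], X))
      push("item-rest", "item_total_r", nm[j], try_est(se_correlation(pt_t)))
    }
  }
  # rest statistics (one item deleted)
  if (k >= 3) {
    for (j in seq_len(k)) {
      reduced <- scores[, -j, drop = FALSE]
      pt_rest <- new_pattern_table(matrix(rowSums(reduced), ncol = 1))
      push("rest", "mean", nm[j], try_est(se_mean(pt_rest, variant = mean_se)))
      push("rest", "variance", nm[j], try_est(se_variance(pt_rest)))
      push("rest", "sd", nm[j], try_est(se_sd(pt_rest)))
      pt_red <- new_pattern_table(reduced)
      push("rest", "lambda3_deleted", nm[j], try_est(se_lambda3(pt_red)))
    }
  }
  structure(list(
    table = dplyr::bind_rows(rows),
    N = N, k = k, level = level, partition = partition
  ), class = "reliability_analysis")
}

#' @export
tidy.reliability_analysis <- function(x, ...) x$table

#' @export
glance.reliability_analysis <- function(x, ...) {
  get1 <- function(coefficient) {
    i <- which(x$table$type == "scale" & x$table$coefficient == coefficient)
    if (length(i) == 0) return(c(NA_real_, NA_real_))
    c(x$table$estimate[i[1]], x$table$se[i[1]])
  }
  a <- get1("lambda3")
  tibble::tibble(
    N = x$N, k = x$k, level = x$level,
    alpha = a[1], alpha_se = a[2],
    n_coefficients = nrow(x$table),
    n_undefined = sum(vapply(x$table$flags, function(f) "undefined" %in% f, logical(1)))
  )
}

#' @export
print.reliability_analysis <- function(x, digits = 3, ...) {
  cat("<reliability_analysis> N =", x$N, ", k =", x$k,
      ", level =", x$level, "\n")
  tab <- x$table
  tab$flags <- vapply(tab$flags, paste, character(1), collapse = ";")
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tibble::as_tibble(tab), n = Inf)
  invisible(x)
}
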