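# Simulation harness: replicate data generation, estimate every coefficient
# with its SE and Wald CI, and summarise scaled bias and coverage against
# Agresti-Coull bands.
#
# "True" SE is defined empirically as the SD of the coefficient across
# replications; scaled bias is 100 * (mean estimated SE - true SE) / true SE.
# Replications in which a coefficient sits on the boundary of its parameter
# space (its SE does not exist) are omitted and counted.

# One replication: every (coefficient, target, method) with estimate, se, CI.
replication_estimates <- function(X, k, partition, level, benchmarks = TRUE) {
  f <- focal_items(k)
  N <- nrow(X)
  singles <- list(
    itemA = X[, f$A, drop = FALSE],
    itemB = X[, f$B, drop = FALSE],
    sum = matrix(rowSums(X), ncol = 1)
  )
  pair_vals <- list(
    "A,B" = X[, c(f$A, f$B)],
    "A,restA" = cbind(X[, f$A], rowSums(X[, -f$A, drop = FALSE])),
    "B,restB" = cbind(X[, f$B], rowSums(X[, -f$B, drop = FALSE]))
  )
  halves <- cbind(
    rowSums(X[, partition$half_a, drop = FALSE]),
    rowSums(X[, partition$half_b, drop = FALSE])
  )
  pt_singles <- lapply(singles, new_pattern_table)
  pt_pairs <- lapply(pair_vals, new_pattern_table)
  pt_halves <- new_pattern_table(halves)
  pt_items <- new_pattern_table(X)

  rows <- list()
  add <- function(coefficient, target, method, expr, ci_fun = NULL) {
    res <- tryCatch(expr(), error = function(e) e)
    if (inherits(res, "error")) {
      omitted <- is_boundary_error(res)
      rows[[length(rows) + 1]] <<- tibble::tibble(
        coefficient = coefficient, target = target, method = method,
        estimate = NA_real_, se = NA_real_,
        lower = NA_real_, upper = NA_real_, omitted = omitted
      )
      return(invisible())
    }
    ci <- if (is.null(ci_fun)) wald_ci(res, level) else ci_fun(res)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      coefficient = coefficient, target = target, method = method,
      estimate = res$estimate, se = res$se,
      lower = ci$lower, upper = ci$upper, omitted = FALSE
    )
  }

  for (tg in names(pt_singles)) {
    pt <- pt_singles[[tg]]
    add("mean", tg, "delta", function() se_mean(pt))
    add("variance", tg, "delta", function() se_variance(pt))
    add("sd", tg, "delta", function() se_sd(pt))
    if (benchmarks) {
      w <- wcov2(pt$R[, 1], pt$R[, 1], pt$n)
      if (w$s > 0) {
        add("variance", tg, "benchmark-normal",
            function() normal_theory_se("variance", N, s = sqrt(w$s)))
        add("sd", tg, "benchmark-normal",
            function() normal_theory_se("sd", N, s = sqrt(w$s)))
      }
    }
  }
  for (tg in names(pt_pairs)) {
    pt <- pt_pairs[[tg]]
    add("covariance", tg, "delta", function() se_covariance(pt))
    add("correlation", tg, "delta", function() se_correlation(pt))
    if (benchmarks) {
      w <- wcov2(pt$R[, 1], pt$R[, 2], pt$n)
      sx <- sqrt(wcov2(pt$R[, 1], pt$R[, 1], pt$n)$s)
      sy <- sqrt(wcov2(pt$R[, 2], pt$R[, 2], pt$n)$s)
      add("covariance", tg, "benchmark-normal",
          function() normal_theory_se("covariance", N, s_x = sx, s_y = sy, s_xy = w$s))
      r <- w$s / (sx * sy)
      if (abs(r) < 1) {
        add("correlation", tg, "benchmark-fisher-z",
            function() new_estimate("correlation", tg, r, NA_real_, "benchmark-fisher-z"),
            ci_fun = function(res) fisher_z_ci(r, N, level))
      }
    }
  }
  add("split_half", "scale", "delta", function() se_split_half(pt_halves))
  add("lambda1", "scale", "delta", function() se_lambda1(pt_items))
  add("lambda2", "scale", "delta", function() se_lambda2(pt_items))
  add("lambda3", "scale", "delta", function() se_lambda3(pt_items))
  if (benchmarks) {
    a_hat <- lambda3_from_pt(pt_items)
    if (a_hat < 1) {
      add("lambda3", "scale", "benchmark-feldt",
          function() new_estimate("lambda3", "scale", a_hat, NA_real_, "benchmark-feldt"),
          ci_fun = function(res) feldt_ci(a_hat, N, k, level))
    }
  }
  dplyr::bind_rows(rows)
}

lambda3_from_pt <- function(pt) {
  S <- wmoments(pt$R, pt$n)$S
  p <- lambda_parts(S)
  p$k / (p$k - 1) * (1 - p$Tsum / p$sX2)
}

#' Run the bias and coverage study for a simulation design
#'
#' For each replication a dataset is generated, every coefficient is
#' estimated with its delta-method SE and Wald CI (plus benchmark SEs and
#' CIs), and results are aggregated against the cell's population values:
#' true SE (the SD of the estimates), mean estimated SE, scaled bias, and
#' coverage of the level-`level` CI, judged against the Agresti-Coull band
#' for the number of used replications.  Replications where an SE does not
#' exist (parameter-space boundary) are omitted and counted.
#'
#' @param design A [sim_design()].
#' @param reps Number of replications (defaults to the design's).
#' @param level CI level.
#' @param pop_M Population sample size for the cell's coefficient values.
#' @param partition Split-half partition (default odd/even).
#' @param benchmarks Include the normal-theory / Fisher-Z / Feldt benchmarks.
#' @param seed Master seed for replication child seeds (defaults to the
#'   design's); the same design and seed give identical results.
#' @return An object of class `se_study`; `tidy()` returns the per-cell
#'   results table.
#' @export
run_study <- function(design, reps = design$replications, level = 0.95,
                      pop_M = 1e6, partition = split_odd_even(design$k),
                      benchmarks = TRUE, seed = design$seed) {
  if (reps < 2) abort("Need at least two replications.")
  params <- sample_item_params(design, seed = design$seed)
  pop <- population_values(design, params, M = pop_M, seed = design$seed + 1L)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, reps)
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    X <- simulate_responses(design, params, seed = child_seeds[r])
    per_rep[[r]] <- replication_estimates(X, design$k, partition, level, benchmarks)
    per_rep[[r]]$rep <- r
  }
  all_est <- dplyr::bind_rows(per_rep)
  results <- all_est |>
    dplyr::left_join(pop, by = c("coefficient", "target")) |>
    dplyr::group_by(.data$coefficient, .data$target, .data$method) |>
    dplyr::summarise(
      pop_value = .data$value[1],
      true_se = stats::sd(.data$estimate[!is.na(.data$lower)]),
      mean_se = mean(.data$se[!is.na(.data$lower)]),
      coverage = 100 * mean(.data$lower <= .data$value[1] &
                              .data$value[1] <= .data$upper, na.rm = TRUE),
      n_used = sum(!is.na(.data$lower)),
      n_omitted = sum(is.na(.data$lower)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      scaled_bias = 100 * (.data$mean_se - .data$true_se) / .data$true_se,
      band_lower = vapply(.data$n_used, function(m) coverage_band(m, level)[["lower"]], numeric(1)),
      band_upper = vapply(.data$n_used, function(m) coverage_band(m, level)[["upper"]], numeric(1)),
      flag_coverage = .data$coverage < .data$band_lower | .data$coverage > .data$band_upper,
      flag_bias = !is.na(.data$scaled_bias) & abs(.data$scaled_bias) > 10
    ) |>
    dplyr::arrange(.data$coefficient, .data$target, .data$method)
  structure(list(
    results = results, design = design, population = pop,
    level = level, reps = reps
  ), class = "se_study")
}

#' @export
tidy.se_study <- function(x, ...) x$results

#' @export
glance.se_study <- function(x, ...) {
  tibble::tibble(
    model = x$design$model, N = x$design$N, k = x$design$k,
    dims = x$design$dims, replications = x$reps, level = x$level,
    n_cells = nrow(x$results),
    n_flagged_coverage = sum(x$results$flag_coverage, na.rm = TRUE),
    n_flagged_bias = sum(x$results$flag_bias, na.rm = TRUE)
  )
}

#' Formatted study report
#'
#' Three-decimal display of the study results with the flagging rules used
#' in the tables of the simulation study: coverage outside the
#' Agresti-Coull band and |scaled bias| > 10% are marked with an asterisk.
#'
#' @param x An `se_study` object.
#' @return A tibble of formatted character columns.
#' @export
study_report <- function(x) {
  stopifnot(inherits(x, "se_study"))
  r <- x$results
  if (nrow(r) == 0) {
    return(tibble::tibble(coefficient = character(), target = character(),
                          method = character(), bias = character(),
                          coverage = character()))
  }
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 3, format = "f"))
  tibble::tibble(
    coefficient = r$coefficient,
    target = r$target,
    method = r$method,
    pop_value = fmt(r$pop_value),
    true_se = fmt(r$true_se),
    mean_se = fmt(r$mean_se),
    bias = paste0(fmt(r$scaled_bias), ifelse(r$flag_bias, "*", "")),
    coverage = paste0(formatC(r$coverage, digits = 1, format = "f"),
                      ifelse(r$flag_coverage, "*", "")),
    used = as.character(r$n_used),
    omitted = as.character(r$n_omitted)
  )
}

#' @export
print.se_study <- function(x, ...) {
  cat("<se_study>", x$design$model, "N =", x$design$N, "k =", x$design$k,
      "replications =", x$reps, "\n")
  print(study_report(x), n = Inf)
  invisible(x)
}
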