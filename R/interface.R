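# File-level interface: strict CSV input, result serialization, and the
# functions behind the command-line script (inst/cli/relcli.R).

#' Read a score matrix from CSV
#'
#' Strict parsing: a header row of item labels, one respondent per row,
#' numeric cells only.  Any missing or non-numeric cell is an error --
#' the multinomial framework assumes complete data.
#'
#' @param path CSV file path.
#' @return A tibble of item scores.
#' @export
read_scores <- function(path) {
  out <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    na = character(), progress = FALSE)
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed cells in ", path, " (first: row ",
                 probs$row[1], ", col ", probs$col[1], ")."))
  }
  if (anyNA(out)) abort(paste0("Missing values in ", path, "; complete data required."))
  if (ncol(out) < 1 || nrow(out) < 2) abort("Need at least 2 rows and 1 column.")
  out
}

#' Write a score matrix to CSV
#'
#' @param scores Matrix or data frame of scores.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(scores)), path)
  invisible(path)
}

#' Load an analysis/simulation configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON file mapping onto the arguments of
#' [sim_design()], [reliability_analysis()] and [run_study()].
#'
#' @param path Config file path.
#' @return A named list.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    out <- yaml::read_yaml(path)
    # YAML 1.1 parses bare N/Y keys as booleans; map them back
    names(out)[names(out) == "FALSE"] <- "N"
    names(out)[names(out) == "TRUE"] <- "Y"
    out
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort("Config must be .yaml/.yml or .json.")
  }
}

config_design <- function(config) {
  args <- config[intersect(names(config),
                           names(formals(sim_design)))]
  do.call(sim_design, args)
}

flatten_flags <- function(tab) {
  tab$flags <- vapply(tab$flags, paste, character(1), collapse = ";")
  tab
}

#' Analyze a CSV of item scores and write the coefficient table
#'
#' @param input Path to the score CSV.
#' @param output Optional output path (`.csv` or `.json`); `NULL` returns
#'   the table only.
#' @param level CI level.
#' @param partition Optional split-half partition.
#' @return The tidy coefficient table, invisibly when `output` is given.
#' @export
analyze_file <- function(input, output = NULL, level = 0.95, partition = NULL) {
  scores <- read_scores(input)
  fit <- reliability_analysis(scores, level = level, partition = partition)
  tab <- flatten_flags(tidy(fit))
  if (!is.null(output)) {
    write_result(tab, output)
    return(invisible(tab))
  }
  tab
}

#' Simulate item scores from a config and write them to CSV
#'
#' @param config A named list (or path loadable by [load_config()]) of
#'   [sim_design()] arguments.
#' @param output Output CSV path.
#' @param seed Seed overriding the design's.
#' @return The output path, invisibly.
#' @export
simulate_file <- function(config, output, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  design <- config_design(config)
  if (!is.null(seed)) design$seed <- as.integer(seed)
  params <- sample_item_params(design)
  X <- simulate_responses(design, params, seed = design$seed + 2L)
  write_scores(X, output)
  invisible(output)
}

#' Run the bias/coverage study from a config and write the result table
#'
#' @inheritParams simulate_file
#' @param output Output path (`.csv` or `.json`).
#' @return The study results tibble, invisibly.
#' @export
evaluate_file <- function(config, output, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  design <- config_design(config)
  if (!is.null(seed)) design$seed <- as.integer(seed)
  reps <- config$replications %||% design$replications
  pop_M <- config$pop_M %||% 1e6
  study <- run_study(design, reps = reps, pop_M = pop_M)
  write_result(tidy(study), output)
  invisible(tidy(study))
}

write_result <- function(tab, output) {
  ext <- tolower(tools::file_ext(output))
  if (ext == "json") {
    jsonlite::write_json(tab, output, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    readr::write_csv(tab, output)
  }
  invisible(output)
}
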