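test_that("CSV reading is strict about missing and malformed cells", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,1", "1,0", "1,1"), tmp)
  x <- read_scores(tmp)
  expect_equal(dim(x), c(3, 2))
  writeLines(c("a,b", "0,NA", "1,0"), tmp)
  expect_error(read_scores(tmp), "alformed|issing")
  writeLines(c("a,b", "0,x", "1,0"), tmp)
  expect_error(read_scores(tmp), "alformed")
})

test_that("reliability_analysis covers every statistic type with SEs and CIs", {
  # a Table-2-like scenario: 426 respondents, 3 dichotomous items
  d <- sim_design(N = 426, k = 3, seed = 2)
  X <- simulate_responses(d)
  fit <- reliability_analysis(X)
  tab <- tidy(fit)
  expect_setequal(unique(tab$type), c("item", "scale", "inter-item", "item-rest", "rest"))
  lam <- tab[tab$coefficient %in% c("lambda1", "lambda2", "lambda3"), ]
  expect_equal(nrow(lam), 3)
  expect_true(all(is.finite(lam$se)))
  expect_true(all(lam$lower <= lam$estimate & lam$estimate <= lam$upper))
  # values agree with direct library calls
  expect_equal(lam$estimate[lam$coefficient == "lambda3"], lambda3(X))
  expect_equal(tab$estimate[tab$type == "scale" & tab$coefficient == "split_half"],
               split_half(X))
  g <- glance(fit)
  expect_equal(g$N, 426)
  expect_equal(g$alpha, lambda3(X))
})

test_that("single-column and constant-column inputs degrade gracefully", {
  fit1 <- reliability_analysis(data.frame(a = c(0, 1, 0, 1, 1)))
  expect_false(any(grepl("lambda", tidy(fit1)$coefficient)))
  expect_true(any(tidy(fit1)$coefficient == "mean"))

  Xc <- data.frame(a = rep(1, 30), b = rbinom(30, 1, 0.5), c = rbinom(30, 1, 0.4))
  fit <- suppressWarnings(reliability_analysis(Xc))
  tab <- tidy(fit)
  covs <- tab[tab$coefficient == "covariance" & grepl("^a,", tab$item), ]
  expect_true(all(covs$se == 0))
  cors <- tab[tab$coefficient == "correlation" & grepl("^a,", tab$item), ]
  expect_true(all(vapply(cors$flags, function(f) "undefined" %in% f, logical(1))))
})

test_that("simulate_file is byte-identical under a fixed seed and round-trips through analyze", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("N: 80", "k: 4", "model: 2PLM", "seed: 5"), cfg)
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  simulate_file(cfg, out1)
  simulate_file(cfg, out2)
  expect_identical(readLines(out1), readLines(out2))
  # CLI round trip: analyze on the CSV equals library calls on the same data
  rep_out <- withr::local_tempfile(fileext = ".csv")
  tab <- analyze_file(out1, rep_out)
  X <- as.matrix(read_scores(out1))
  expect_equal(tab$estimate[tab$coefficient == "lambda3" & tab$type == "scale"],
               lambda3(X))
  expect_true(file.exists(rep_out))
})

test_that("evaluate_file writes a table with bias and coverage columns", {
  cfg <- list(N = 120, k = 4, model = "2PLM", seed = 4, replications = 25, pop_M = 1e5)
  out <- withr::local_tempfile(fileext = ".json")
  res <- evaluate_file(cfg, out)
  expect_true(all(c("scaled_bias", "coverage", "flag_coverage") %in% names(res)))
  expect_true(file.exists(out))
  parsed <- jsonlite::fromJSON(out)
  expect_equal(nrow(parsed), nrow(res))
})

test_that("config files load from YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("N: 50", "k: 3"), y)
  expect_equal(load_config(y)$N, 50)
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"N": 60, "k": 4}', j)
  expect_equal(load_config(j)$k, 4)
  expect_error(load_config("x.txt"), "yaml")
})

test_that("the command-line script runs end to end", {
  script <- system.file("cli", "relcli.R", package = "deltarel")
  expect_true(nzchar(script))
  csv <- withr::local_tempfile(fileext = ".csv")
  d <- sim_design(N = 60, k = 3, seed = 12)
  write_scores(simulate_responses(d), csv)
  out <- withr::local_tempfile(fileext = ".csv")
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c(script, "analyze", "--input", shQuote(csv),
                               "--output", shQuote(out)),
                    stdout = TRUE, stderr = TRUE,
                    env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(out))
  tab <- readr::read_csv(out, show_col_types = FALSE)
  expect_true("lambda3" %in% tab$coefficient)
  # malformed input gives a nonzero exit
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,NA"), bad)
  res <- suppressWarnings(system2(rscript, c(script, "analyze", "--input", shQuote(bad),
                                             "--output", shQuote(out)),
                                  stdout = TRUE, stderr = TRUE,
                                  env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))))
  expect_false(is.null(attr(res, "status")))
})

test_that("autoplot methods return ggplot objects", {
  X <- simulate_responses(sim_design(N = 80, k = 3, seed = 6))
  p1 <- autoplot(reliability_analysis(X))
  expect_s3_class(p1, "ggplot")
  design <- sim_design(N = 80, k = 4, replications = 8, seed = 6)
  p2 <- autoplot(run_study(design, pop_M = 1e5, benchmarks = FALSE))
  expect_s3_class(p2, "ggplot")
})
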