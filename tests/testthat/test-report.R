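# A stratified multi-item panel roughly shaped like a real needs
# assessment: three subpopulations with unbalanced issue lists.
stratified_sim <- function(sizes = c(A = 9, B = 7, C = 5), n = 6,
                           seed = 31) {
  items <- list()
  idx <- 0
  for (pop in names(sizes)) {
    for (j in seq_len(sizes[[pop]])) {
      idx <- idx + 1
      set.seed(seed * 100 + idx)
      pi <- as.vector(stats::rmultinom(1, 20, c(1, 1, 1))) / 20
      pc <- as.vector(stats::rmultinom(1, 20, c(1, 1, 1))) / 20
      items[[idx]] <- item_scenario(sprintf("%s%d", pop, j),
                                    list(importance = pi,
                                         changeability = pc),
                                    population = pop, missing_rate = 0.05)
    }
  }
  generate_panel(panel_scenario(n, 3, items = items, seed = seed))
}

fast_cfg <- bootstrap_config(n_replicates = 300, seed = 2)

test_that("reports are stratified with ranks forming a permutation", {
  sim <- stratified_sim()
  rep <- build_report(sim$panel, fast_cfg)
  res <- rep$results
  expect_equal(nrow(res), 21)
  expect_equal(as.vector(table(res$population)[c("A", "B", "C")]),
               c(9, 7, 5))
  for (pop in c("A", "B", "C")) {
    block <- res[res$population == pop, ]
    expect_equal(sort(block$rank), seq_len(nrow(block)))
    expect_true(all(diff(block$std_cpi[order(block$rank)]) <= 0))
  }
  expect_true(all(res$ci_lower <= res$observed_cpi + 1e-9))
  expect_true(all(res$observed_cpi <= res$ci_upper + 1e-9))
})

test_that("a single unstratified item lands in the default stratum", {
  p <- make_panel(list(c("s1", "q1", 3, 2), c("s2", "q1", 2, 3)))
  rep <- build_report(p, fast_cfg)
  expect_equal(nrow(rep$results), 1)
  expect_equal(rep$results$population, "all")
  expect_equal(rep$results$rank, 1L)
})

test_that("equal standardized CPIs are ranked by item id", {
  p <- make_panel(list(c("s1", "qb", 3, 2), c("s2", "qb", 2, 3),
                       c("s1", "qa", 3, 2), c("s2", "qa", 2, 3)),
                  strata = c(qa = "A", qb = "A"))
  rep <- build_report(p, bootstrap_config(100, seed = 1))
  expect_equal(rep$results$issue[order(rep$results$rank)], c("qa", "qb"))
})

test_that("CSV output has the exact column contract and 2-decimal rendering", {
  sim <- stratified_sim(sizes = c(A = 3, B = 2), n = 5, seed = 8)
  rep <- build_report(sim$panel, fast_cfg)
  f <- tempfile(fileext = ".csv")
  write_report(rep, f, format = "csv")
  got <- utils::read.csv(f, colClasses = "character")
  expect_identical(names(got),
                   c("population", "issue", "observed_cpi", "ci_lower",
                     "ci_upper", "std_cpi", "std_ci_lower", "std_ci_upper",
                     "priority_class", "rank"))
  expect_equal(nrow(got), 5)
  b <- cpi_bounds(3, 2)
  for (i in seq_len(nrow(got))) {
    obs <- rep$results$observed_cpi[rep$results$issue == got$issue[i]]
    expect_identical(
      got$std_cpi[i],
      sprintf("%.2f", round_half_up(standardize_cpi(obs, b), 2)))
    expect_match(got$observed_cpi[i], "^[0-9]+\\.[0-9]{2}$")
  }
})

test_that("JSON reports round-trip at full precision", {
  sim <- stratified_sim(sizes = c(A = 2, B = 2), n = 4, seed = 12)
  rep <- build_report(sim$panel, fast_cfg)
  f <- tempfile(fileext = ".json")
  write_report(rep, f, format = "json")
  back <- read_report(f)
  expect_equal(back$results$observed_cpi, rep$results$observed_cpi,
               tolerance = 1e-12)
  expect_equal(back$results$std_ci_upper, rep$results$std_ci_upper,
               tolerance = 1e-12)
  expect_identical(back$results$issue, rep$results$issue)
  expect_identical(back$results$rank, rep$results$rank)
  expect_equal(back$metadata$k, 3)
})

test_that("disabling the bootstrap yields point estimates with empty CIs", {
  p <- make_panel(list(c("s1", "q1", 3, 2), c("s2", "q1", 2, 3)))
  rep <- build_report(p, bootstrap_config(n_replicates = 0, seed = 1))
  expect_true(is.na(rep$results$ci_lower))
  expect_false(is.na(rep$results$std_cpi))
  f <- tempfile(fileext = ".csv")
  write_report(rep, f, format = "csv")
  got <- utils::read.csv(f, colClasses = "character")
  expect_identical(got$ci_lower, "")
  expect_identical(got$std_ci_upper, "")
})

test_that("uncomputable items are skipped with a log entry, not fatally", {
  p <- make_panel(list(c("s1", "q1", 0, 2), c("s2", "q1", 9, 3),
                       c("s1", "q2", 3, 3), c("s2", "q2", 2, 2)))
  rep <- build_report(validate_likert(p), fast_cfg)
  expect_equal(rep$results$issue, "q2")
  expect_equal(rep$skipped$item_id, "q1")
  expect_match(rep$skipped$reason, "importance")
  expect_equal(rep$metadata$validation$n_replaced, 2)
})

test_that("report construction is deterministic and classes match cut-offs", {
  sim <- stratified_sim(sizes = c(A = 4), n = 6, seed = 19)
  r1 <- build_report(sim$panel, fast_cfg)
  r2 <- build_report(sim$panel, fast_cfg)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$results$priority_class,
                   classify_priority(round_half_up(r1$results$std_cpi, 2)))
  r3 <- build_report(sim$panel, fast_cfg, full_precision = TRUE)
  expect_identical(r3$results$priority_class,
                   classify_priority(r3$results$std_cpi))
})

test_that("the optional merged view ranks all items globally", {
  sim <- stratified_sim(sizes = c(A = 3, B = 3), n = 5, seed = 23)
  rep <- build_report(sim$panel, fast_cfg, include_overall = TRUE)
  expect_equal(sort(rep$overall$rank), 1:6)
  expect_true(all(diff(rep$overall$std_cpi[order(rep$overall$rank)]) <= 0))
})

test_that("a report with no computable items writes a header-only CSV", {
  p <- make_panel(list(c("s1", "q1", NA, 2)))
  rep <- build_report(validate_likert(p), fast_cfg)
  expect_equal(nrow(rep$results), 0)
  expect_equal(rep$skipped$item_id, "q1")
  f <- tempfile(fileext = ".csv")
  write_report(rep, f, format = "csv")
  expect_length(readLines(f), 1)

  # plain-text rendering works on ordinary reports too
  p2 <- make_panel(list(c("s1", "q1", 3, 2), c("s2", "q1", 2, 3)))
  f2 <- tempfile(fileext = ".txt")
  write_report(build_report(p2, fast_cfg), f2, format = "table")
  expect_match(paste(readLines(f2), collapse = "\n"), "Population: all")
})

test_that("an empty panel is rejected", {
  empty <- rating_panel(data.frame(stakeholder_id = character(0),
                                   item_id = character(0),
                                   criterion = character(0),
                                   score = numeric(0)))
  expect_error(build_report(empty, fast_cfg),
               class = "cpi_empty_input_error")
})
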