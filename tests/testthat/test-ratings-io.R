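test_that("read_ratings builds one record per row and criterion", {
  f <- write_csv_fixture(c("1,1,3,2", "2,1,2,3"))
  p <- read_ratings(f, k = 3)
  expect_s3_class(p, "rating_panel")
  expect_equal(nrow(p$records), 4)
  expect_equal(n_stakeholders(p), 2)
  expect_equal(panel_items(p), "1")
  expect_equal(p$records$criterion,
               rep(c("importance", "changeability"), each = 2))
  expect_equal(p$records$score[p$records$criterion == "importance"], c(3, 2))
})

test_that("blank cells and literal NA are abstentions", {
  f <- write_csv_fixture(c("1,1,,3", "2,1,NA,2"))
  p <- read_ratings(f, k = 3)
  imp <- p$records[p$records$criterion == "importance", ]
  chg <- p$records[p$records$criterion == "changeability", ]
  expect_true(all(is.na(imp$score)))
  expect_equal(chg$score, c(3, 2))
})

test_that("duplicate stakeholder-item-criterion ratings are rejected", {
  f <- write_csv_fixture(c("1,1,3,2", "1,1,3,2"))
  expect_error(read_ratings(f, k = 3), class = "cpi_validation_error")
})

test_that("non-numeric score cells raise a parse error naming row and column", {
  f <- write_csv_fixture(c("1,1,3,2", "2,1,x,3"))
  err <- expect_error(read_ratings(f, k = 3), class = "cpi_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "importance")
  expect_error(read_ratings(tempfile()), class = "cpi_io_error")
  expect_error(read_ratings(write_csv_fixture("1,1")), class = "cpi_parse_error")
})

test_that("header rows are auto-detected and overridable", {
  body <- c("1,1,3,2", "2,1,2,3")
  with_hdr <- write_csv_fixture(c("id,item,importance,changeability", body))
  no_hdr <- write_csv_fixture(body)
  p1 <- read_ratings(with_hdr, k = 3)
  p2 <- read_ratings(no_hdr, k = 3)
  p3 <- read_ratings(no_hdr, k = 3, has_header = FALSE)
  expect_identical(sorted_records(p1), sorted_records(p2))
  expect_identical(sorted_records(p2), sorted_records(p3))
  # error positions are reported in file coordinates, after the header
  f <- write_csv_fixture(c("id,item,importance,changeability",
                           "1,1,3,2", "2,1,?,3"))
  err <- expect_error(read_ratings(f, k = 3), class = "cpi_parse_error")
  expect_match(conditionMessage(err), "row 3")
})

test_that("a named population column populates the strata", {
  f <- write_csv_fixture(c("id,item,importance,changeability,population",
                           "1,q1,3,2,A", "2,q1,2,3,A", "1,q2,1,2,B"))
  p <- read_ratings(f, k = 3, population_column = "population")
  expect_equal(unname(p$strata[c("q1", "q2")]), c("A", "B"))
  # one item in two populations is contradictory
  g <- write_csv_fixture(c("id,item,importance,changeability,population",
                           "1,q1,3,2,A", "2,q1,2,3,B"))
  expect_error(read_ratings(g, k = 3, population_column = "population"),
               class = "cpi_validation_error")
  # by-name lookup needs a header
  h <- write_csv_fixture(c("1,q1,3,2,A"))
  expect_error(read_ratings(h, k = 3, population_column = "population"),
               class = "cpi_argument_error")
  expect_equal(read_ratings(h, k = 3, population_column = 5)$strata[["q1"]],
               "A")
})

test_that("writing a panel and re-reading it round-trips the record set", {
  for (seed in c(11, 12, 13)) {
    sc <- panel_scenario(5, 3, items = list(
      item_scenario("q1", list(importance = c(.2, .3, .5),
                               changeability = c(.5, .3, .2)),
                    population = "A", missing_rate = 0.2),
      item_scenario("q2", list(importance = c(0, .5, .5),
                               changeability = c(.1, .8, .1)),
                    population = "B")
    ), seed = seed)
    sim <- generate_panel(sc)
    f <- tempfile(fileext = ".csv")
    write_ratings(sim$panel, f)
    back <- read_ratings(f, k = 3, population_column = "population")
    expect_identical(sorted_records(back), sorted_records(sim$panel))
    expect_identical(back$strata[panel_items(back)],
                     sim$panel$strata[panel_items(sim$panel)])
  }
})

test_that("validate_likert coerces out-of-range scores to NA and logs them", {
  p <- make_panel(list(c("s1", "q1", 4, 2),   # above k
                       c("s2", "q1", 0, 3),   # below 1
                       c("s3", "q1", 2.5, 1), # non-integer
                       c("s4", "q1", 3, 2)))
  v <- validate_likert(p)
  log <- validation_log(v)
  expect_equal(nrow(v$records), nrow(p$records))  # record count invariant
  expect_equal(nrow(log$replacements), 3)
  expect_setequal(log$replacements$original, c(4, 0, 2.5))
  expect_equal(sum(is.na(v$records$score)), 3)
  kept <- v$records[v$records$stakeholder_id == "s4", "score"]
  expect_equal(kept, c(3, 2))
})

test_that("validate_likert is the identity on clean panels and idempotent", {
  p <- make_panel(list(c("s1", "q1", 3, 2), c("s2", "q1", 1, 3)))
  v1 <- validate_likert(p)
  expect_identical(sorted_records(v1), sorted_records(p))
  expect_equal(nrow(validation_log(v1)$replacements), 0)

  dirty <- make_panel(list(c("s1", "q1", 9, 2), c("s2", "q1", 1, 3)))
  once <- validate_likert(dirty)
  twice <- validate_likert(once)
  expect_identical(sorted_records(twice), sorted_records(once))
  expect_equal(nrow(validation_log(twice)$replacements), 0)
})

test_that("items stripped of all usable scores are flagged, not dropped", {
  p <- make_panel(list(c("s1", "q1", 0, 2), c("s2", "q1", 5, 3),
                       c("s1", "q2", 2, 2)))
  v <- validate_likert(p)
  flagged <- validation_log(v)$flagged
  expect_equal(flagged$item_id, "q1")
  expect_equal(flagged$criterion, "importance")
  expect_true("q1" %in% panel_items(v))
})
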