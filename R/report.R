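#' Build a stratified, ranked priority report
#'
#' Runs the full CPI pipeline for every item in the panel: validation
#' (unless already applied), criterion means under abstention, the CPI
#' product, an optional percentile-bootstrap 95% CI, standardization to
#' `[0, 1]`, priority classification and within-stratum descending ranking
#' (ties broken by item id). Items without a population label form the
#' `"all"` stratum. Items that cannot be computed (no usable scores on some
#' criterion) are skipped with a log entry, never silently dropped.
#'
#' Ranking uses the standardized CPI, which orders items identically to the
#' raw CPI because standardization is strictly increasing; it is used as
#' the key so that the report reads in the same scale it prints.
#'
#' @param panel a [rating_panel()].
#' @param config a [bootstrap_config()]; `n_replicates = 0` disables the
#'   bootstrap and leaves the interval columns empty.
#' @param cutoffs priority cut-offs passed to [classify_priority()].
#' @param full_precision classify on the full-precision standardized CPI
#'   instead of the 2-decimal reported value (default `FALSE`, so the
#'   printed class always agrees with the printed score).
#' @param include_overall also compute a merged, globally ranked view
#'   across strata (stored as `overall`), useful when comparing priorities
#'   across populations.
#' @return Object of class `priority_report`: list with `results` (one row
#'   per item: `population`, `issue`, `observed_cpi`, `ci_lower`,
#'   `ci_upper`, `std_cpi`, `std_ci_lower`, `std_ci_upper`,
#'   `priority_class`, `rank`; full precision), `metadata`, `skipped`, and
#'   optionally `overall`.
#' @export
build_report <- function(panel, config = bootstrap_config(),
                         cutoffs = c(0.3, 0.7), full_precision = FALSE,
                         include_overall = FALSE) {
  if (nrow(panel$records) == 0) {
    cpi_stop("panel has no records", "cpi_empty_input_error")
  }
  if (!isTRUE(attr(panel, "validated"))) panel <- validate_likert(panel)
  vlog <- validation_log(panel)
  bounds <- cpi_bounds(panel$k, length(panel$criteria))
  do_boot <- config$n_replicates >= 1

  items <- panel_items(panel)
  skipped <- data.frame(item_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  total_discarded <- 0L
  rows <- list()
  for (it in items) {
    row <- tryCatch({
      cm <- criterion_means(panel, it)
      cpi <- compute_cpi(cm, criteria = panel$criteria)
      if (do_boot) {
        ci <- bootstrap_ci(panel, it, config)
        total_discarded <- total_discarded + ci$n_discarded
        ci_lo <- ci$lower; ci_hi <- ci$upper
        std_ci <- standardize_interval(ci, bounds)
      } else {
        ci_lo <- NA_real_; ci_hi <- NA_real_
        std_ci <- c(NA_real_, NA_real_)
      }
      std <- standardize_cpi(cpi, bounds)
      cls <- classify_priority(
        if (full_precision) std else round_half_up(std, 2), cutoffs)
      pop <- if (!is.null(panel$strata) && !is.na(panel$strata[it])) {
        unname(panel$strata[it])
      } else "all"
      data.frame(population = pop, issue = it, observed_cpi = cpi,
                 ci_lower = ci_lo, ci_upper = ci_hi, std_cpi = std,
                 std_ci_lower = std_ci[1], std_ci_upper = std_ci[2],
                 priority_class = cls, rank = NA_integer_,
                 stringsAsFactors = FALSE)
    }, cpi_no_responses_error = function(e) {
      skipped[nrow(skipped) + 1L, ] <<- list(it, conditionMessage(e))
      NULL
    }, cpi_degenerate_item_error = function(e) {
      skipped[nrow(skipped) + 1L, ] <<- list(it, conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  results <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(population = character(0), issue = character(0),
               observed_cpi = numeric(0), ci_lower = numeric(0),
               ci_upper = numeric(0), std_cpi = numeric(0),
               std_ci_lower = numeric(0), std_ci_upper = numeric(0),
               priority_class = character(0), rank = integer(0),
               stringsAsFactors = FALSE)
  }

  rank_block <- function(df) {
    ord <- order(-df$std_cpi, df$issue)
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df
  }
  if (nrow(results)) {
    parts <- lapply(split(results, results$population), rank_block)
    results <- do.call(rbind, parts[order(names(parts))])
    rownames(results) <- NULL
  }

  report <- structure(
    list(
      results = results,
      metadata = list(
        k = panel$k, n_c = length(panel$criteria),
        criteria = panel$criteria, bounds = bounds,
        bootstrap = config, cutoffs = cutoffs,
        full_precision_class = full_precision,
        n_stakeholders = n_stakeholders(panel),
        validation = list(
          n_replaced = if (is.null(vlog)) 0L else nrow(vlog$replacements),
          n_flagged_cells = if (is.null(vlog)) 0L else nrow(vlog$flagged)
        ),
        n_discarded_replicates = total_discarded
      ),
      skipped = skipped
    ),
    class = "priority_report"
  )
  if (include_overall) {
    overall <- report$results
    if (nrow(overall)) {
      overall <- rank_block(overall)
      rownames(overall) <- NULL
    }
    report$overall <- overall
  }
  report
}

# Rendered (2-decimal) view of the results table, as written to CSV/text.
rendered_results <- function(results) {
  out <- results
  for (col in c("observed_cpi", "ci_lower", "ci_upper", "std_cpi",
                "std_ci_lower", "std_ci_upper")) {
    out[[col]] <- format_num(results[[col]])
  }
  out
}

#' @export
print.priority_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "Community Priority Index report  (k = %d, %d criteria: %s)\n",
    md$k, md$n_c, paste(md$criteria, collapse = ", ")))
  cat(sprintf("%d stakeholders; bootstrap B = %d, seed = %d\n",
              md$n_stakeholders, md$bootstrap$n_replicates, md$bootstrap$seed))
  if (nrow(x$results) == 0) {
    cat("(no computable items)\n")
    return(invisible(x))
  }
  for (pop in unique(x$results$population)) {
    cat("\nPopulation:", pop, "\n")
    block <- rendered_results(x$results[x$results$population == pop, ])
    block$population <- NULL
    print(block, row.names = FALSE, right = TRUE)
  }
  if (nrow(x$skipped)) {
    cat("\nSkipped items:\n")
    for (i in seq_len(nrow(x$skipped))) {
      cat("  -", x$skipped$item_id[i], ":", x$skipped$reason[i], "\n")
    }
  }
  invisible(x)
}

#' Write a priority report to disk
#'
#' CSV and plain-text formats render numbers at two decimals (half-up);
#' JSON keeps full precision and round-trips losslessly through
#' [read_report()]. CSV columns are, in order: `population`, `issue`,
#' `observed_cpi`, `ci_lower`, `ci_upper`, `std_cpi`, `std_ci_lower`,
#' `std_ci_upper`, `priority_class`, `rank`.
#'
#' @param report a [build_report()] result.
#' @param path output path.
#' @param format `"csv"`, `"json"` or `"table"` (aligned plain text).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json", "table")) {
  format <- match.arg(format)
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(rendered_results(report$results), path,
                       row.names = FALSE, quote = TRUE, na = "")
    } else if (format == "json") {
      payload <- list(
        results = report$results,
        metadata = report$metadata[c("k", "n_c", "criteria", "cutoffs",
                                     "full_precision_class",
                                     "n_stakeholders", "validation",
                                     "n_discarded_replicates")],
        bootstrap = unclass(report$metadata$bootstrap),
        skipped = report$skipped
      )
      if (!is.null(report$overall)) payload$overall <- report$overall
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           na = "null", dataframe = "columns")
    } else {
      con <- file(path, "w")
      on.exit(close(con), add = TRUE)
      sink(con)
      print(report)
      sink()
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cpi_stop(paste0("cannot write report to ", path), "cpi_io_error")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  res <- as.data.frame(x$results, stringsAsFactors = FALSE)
  if (nrow(res)) res$rank <- as.integer(res$rank)
  list(results = res, metadata = x$metadata, bootstrap = x$bootstrap,
       skipped = as.data.frame(x$skipped, stringsAsFactors = FALSE))
}
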