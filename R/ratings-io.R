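#' Construct a stakeholder rating panel
#'
#' A rating panel holds one record per stakeholder x item x criterion cell:
#' the score a stakeholder gave one community issue on one decision
#' criterion of a k-point Likert scale. Abstentions are `NA`. The panel is
#' the single container every downstream operation (criterion means, CPI,
#' bootstrap, reporting) consumes.
#'
#' @param records data frame with columns `stakeholder_id`, `item_id`,
#'   `criterion` (character) and `score` (numeric; `NA` = abstention).
#' @param k integer scale maximum (>= 2); valid scores lie in 1..k.
#' @param criteria ordered character vector of criterion names; every
#'   record's criterion must be on this roster.
#' @param strata optional named character vector mapping `item_id` to a
#'   population label, used for stratified reporting.
#' @return An object of class `rating_panel`.
#' @seealso [read_ratings()], [validate_likert()]
#' @export
rating_panel <- function(records, k = 3,
                         criteria = c("importance", "changeability"),
                         strata = NULL) {
  if (!is.data.frame(records)) {
    cpi_stop("`records` must be a data frame", "cpi_argument_error")
  }
  needed <- c("stakeholder_id", "item_id", "criterion", "score")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    cpi_stop(paste0("records lack column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "cpi_argument_error")
  }
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 2 || k != round(k)) {
    cpi_stop("`k` must be a single integer >= 2", "cpi_argument_error")
  }
  if (length(criteria) < 1 || anyDuplicated(criteria)) {
    cpi_stop("`criteria` must be a non-empty set of distinct names",
             "cpi_argument_error")
  }
  records <- data.frame(
    stakeholder_id = as.character(records$stakeholder_id),
    item_id        = as.character(records$item_id),
    criterion      = as.character(records$criterion),
    score          = as.numeric(records$score),
    stringsAsFactors = FALSE
  )
  bad_crit <- setdiff(unique(records$criterion), criteria)
  if (length(bad_crit)) {
    cpi_stop(paste0("record criterion not on roster: ",
                    paste(bad_crit, collapse = ", ")),
             "cpi_validation_error")
  }
  key <- paste(records$stakeholder_id, records$item_id, records$criterion,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1, ]
    cpi_stop(sprintf(
      "duplicate rating for stakeholder '%s', item '%s', criterion '%s'",
      d$stakeholder_id, d$item_id, d$criterion), "cpi_validation_error")
  }
  if (!is.null(strata)) {
    if (is.null(names(strata))) {
      cpi_stop("`strata` must be a named vector (item_id -> population)",
               "cpi_argument_error")
    }
    strata <- vapply(strata, as.character, character(1))
  }
  structure(
    list(records = records, k = as.integer(k),
         criteria = as.character(criteria), strata = strata),
    class = "rating_panel"
  )
}

#' @export
print.rating_panel <- function(x, ...) {
  cat(sprintf(
    "<rating_panel> %d records | %d stakeholders | %d items | k = %d\n",
    nrow(x$records), n_stakeholders(x), length(panel_items(x)), x$k))
  cat("criteria:", paste(x$criteria, collapse = ", "), "\n")
  if (!is.null(x$strata)) {
    cat("strata:", paste(sort(unique(x$strata)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Panel accessors
#'
#' @param panel a [rating_panel()].
#' @return `n_stakeholders()` the number of distinct stakeholder ids (the
#'   n_I of the CPI formulas); `panel_items()` the distinct item ids in
#'   first-appearance order; `validation_log()` the replacement log attached
#'   by [validate_likert()] (or `NULL`).
#' @export
n_stakeholders <- function(panel) {
  length(unique(panel$records$stakeholder_id))
}

#' @rdname n_stakeholders
#' @export
panel_items <- function(panel) unique(panel$records$item_id)

#' @rdname n_stakeholders
#' @export
validation_log <- function(panel) attr(panel, "validation_log")

#' Read a stakeholder rating file
#'
#' Reads the plain CSV dialect used for community rating data: column 1 is
#' the stakeholder (interviewee) id, column 2 the item (question) id, then
#' one column per criterion in roster order (importance, changeability by
#' default), optionally followed by a population column for stratified
#' reports. Blank cells and the literal `NA` are abstentions.
#'
#' A header row is auto-detected (first row non-numeric in the score
#' columns) unless `has_header` is given explicitly.
#'
#' @param path path to a CSV file.
#' @param k Likert scale maximum (default 3).
#' @param criteria criterion roster, in column order.
#' @param has_header `TRUE`/`FALSE` to force, `NULL` (default) to detect.
#' @param population_column name (with header) or column index of the
#'   population label column, or `NULL` for an unstratified panel.
#' @return A [rating_panel()] with one record per row x criterion.
#' @export
read_ratings <- function(path, k = 3,
                         criteria = c("importance", "changeability"),
                         has_header = NULL, population_column = NULL) {
  if (!file.exists(path)) {
    cpi_stop(paste0("rating file not found: ", path), "cpi_io_error")
  }
  raw <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "character",
                    strip.white = TRUE, blank.lines.skip = TRUE,
                    na.strings = character(0)),
    error = function(e) {
      cpi_stop(paste0("cannot parse '", path, "': ", conditionMessage(e)),
               "cpi_parse_error")
    }
  )
  n_c <- length(criteria)
  if (ncol(raw) < 2 + n_c) {
    cpi_stop(sprintf(
      "file has %d column(s); need at least %d (id, item, %s)",
      ncol(raw), 2 + n_c, paste(criteria, collapse = ", ")),
      "cpi_parse_error")
  }
  score_cols <- 2 + seq_len(n_c)
  looks_numeric <- function(v) {
    v == "" | toupper(v) == "NA" | !is.na(suppressWarnings(as.numeric(v)))
  }
  if (is.null(has_header)) {
    first <- as.character(raw[1, score_cols])
    has_header <- !all(looks_numeric(first))
  }
  header <- NULL
  if (has_header) {
    header <- as.character(raw[1, ])
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) == 0) {
    cpi_stop("rating file contains no data rows", "cpi_empty_input_error")
  }
  pop_idx <- NULL
  if (!is.null(population_column)) {
    if (is.character(population_column)) {
      if (is.null(header)) {
        cpi_stop("population column given by name but the file has no header",
                 "cpi_argument_error")
      }
      pop_idx <- match(population_column, header)
      if (is.na(pop_idx)) {
        cpi_stop(paste0("no column named '", population_column, "' in header"),
                 "cpi_parse_error")
      }
    } else {
      pop_idx <- as.integer(population_column)
      if (is.na(pop_idx) || pop_idx < 1 || pop_idx > ncol(raw)) {
        cpi_stop("population column index out of range", "cpi_argument_error")
      }
    }
  }

  ids <- as.character(raw[[1]])
  items <- as.character(raw[[2]])
  data_rows <- seq_len(nrow(raw)) + if (has_header) 1L else 0L

  parse_scores <- function(col, crit_name) {
    v <- as.character(raw[[col]])
    blank <- v == "" | toupper(v) == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- !blank & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      cpi_stop(sprintf(
        "non-numeric score '%s' at file row %d, column %d (%s)",
        v[i], data_rows[i], col, crit_name), "cpi_parse_error")
    }
    num[blank] <- NA_real_
    num
  }

  recs <- do.call(rbind, lapply(seq_len(n_c), function(ci) {
    data.frame(
      stakeholder_id = ids,
      item_id        = items,
      criterion      = criteria[ci],
      score          = parse_scores(score_cols[ci], criteria[ci]),
      stringsAsFactors = FALSE
    )
  }))

  strata <- NULL
  if (!is.null(pop_idx)) {
    pop <- as.character(raw[[pop_idx]])
    strata <- tapply(pop, items, function(v) v[1])
    conflict <- tapply(pop, items, function(v) length(unique(v)) > 1)
    if (any(conflict)) {
      cpi_stop(paste0("item(s) mapped to more than one population: ",
                      paste(names(conflict)[conflict], collapse = ", ")),
               "cpi_validation_error")
    }
    strata <- stats::setNames(as.character(strata), names(strata))
  }

  rating_panel(recs, k = k, criteria = criteria, strata = strata)
}

#' Write a rating panel back to the CSV rating dialect
#'
#' Inverse of [read_ratings()]: one row per stakeholder x item, criterion
#' scores in roster order, abstentions as empty cells, and a trailing
#' `population` column when the panel is stratified.
#'
#' @param panel a [rating_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(panel, path) {
  r <- panel$records
  keys <- unique(r[, c("stakeholder_id", "item_id")])
  wide <- keys
  for (crit in panel$criteria) {
    sub <- r[r$criterion == crit, ]
    m <- match(paste(keys$stakeholder_id, keys$item_id, sep = "\r"),
               paste(sub$stakeholder_id, sub$item_id, sep = "\r"))
    wide[[crit]] <- sub$score[m]
  }
  names(wide)[1:2] <- c("id", "item")
  if (!is.null(panel$strata)) {
    wide$population <- unname(panel$strata[wide$item])
  }
  for (crit in panel$criteria) {
    wide[[crit]] <- ifelse(is.na(wide[[crit]]), "",
                           format(wide[[crit]], trim = TRUE))
  }
  ok <- tryCatch({
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cpi_stop(paste0("cannot write ", path), "cpi_io_error")
  invisible(path)
}

#' Coerce out-of-range Likert scores to missing
#'
#' Replaces every score outside the valid range 1..k — including 0,
#' values above k, and non-integers — with `NA`, and logs each replacement
#' with the stakeholder, item, criterion and original value. Items left
#' with zero usable scores on some criterion are flagged (not dropped) so
#' downstream computation can report them explicitly. The operation is
#' idempotent and never changes the record count.
#'
#' @param panel a [rating_panel()].
#' @return The panel with invalid scores set to `NA` and a
#'   `validation_log` attribute: a list with `replacements` (data frame)
#'   and `flagged` (data frame of item x criterion cells with no usable
#'   scores). Retrieve it with [validation_log()].
#' @export
validate_likert <- function(panel) {
  r <- panel$records
  s <- r$score
  bad <- !is.na(s) & (s < 1 | s > panel$k | s != round(s))
  replacements <- data.frame(
    stakeholder_id = r$stakeholder_id[bad],
    item_id        = r$item_id[bad],
    criterion      = r$criterion[bad],
    original       = s[bad],
    stringsAsFactors = FALSE
  )
  r$score[bad] <- NA_real_

  cells <- expand.grid(item_id = unique(r$item_id), criterion = panel$criteria,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  usable <- mapply(function(it, cr) {
    any(!is.na(r$score[r$item_id == it & r$criterion == cr]))
  }, cells$item_id, cells$criterion)
  flagged <- cells[!usable, , drop = FALSE]
  rownames(flagged) <- NULL

  out <- rating_panel(r, k = panel$k, criteria = panel$criteria,
                      strata = panel$strata)
  attr(out, "validation_log") <- list(replacements = replacements,
                                      flagged = flagged)
  attr(out, "validated") <- TRUE
  out
}
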