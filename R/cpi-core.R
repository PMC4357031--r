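#' Mean criterion score for one item
#'
#' Averages the non-missing scores one item received on one criterion.
#' Abstentions do not enter the denominator: the sum of observed scores is
#' divided by the number of respondents for that particular item and
#' criterion, not by the full panel size, so partial response never
#' deflates an item's mean.
#'
#' @param panel a [rating_panel()].
#' @param item_id item to summarise.
#' @param criterion criterion name from the panel roster.
#' @return A list of class `criterion_mean` with `item_id`, `criterion`,
#'   `mean` (in `[1, k]` for validated panels) and `n_respondents`.
#' @export
criterion_mean <- function(panel, item_id, criterion) {
  if (!criterion %in% panel$criteria) {
    cpi_stop(paste0("unknown criterion: ", criterion), "cpi_argument_error")
  }
  r <- panel$records
  s <- r$score[r$item_id == item_id & r$criterion == criterion]
  if (length(s) == 0) {
    cpi_stop(paste0("no records for item '", item_id, "'"),
             "cpi_argument_error")
  }
  s <- s[!is.na(s)]
  if (length(s) == 0) {
    cpi_stop(sprintf(
      "item '%s' has no usable responses on criterion '%s'",
      item_id, criterion), "cpi_no_responses_error")
  }
  structure(
    list(item_id = item_id, criterion = criterion,
         mean = sum(s) / length(s), n_respondents = length(s)),
    class = "criterion_mean"
  )
}

#' All criterion means for one item
#'
#' @inheritParams criterion_mean
#' @return Data frame with one row per roster criterion: `item_id`,
#'   `criterion`, `mean`, `n_respondents`.
#' @export
criterion_means <- function(panel, item_id) {
  rows <- lapply(panel$criteria, function(cr) {
    m <- criterion_mean(panel, item_id, cr)
    data.frame(item_id = m$item_id, criterion = m$criterion, mean = m$mean,
               n_respondents = m$n_respondents, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Community Priority Index of one item
#'
#' The CPI is the product of the item's mean criterion scores — with the
#' default roster, mean importance times mean changeability. Higher values
#' indicate issues rated both more important and more changeable; for a
#' k-point scale and n_c criteria the index lies in `[1, k^n_c]`.
#'
#' @param means the output of [criterion_means()] (a data frame), a list of
#'   [criterion_mean()] objects, or a bare numeric vector of means.
#' @param criteria optional roster to check completeness against; one mean
#'   per criterion is required, in any order (the product is commutative).
#' @return The CPI, a single number.
#' @export
compute_cpi <- function(means, criteria = NULL) {
  if (inherits(means, "criterion_mean")) means <- list(means)
  if (is.list(means) && !is.data.frame(means) &&
      all(vapply(means, inherits, logical(1), "criterion_mean"))) {
    means <- data.frame(
      criterion = vapply(means, `[[`, character(1), "criterion"),
      mean = vapply(means, `[[`, numeric(1), "mean"),
      stringsAsFactors = FALSE
    )
  }
  if (is.data.frame(means)) {
    if (!is.null(criteria)) {
      have <- means$criterion
      if (length(have) != length(criteria) || !setequal(have, criteria) ||
          anyDuplicated(have)) {
        cpi_stop(paste0(
          "need exactly one mean per criterion (",
          paste(criteria, collapse = ", "), "); got: ",
          paste(have, collapse = ", ")), "cpi_incomplete_item_error")
      }
    }
    vals <- means$mean
  } else {
    vals <- as.numeric(means)
    if (!is.null(criteria) && length(vals) != length(criteria)) {
      cpi_stop("one mean per criterion is required",
               "cpi_incomplete_item_error")
    }
  }
  if (length(vals) == 0 || anyNA(vals)) {
    cpi_stop("criterion means are missing", "cpi_incomplete_item_error")
  }
  prod(vals)
}

#' Theoretical CPI bounds
#'
#' If every stakeholder gives the minimum score 1 on every criterion the
#' CPI is 1; if every one gives the maximum k it is k^n_c. These bounds
#' hold for any panel size and anchor the standardization of
#' [standardize_cpi()].
#'
#' @param k Likert scale maximum (>= 2).
#' @param n_c number of criteria (>= 1).
#' @return List of class `cpi_bounds` with `lower` (1) and `upper` (k^n_c).
#' @examples
#' cpi_bounds(3, 2) # lower 1, upper 9
#' @export
cpi_bounds <- function(k, n_c) {
  ok <- function(x, lo) is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x >= lo && x == round(x)
  if (!ok(k, 2)) cpi_stop("`k` must be an integer >= 2", "cpi_argument_error")
  if (!ok(n_c, 1)) cpi_stop("`n_c` must be an integer >= 1",
                            "cpi_argument_error")
  structure(list(lower = 1, upper = k^n_c), class = "cpi_bounds")
}

#' @export
print.cpi_bounds <- function(x, ...) {
  cat(sprintf("<cpi_bounds> [%g, %g]\n", x$lower, x$upper))
  invisible(x)
}

#' Standardize a CPI onto [0, 1]
#'
#' Min–max standardization against the theoretical bounds:
#' `(cpi - LB) / (UB - LB) = (cpi - 1) / (k^n_c - 1)`. The standardized
#' index is scale-free, so priorities measured on different Likert scales
#' or criterion counts become comparable.
#'
#' @param cpi numeric vector of CPI values (each within the bounds).
#' @param bounds a [cpi_bounds()] object.
#' @return Standardized values in `[0, 1]`.
#' @examples
#' standardize_cpi(7.80, cpi_bounds(3, 2)) # 0.85
#' @export
standardize_cpi <- function(cpi, bounds) {
  stopifnot(inherits(bounds, "cpi_bounds"))
  tol <- 1e-9
  if (any(!is.na(cpi) & (cpi < bounds$lower - tol | cpi > bounds$upper + tol))) {
    cpi_stop(sprintf("CPI outside theoretical bounds [%g, %g]",
                     bounds$lower, bounds$upper), "cpi_range_error")
  }
  (cpi - bounds$lower) / (bounds$upper - bounds$lower)
}

#' @rdname standardize_cpi
#' @param std standardized values in `[0, 1]` to map back to the raw scale.
#' @export
unstandardize_cpi <- function(std, bounds) {
  stopifnot(inherits(bounds, "cpi_bounds"))
  tol <- 1e-9
  if (any(!is.na(std) & (std < -tol | std > 1 + tol))) {
    cpi_stop("standardized CPI outside [0, 1]", "cpi_range_error")
  }
  bounds$lower + std * (bounds$upper - bounds$lower)
}

#' Classify a standardized CPI into priority bands
#'
#' Applies the conventional cut-offs: below `cutoffs[1]` is low priority,
#' above `cutoffs[2]` high, and the closed middle band (endpoints
#' included) intermediate. The cut-offs are a community convention, not a
#' statistical property, and are fully configurable.
#'
#' @param std_cpi numeric vector of standardized CPI values in `[0, 1]`.
#' @param cutoffs length-2 numeric `(low_max, high_min)` with
#'   `0 < low_max <= high_min < 1`; default `c(0.3, 0.7)`.
#' @return Character vector: `"low"`, `"intermediate"` or `"high"`.
#' @examples
#' classify_priority(c(0.85, 0.28, 0.70)) # high, low, intermediate
#' @export
classify_priority <- function(std_cpi, cutoffs = c(0.3, 0.7)) {
  if (length(cutoffs) != 2 || anyNA(cutoffs) ||
      cutoffs[1] <= 0 || cutoffs[2] >= 1 || cutoffs[1] > cutoffs[2]) {
    cpi_stop("cutoffs must satisfy 0 < low_max <= high_min < 1",
             "cpi_argument_error")
  }
  if (any(!is.na(std_cpi) & (std_cpi < 0 | std_cpi > 1))) {
    cpi_stop("standardized CPI outside [0, 1]", "cpi_range_error")
  }
  ifelse(is.na(std_cpi), NA_character_,
         ifelse(std_cpi < cutoffs[1], "low",
                ifelse(std_cpi > cutoffs[2], "high", "intermediate")))
}
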