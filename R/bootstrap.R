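#' Bootstrap configuration
#'
#' Settings for the percentile-bootstrap confidence interval of an item's
#' CPI. Defaults follow common practice for small stakeholder panels:
#' 10,000 replicates and the 2.5th/97.5th percentiles for a 95% interval.
#'
#' @param n_replicates number of bootstrap replicates B (>= 1); 0 is
#'   accepted by the reporting pipeline to mean "no interval".
#' @param seed integer seed for the run; each item draws from its own
#'   substream derived from `(seed, item_id)`, so results do not depend on
#'   the order in which items are processed.
#' @param percentiles length-2 percent pair, default `c(2.5, 97.5)`.
#' @param max_redraws how many times a degenerate replicate (one in which
#'   some criterion resamples to all-missing) may be redrawn before the
#'   item is declared degenerate.
#' @param resampling `"joint"` resamples whole stakeholder rows so the
#'   within-stakeholder correlation between criteria is preserved;
#'   `"independent"` resamples each criterion's scores separately.
#' @param quantile_type `"nearest-rank"` (order statistic at rank
#'   `ceiling(p * B)`) or `"interpolated"` (type-7 quantile).
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 10000, seed = 1,
                             percentiles = c(2.5, 97.5),
                             max_redraws = 100,
                             resampling = c("joint", "independent"),
                             quantile_type = c("nearest-rank", "interpolated")) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      is.na(n_replicates) || n_replicates < 0 ||
      n_replicates != round(n_replicates)) {
    cpi_stop("`n_replicates` must be a non-negative integer",
             "cpi_argument_error")
  }
  if (length(percentiles) != 2 || anyNA(percentiles) ||
      percentiles[1] <= 0 || percentiles[2] >= 100 ||
      percentiles[1] >= percentiles[2]) {
    cpi_stop("percentiles must satisfy 0 < lower < upper < 100",
             "cpi_argument_error")
  }
  structure(
    list(n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         percentiles = as.numeric(percentiles),
         max_redraws = as.integer(max_redraws),
         resampling = match.arg(resampling),
         quantile_type = match.arg(quantile_type)),
    class = "bootstrap_config"
  )
}

# Scores of one item as a stakeholder x criterion matrix, rows ordered by
# stakeholder id so results are independent of record order.
item_score_matrix <- function(panel, item_id) {
  r <- panel$records[panel$records$item_id == item_id, , drop = FALSE]
  if (nrow(r) == 0) {
    cpi_stop(paste0("no records for item '", item_id, "'"),
             "cpi_argument_error")
  }
  ids <- sort(unique(r$stakeholder_id))
  m <- matrix(NA_real_, length(ids), length(panel$criteria),
              dimnames = list(ids, panel$criteria))
  m[cbind(match(r$stakeholder_id, ids), match(r$criterion, panel$criteria))] <-
    r$score
  m
}

# Replicate CPI values for an index matrix (B x n); per-criterion column
# index matrices allow the independent-resampling mode. Returns NaN where a
# criterion resampled to all-missing.
replicate_cpis <- function(scores, idx_list) {
  n <- nrow(scores)
  cpi <- 1
  degenerate <- FALSE
  for (ci in seq_len(ncol(scores))) {
    v <- matrix(scores[, ci][idx_list[[ci]]], nrow = nrow(idx_list[[ci]]))
    cnt <- rowSums(!is.na(v))
    degenerate <- degenerate | cnt == 0
    sums <- rowSums(v, na.rm = TRUE)
    cpi <- cpi * ifelse(cnt == 0, NaN, sums / cnt)
  }
  list(cpi = cpi, degenerate = degenerate)
}

nearest_rank <- function(sorted, p, B) sorted[pmax(1L, ceiling(p / 100 * B))]

#' Percentile-bootstrap confidence interval for an item's CPI
#'
#' Resamples the item's stakeholder rows with replacement (same size as the
#' observed roster for that item), recomputes criterion means over the
#' non-missing resampled scores and their product per replicate, and takes
#' empirical percentiles of the replicate CPI distribution. Abstentions
#' travel through resampling as missing values, mirroring how the observed
#' criterion means handle them. Replicates in which some criterion draws
#' only missing values are discarded and redrawn (reported in
#' `n_discarded`).
#'
#' The interval width is readable as stakeholder consensus: the narrower
#' the interval, the stronger the agreement on the item's priority.
#'
#' @param panel a [rating_panel()].
#' @param item_id item to bootstrap.
#' @param config a [bootstrap_config()].
#' @return List of class `bootstrap_ci` with `item_id`, `lower`, `upper`,
#'   `n_valid_replicates`, `n_discarded`.
#' @export
bootstrap_ci <- function(panel, item_id, config = bootstrap_config()) {
  if (config$n_replicates < 1) {
    cpi_stop("`n_replicates` must be >= 1 for a confidence interval",
             "cpi_argument_error")
  }
  scores <- item_score_matrix(panel, item_id)
  n <- nrow(scores)
  for (ci in seq_len(ncol(scores))) {
    if (all(is.na(scores[, ci]))) {
      cpi_stop(sprintf(
        "item '%s' has no usable responses on criterion '%s'",
        item_id, panel$criteria[ci]), "cpi_no_responses_error")
    }
  }
  B <- config$n_replicates
  n_c <- ncol(scores)
  draw_idx <- function(b) {
    if (config$resampling == "joint") {
      one <- matrix(sample.int(n, b * n, replace = TRUE), nrow = b)
      rep(list(one), n_c)
    } else {
      lapply(seq_len(n_c), function(ci) {
        matrix(sample.int(n, b * n, replace = TRUE), nrow = b)
      })
    }
  }
  res <- with_local_seed(item_stream_seed(config$seed, item_id), {
    out <- replicate_cpis(scores, draw_idx(B))
    cpi <- out$cpi
    n_discarded <- 0L
    tries <- 0L
    while (any(out$degenerate)) {
      bad <- which(out$degenerate)
      n_discarded <- n_discarded + length(bad)
      tries <- tries + 1L
      if (tries > config$max_redraws) {
        cpi_stop(sprintf(
          "item '%s': degenerate replicates persist after %d redraws",
          item_id, config$max_redraws), "cpi_degenerate_item_error")
      }
      redraw <- draw_idx(length(bad))
      out2 <- replicate_cpis(scores, redraw)
      cpi[bad] <- out2$cpi
      out$degenerate[bad] <- out2$degenerate
    }
    list(cpi = cpi, n_discarded = n_discarded)
  })
  ci <- if (config$quantile_type == "nearest-rank") {
    s <- sort(res$cpi)
    c(nearest_rank(s, config$percentiles[1], B),
      nearest_rank(s, config$percentiles[2], B))
  } else {
    unname(stats::quantile(res$cpi, config$percentiles / 100, type = 7))
  }
  structure(
    list(item_id = item_id, lower = ci[1], upper = ci[2],
         n_valid_replicates = B, n_discarded = res$n_discarded),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> item %s: [%.4g, %.4g] (%d replicates, %d discarded)\n",
              x$item_id, x$lower, x$upper, x$n_valid_replicates, x$n_discarded))
  invisible(x)
}

#' Exact resampling distribution of an item's CPI
#'
#' Enumerates all `n^n` equally likely ordered with-replacement resamples of
#' an item's `n` stakeholder rows and computes the CPI of each, giving the
#' exact sampling distribution that the Monte-Carlo bootstrap approximates.
#' Intended as a ground-truth oracle for small panels; refuses rosters
#' larger than 6 (6^6 = 46,656 outcomes). Degenerate outcomes (a criterion
#' resampling to all-missing) are excluded and the distribution
#' renormalized, matching the bootstrap's discard-and-redraw rule.
#'
#' @param panel a [rating_panel()].
#' @param item_id item to enumerate.
#' @return Data frame of class `cpi_resample_distribution`: sorted `value`
#'   and `probability` columns summing to 1; attribute `n` is the roster
#'   size.
#' @export
exact_resample_distribution <- function(panel, item_id) {
  scores <- item_score_matrix(panel, item_id)
  n <- nrow(scores)
  if (n > 6) {
    cpi_stop(sprintf(
      "roster of %d stakeholders is too large to enumerate (max 6)", n),
      "cpi_size_error")
  }
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n),
                               KEEP.OUT.ATTRS = FALSE))
  out <- replicate_cpis(scores, rep(list(idx), ncol(scores)))
  keep <- !out$degenerate
  if (!any(keep)) {
    cpi_stop(paste0("item '", item_id, "' has no non-degenerate resamples"),
             "cpi_degenerate_item_error")
  }
  tab <- tapply(rep(1, sum(keep)), out$cpi[keep], sum)
  vals <- as.numeric(names(tab))
  ord <- order(vals)
  d <- data.frame(value = vals[ord],
                  probability = as.numeric(tab)[ord] / sum(keep))
  attr(d, "n") <- n
  class(d) <- c("cpi_resample_distribution", "data.frame")
  d
}

#' Nearest-rank percentiles of an exact resampling distribution
#'
#' The population analogue of the bootstrap's nearest-rank convention: the
#' p-th percentile is the smallest support value whose cumulative
#' probability reaches p/100.
#'
#' @param dist a [exact_resample_distribution()] result.
#' @param percentiles percent values, default `c(2.5, 97.5)`.
#' @return Numeric vector of percentile values.
#' @export
exact_percentiles <- function(dist, percentiles = c(2.5, 97.5)) {
  cdf <- cumsum(dist$probability)
  vapply(percentiles / 100, function(p) {
    dist$value[which(cdf >= p - 1e-12)[1]]
  }, numeric(1))
}

#' Standardize a confidence interval
#'
#' Maps both endpoints of a raw-scale CPI interval through
#' [standardize_cpi()]; the map is strictly increasing so endpoint order is
#' preserved.
#'
#' @param ci a [bootstrap_ci()] object or a length-2 numeric
#'   `(lower, upper)`.
#' @param bounds a [cpi_bounds()] object.
#' @return Length-2 numeric: standardized `(lower, upper)`.
#' @examples
#' standardize_interval(c(6.60, 9.00), cpi_bounds(3, 2)) # 0.70, 1.00
#' @export
standardize_interval <- function(ci, bounds) {
  ends <- if (inherits(ci, "bootstrap_ci")) c(ci$lower, ci$upper)
          else as.numeric(ci)
  if (length(ends) != 2 || anyNA(ends) || ends[1] > ends[2]) {
    cpi_stop("interval must be a (lower, upper) pair with lower <= upper",
             "cpi_argument_error")
  }
  standardize_cpi(ends, bounds)
}
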