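#' Define a synthetic rating scenario for one item
#'
#' An item scenario fixes, for each criterion, the probability distribution
#' of a stakeholder's score over the Likert levels 1..k, together with a
#' missingness rate (each elicited score is independently replaced by an
#' abstention with this probability). The implied truth — true criterion
#' means and their product, the true CPI — is computed here once so
#' recovery and coverage checks never re-derive it from data.
#'
#' @param item_id item identifier.
#' @param distributions named list (one entry per criterion) of probability
#'   vectors over levels `1..k`; each must be non-negative and sum to 1.
#' @param population optional population label for stratified reports.
#' @param missing_rate abstention probability in `[0, 1)`.
#' @return List of class `item_scenario` with the inputs plus `true_means`
#'   (named) and `true_cpi`.
#' @export
item_scenario <- function(item_id, distributions, population = NA_character_,
                          missing_rate = 0) {
  if (!is.list(distributions) || is.null(names(distributions)) ||
      any(names(distributions) == "")) {
    cpi_stop("`distributions` must be a named list of probability vectors",
             "cpi_argument_error")
  }
  k <- length(distributions[[1]])
  for (nm in names(distributions)) {
    p <- distributions[[nm]]
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      cpi_stop(sprintf(
        "distribution for '%s' must be %d non-negative probabilities summing to 1",
        nm, k), "cpi_argument_error")
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    cpi_stop("`missing_rate` must lie in [0, 1)", "cpi_argument_error")
  }
  true_means <- vapply(distributions, function(p) sum(seq_len(k) * p),
                       numeric(1))
  structure(
    list(item_id = as.character(item_id), population = population,
         distributions = distributions, missing_rate = missing_rate,
         k = k, true_means = true_means, true_cpi = prod(true_means)),
    class = "item_scenario"
  )
}

#' Define a synthetic panel scenario
#'
#' @param n_stakeholders panel size (>= 1).
#' @param k Likert scale maximum; every item's distributions must have k
#'   levels.
#' @param items list of [item_scenario()] objects.
#' @param criteria criterion roster; defaults to the criterion names of the
#'   first item.
#' @param seed integer seed; the same scenario always generates the
#'   identical panel.
#' @return List of class `panel_scenario`.
#' @export
panel_scenario <- function(n_stakeholders, k, items, criteria = NULL,
                           seed = 1) {
  if (n_stakeholders < 1) {
    cpi_stop("`n_stakeholders` must be >= 1", "cpi_argument_error")
  }
  if (length(items) < 1) cpi_stop("at least one item is required",
                                  "cpi_argument_error")
  if (is.null(criteria)) criteria <- names(items[[1]]$distributions)
  for (it in items) {
    if (it$k != k) {
      cpi_stop(sprintf("item '%s' has %d levels, scenario k = %d",
                       it$item_id, it$k, k), "cpi_argument_error")
    }
    if (!setequal(names(it$distributions), criteria)) {
      cpi_stop(sprintf("item '%s' criteria do not match the roster",
                       it$item_id), "cpi_argument_error")
    }
  }
  structure(
    list(n_stakeholders = as.integer(n_stakeholders), k = as.integer(k),
         criteria = as.character(criteria), items = items,
         seed = as.integer(seed)),
    class = "panel_scenario"
  )
}

#' Generate a synthetic rating panel with known truth
#'
#' Draws each stakeholder x item x criterion score independently from the
#' item's criterion distribution, then masks it as an abstention with the
#' item's missingness rate. Stakeholder ids are `S01, S02, ...`. The truth
#' record carries each item's true criterion means and true CPI, so
#' parameter-recovery and interval-coverage checks compare against known
#' values rather than re-estimated ones.
#'
#' If an item's missingness is so high that a criterion could end up with
#' zero usable scores, that cell is left as generated and a warning is
#' raised; downstream validation flags it.
#'
#' @param scenario a [panel_scenario()].
#' @return List with `panel` (a [rating_panel()]) and `truth` (data frame:
#'   `item_id`, `population`, `true_mean_<criterion>` columns, `true_cpi`).
#' @export
generate_panel <- function(scenario) {
  n <- scenario$n_stakeholders
  ids <- sprintf("S%02d", seq_len(n))
  recs <- with_local_seed(scenario$seed, {
    rows <- lapply(scenario$items, function(it) {
      per_crit <- lapply(scenario$criteria, function(cr) {
        s <- sample.int(scenario$k, n, replace = TRUE,
                        prob = it$distributions[[cr]])
        s[stats::runif(n) < it$missing_rate] <- NA_integer_
        data.frame(stakeholder_id = ids, item_id = it$item_id,
                   criterion = cr, score = as.numeric(s),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_crit)
    })
    do.call(rbind, rows)
  })
  empties <- stats::aggregate(score ~ item_id + criterion, data = recs,
                              FUN = function(s) all(is.na(s)), na.action = NULL)
  if (any(empties$score)) {
    warning("some item/criterion cells generated with zero usable scores",
            call. = FALSE)
  }
  pops <- vapply(scenario$items, `[[`, character(1), "population")
  strata <- NULL
  if (any(!is.na(pops))) {
    labels <- ifelse(is.na(pops), "all", pops)
    strata <- stats::setNames(labels,
                              vapply(scenario$items, `[[`, character(1),
                                     "item_id"))
  }
  panel <- rating_panel(recs, k = scenario$k, criteria = scenario$criteria,
                        strata = strata)
  truth <- do.call(rbind, lapply(scenario$items, function(it) {
    row <- data.frame(item_id = it$item_id, population = it$population,
                      stringsAsFactors = FALSE)
    for (cr in scenario$criteria) {
      row[[paste0("true_mean_", cr)]] <- it$true_means[[cr]]
    }
    row$true_cpi <- it$true_cpi
    row
  }))
  list(panel = panel, truth = truth)
}

#' Matched scenarios with equal means and different dispersion
#'
#' Builds a pair of item scenarios sharing every true criterion mean but
#' differing in score variance, by mixing each base distribution with the
#' maximum-variance two-point distribution on levels `{1, k}` having the
#' same mean. `spread_delta` is the mixing weight: 0 returns two identical
#' scenarios, 1 moves all mass to the extremes. Used to check that wider
#' rating dispersion (weaker consensus) does not shrink bootstrap
#' intervals.
#'
#' @param base an [item_scenario()].
#' @param spread_delta mixing weight in `[0, 1]`.
#' @return List with `low` (the base) and `high` (the higher-dispersion
#'   scenario); item ids gain `_lo` / `_hi` suffixes.
#' @export
consensus_scenario_pair <- function(base, spread_delta) {
  if (spread_delta < 0 || spread_delta > 1) {
    cpi_stop("`spread_delta` must lie in [0, 1]", "cpi_argument_error")
  }
  k <- base$k
  lv <- seq_len(k)
  var_of <- function(p) sum(lv^2 * p) - sum(lv * p)^2
  high_dists <- lapply(names(base$distributions), function(cr) {
    p <- base$distributions[[cr]]
    m <- sum(lv * p)
    if (spread_delta == 0) return(p)
    if (m <= 1 + 1e-12 || m >= k - 1e-12) {
      cpi_stop(sprintf(
        "criterion '%s' mean %.3g is at the scale boundary; no added dispersion is possible",
        cr, m), "cpi_argument_error")
    }
    extreme <- numeric(k)
    extreme[k] <- (m - 1) / (k - 1)
    extreme[1] <- 1 - extreme[k]
    if (var_of(extreme) <= var_of(p) + 1e-12) {
      cpi_stop(sprintf(
        "criterion '%s' already has maximal dispersion for mean %.3g",
        cr, m), "cpi_argument_error")
    }
    (1 - spread_delta) * p + spread_delta * extreme
  })
  names(high_dists) <- names(base$distributions)
  suffix <- function(sc, tag, dists) {
    item_scenario(paste0(sc$item_id, tag), dists,
                  population = sc$population,
                  missing_rate = sc$missing_rate)
  }
  list(low = suffix(base, "_lo", base$distributions),
       high = suffix(base, "_hi", high_dists))
}

#' Read or write a panel scenario as JSON
#'
#' The scenario file holds `n_stakeholders`, `k`, `criteria`, `seed` and an
#' `items` array with `item_id`, optional `population`, `missing_rate` and
#' per-criterion probability vectors under `distributions`.
#'
#' @param path JSON file path.
#' @return `read_scenario()` a [panel_scenario()]; `write_scenario()` the
#'   path, invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    cpi_stop(paste0("scenario file not found: ", path), "cpi_io_error")
  }
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  items <- lapply(x$items, function(it) {
    item_scenario(it$item_id,
                  lapply(it$distributions, as.numeric),
                  population = if (is.null(it$population)) NA_character_
                               else it$population,
                  missing_rate = if (is.null(it$missing_rate)) 0
                                 else it$missing_rate)
  })
  panel_scenario(x$n_stakeholders, x$k, items,
                 criteria = unlist(x$criteria),
                 seed = if (is.null(x$seed)) 1L else x$seed)
}

#' @rdname read_scenario
#' @param scenario a [panel_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  x <- list(
    n_stakeholders = scenario$n_stakeholders, k = scenario$k,
    criteria = scenario$criteria, seed = scenario$seed,
    items = lapply(scenario$items, function(it) {
      list(item_id = it$item_id, population = it$population,
           missing_rate = it$missing_rate, distributions = it$distributions)
    })
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
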