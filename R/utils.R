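# Internal helpers shared across modules.

# Signal a classed condition so callers (and tests) can catch specific
# failure modes rather than matching message text.
cpi_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "cpi_error"), call = call))
}

#' Round half away from zero
#'
#' Decimal rounding in which exact halves round up in magnitude
#' (0.865 -> 0.87), the convention used when rendering CPI reports.
#' Base [round()] uses round-half-even, which would render some reported
#' scores differently from the usual presentation of priority tables.
#' A small decimal pre-rounding step absorbs binary floating-point noise so
#' that values intended as exact halves (e.g. 4.28 / 8 = 0.535) round the
#' way their decimal reading dictates.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, the reporting scale).
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(0.86625, 2) # 0.87
#' round_half_up(0.535, 2)   # 0.54
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's
# .Random.seed afterwards so library calls never perturb user RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic substream seed for one item: a 31-ary polynomial hash of the
# item id folded with the run seed, mod 2^31 - 1. Doubles hold every
# intermediate exactly (all < 2^53), so the stream is platform-stable and
# independent of the order in which items are processed.
item_stream_seed <- function(seed, item_id) {
  h <- 0
  for (b in utf8ToInt(as.character(item_id))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((h + (as.numeric(seed) %% 2147483647) * 69621) %% 2147483647)
}

format_num <- function(x, digits = 2) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), round_half_up(x, digits)))
}
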