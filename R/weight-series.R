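#' Nearest-day weight lookup
#'
#' Resolves the weight to use for a target postnatal day. An exact-day
#' measurement always wins; otherwise the measurement minimizing
#' `|measured day - target day|` is substituted provided the distance is at
#' most `tolerance_days`, with ties at equal distance broken toward the
#' earlier day (the earlier weight of a gaining infant is lower, which can
#' only push a gain criterion toward alarming — the conservative choice for
#' a screening rule). Returns `NULL` when nothing lies within tolerance.
#'
#' @param series tibble (or data.frame) with columns `day` and `weight_g`
#'   for one infant; may be `NULL` or empty.
#' @param day target postnatal day.
#' @param tolerance_days non-negative maximum substitution distance
#'   (default 2, the nearest-measurement rule stated for G-ROP and applied
#'   package-wide).
#' @return list with elements `day` and `weight_g`, or `NULL` if unresolved.
#' @export
weight_at <- function(series, day, tolerance_days = 2L) {
  if (is.na(tolerance_days) || tolerance_days < 0) {
    stop("tolerance_days must be non-negative", call. = FALSE)
  }
  if (is.null(series) || nrow(series) == 0L) return(NULL)
  dist <- abs(series$day - day)
  ok <- which(dist <= tolerance_days)
  if (!length(ok)) return(NULL)
  best <- ok[order(dist[ok], series$day[ok])][1L]
  list(day = series$day[best], weight_g = series$weight_g[best])
}

#' Windowed weight gain
#'
#' Weight gain between two nominal days, with both endpoints resolved via
#' [weight_at()] and the actually-used days recorded for audit. Gains are
#' the raw difference between the resolved weights: when substitution
#' shortens or lengthens the nominal window the gain is *not* rescaled,
#' because the rule sets compare raw gains against fixed gram thresholds.
#'
#' @inheritParams weight_at
#' @param start_day,end_day nominal window bounds, `start_day < end_day`.
#' @return list of class `window_gain` with fields `start_day`, `end_day`,
#'   `resolved_start`, `resolved_end` (each a `weight_at()` result or
#'   `NULL`) and `gain_g` (`NA` unless both endpoints resolved).
#' @export
window_gain <- function(series, start_day, end_day, tolerance_days = 2L) {
  stopifnot(start_day < end_day)
  s <- weight_at(series, start_day, tolerance_days)
  e <- weight_at(series, end_day, tolerance_days)
  gain <- if (!is.null(s) && !is.null(e)) e$weight_g - s$weight_g else NA_real_
  structure(list(start_day = start_day, end_day = end_day,
                 resolved_start = s, resolved_end = e, gain_g = gain),
            class = "window_gain")
}

#' Weekly daily weight-gain rate
#'
#' The daily gain rate computed from weekly measurements: the difference
#' between the weight at the end of the week and the weight one week
#' earlier, divided by 7. Negative rates (weight loss) are legitimate.
#'
#' @inheritParams weight_at
#' @param week_end_day postnatal day ending the week (must be at least 7).
#' @return rate in g/day, or `NA` if either endpoint fails to resolve.
#' @export
weekly_daily_rate <- function(series, week_end_day, tolerance_days = 2L) {
  stopifnot(week_end_day >= 7)
  cur <- weight_at(series, week_end_day, tolerance_days)
  prev <- weight_at(series, week_end_day - 7L, tolerance_days)
  if (is.null(cur) || is.null(prev)) return(NA_real_)
  (cur$weight_g - prev$weight_g) / 7
}

#' Postmenstrual age
#'
#' @param ga_days gestational age at birth in days.
#' @param postnatal_day postnatal day (birth = 0).
#' @return postmenstrual age in days (`ga_days + postnatal_day`).
#' @examples
#' pma_days(parse_ga("28+0"), 84) # 280 days = 40 weeks
#' @export
pma_days <- function(ga_days, postnatal_day) {
  stopifnot(all(ga_days >= 0), all(postnatal_day >= 0))
  as.integer(ga_days + postnatal_day)
}
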