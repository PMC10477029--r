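#' Alarm result
#'
#' Container for one algorithm's verdict on one infant. `eligible` records
#' the algorithm's entry gate, `evaluable` whether the verdict could be
#' determined from the available weights, `alarm` the positive screen, and
#' `triggered_criteria` which criterion ids fired (rule-based algorithms).
#'
#' @param algorithm one of `"grop"`, `"corop"`, `"choprop"`, `"winrop"`.
#' @param eligible,evaluable,alarm logicals.
#' @param triggered_criteria character vector of criterion ids; non-empty
#'   iff `alarm` for the rule-based algorithms.
#' @param alarm_day earliest postnatal day at which a fired criterion is
#'   determinable, or `NA`.
#' @param infant_id optional id carried through for pairing.
#' @return list of class `alarm_result`.
#' @export
alarm_result <- function(algorithm, eligible, evaluable, alarm,
                         triggered_criteria = character(0),
                         alarm_day = NA_integer_, infant_id = NA_character_) {
  stopifnot(algorithm %in% c("grop", "corop", "choprop", "winrop"))
  if (alarm && !(eligible && evaluable)) {
    stop("alarm implies eligible and evaluable", call. = FALSE)
  }
  structure(list(algorithm = algorithm, infant_id = infant_id,
                 eligible = eligible, evaluable = evaluable, alarm = alarm,
                 triggered_criteria = as.character(triggered_criteria),
                 alarm_day = as.integer(alarm_day)),
            class = "alarm_result")
}

# Rule-set day labels are written in the birth = day 0 convention; when a
# cohort charts birth as day 1 every day-window rule shifts by one.
rule_day <- function(day, birth_day_index = 0L) as.integer(day + birth_day_index)

#' G-ROP criteria
#'
#' The six-criterion screening rule set: (1) birth weight < 1051 g;
#' (2) GA < 28 weeks; (3) weight gain day 10–19 < 120 g; (4) gain day
#' 20–29 < 180 g; (5) gain day 30–39 < 170 g; (6) hydrocephalus. Window
#' endpoints are resolved by nearest measurement within `tolerance_days`.
#'
#' @param bw_max_g exclusive birth-weight bound (grams).
#' @param ga_max_days exclusive GA bound (days; 196 = 28 weeks).
#' @param windows data.frame with `start_day`, `end_day`,
#'   `gain_threshold_g` (alarm when gain strictly below threshold).
#' @param hydrocephalus_triggers logical; criterion 6 active.
#' @param tolerance_days nearest-day substitution tolerance.
#' @return list of class `grop_criteria`.
#' @export
grop_criteria <- function(bw_max_g = 1051,
                          ga_max_days = 196L,
                          windows = data.frame(
                            start_day = c(10L, 20L, 30L),
                            end_day = c(19L, 29L, 39L),
                            gain_threshold_g = c(120, 180, 170)),
                          hydrocephalus_triggers = TRUE,
                          tolerance_days = 2L) {
  stopifnot(bw_max_g > 0, ga_max_days > 0, all(windows$gain_threshold_g > 0),
            all(windows$start_day < windows$end_day))
  if (nrow(windows) > 1L) {
    o <- order(windows$start_day)
    windows <- windows[o, ]
    if (any(windows$start_day[-1L] <= windows$end_day[-nrow(windows)])) {
      stop("G-ROP windows must be non-overlapping and ordered", call. = FALSE)
    }
  }
  structure(list(bw_max_g = bw_max_g, ga_max_days = as.integer(ga_max_days),
                 windows = windows,
                 hydrocephalus_triggers = hydrocephalus_triggers,
                 tolerance_days = as.integer(tolerance_days)),
            class = "grop_criteria")
}

#' Evaluate the G-ROP rule set for one infant
#'
#' Alarm fires iff ANY of the six criteria holds. Every infant is entered
#' (the rule set has no separate entry gate). A window whose gain cannot be
#' resolved contributes "not met"; if no criterion fired while at least one
#' window was unresolvable the verdict is marked not evaluable, since a
#' complete series might still have alarmed.
#'
#' @param record one element of [as_infant_records()].
#' @param criteria a [grop_criteria()].
#' @param birth_day_index 0 if the weight series charts birth as day 0
#'   (default), 1 if as day 1; shifts all day-window rules.
#' @return an [alarm_result()].
#' @export
grop_evaluate <- function(record, criteria = grop_criteria(), birth_day_index = 0L) {
  fired <- character(0)
  fired_day <- integer(0)
  if (!is.na(record$bw_g) && record$bw_g < criteria$bw_max_g) {
    fired <- c(fired, "1"); fired_day <- c(fired_day, 0L)
  }
  if (!is.na(record$ga_days) && record$ga_days < criteria$ga_max_days) {
    fired <- c(fired, "2"); fired_day <- c(fired_day, 0L)
  }
  unresolved <- 0L
  for (k in seq_len(nrow(criteria$windows))) {
    wrow <- criteria$windows[k, ]
    g <- window_gain(record$weights,
                     rule_day(wrow$start_day, birth_day_index),
                     rule_day(wrow$end_day, birth_day_index),
                     criteria$tolerance_days)
    if (is.na(g$gain_g)) {
      unresolved <- unresolved + 1L
    } else if (g$gain_g < wrow$gain_threshold_g) {
      fired <- c(fired, as.character(k + 2L))
      fired_day <- c(fired_day, rule_day(wrow$end_day, birth_day_index))
    }
  }
  if (criteria$hydrocephalus_triggers && isTRUE(record$hydrocephalus)) {
    fired <- c(fired, "6"); fired_day <- c(fired_day, 0L)
  }
  alarm <- length(fired) > 0L
  evaluable <- alarm || unresolved == 0L
  alarm_result("grop",
               eligible = TRUE, evaluable = evaluable, alarm = alarm,
               triggered_criteria = sort(fired),
               alarm_day = if (alarm) min(fired_day) else NA_integer_,
               infant_id = record$infant_id)
}

#' CO-ROP criteria
#'
#' Alarm rule: GA at or below 30 weeks AND birth weight below 1501 g AND
#' net weight gain by postnatal day 28 of at most 650 g ("should not gain
#' more than 650 g": a gain of exactly 650 g alarms, 651 g does not).
#'
#' @param ga_max_days inclusive GA bound (days; 210 = 30 weeks).
#' @param bw_max_g exclusive BW bound (grams).
#' @param gain_day postnatal day at which the gain is assessed.
#' @param gain_threshold_g inclusive alarm threshold on the gain (grams).
#' @param tolerance_days nearest-day substitution tolerance for the
#'   day-28 weight.
#' @return list of class `corop_criteria`.
#' @export
corop_criteria <- function(ga_max_days = 210L, bw_max_g = 1501,
                           gain_day = 28L, gain_threshold_g = 650,
                           tolerance_days = 2L) {
  stopifnot(ga_max_days > 0, bw_max_g > 0, gain_day > 0, gain_threshold_g > 0)
  structure(list(ga_max_days = as.integer(ga_max_days), bw_max_g = bw_max_g,
                 gain_day = as.integer(gain_day),
                 gain_threshold_g = gain_threshold_g,
                 tolerance_days = as.integer(tolerance_days)),
            class = "corop_criteria")
}

#' Evaluate the CO-ROP rule for one infant
#'
#' All infants are entered; the GA/BW clauses are part of the alarm rule,
#' so an infant failing them is a determinate non-alarm. Only when the
#' GA/BW clauses hold but the day-28 weight cannot be resolved is the
#' verdict marked not evaluable.
#'
#' @inheritParams grop_evaluate
#' @param criteria a [corop_criteria()].
#' @return an [alarm_result()].
#' @export
corop_evaluate <- function(record, criteria = corop_criteria(), birth_day_index = 0L) {
  gates <- !is.na(record$ga_days) && record$ga_days <= criteria$ga_max_days &&
    !is.na(record$bw_g) && record$bw_g < criteria$bw_max_g
  if (!gates) {
    return(alarm_result("corop", eligible = TRUE, evaluable = TRUE,
                        alarm = FALSE, infant_id = record$infant_id))
  }
  target <- rule_day(criteria$gain_day, birth_day_index)
  w28 <- weight_at(record$weights, target, criteria$tolerance_days)
  if (is.null(w28)) {
    return(alarm_result("corop", eligible = TRUE, evaluable = FALSE,
                        alarm = FALSE, infant_id = record$infant_id))
  }
  gain <- w28$weight_g - record$bw_g
  alarm <- gain <= criteria$gain_threshold_g
  alarm_result("corop", eligible = TRUE, evaluable = TRUE, alarm = alarm,
               triggered_criteria = if (alarm) "gain_day28" else character(0),
               alarm_day = if (alarm) target else NA_integer_,
               infant_id = record$infant_id)
}

#' CHOPROP logistic risk model
#'
#' The CHOPROP alarm evaluates a logistic risk score on gestational age,
#' birth weight and the weekly-computed daily weight-gain rate, from the
#' end of the second week onwards, alarming when the risk reaches the
#' cutoff (0.014, inclusive). The published coefficient set is not shipped
#' with this package: coefficients are user configuration (see
#' [read_choprop_model()]), and their covariate scaling is part of that
#' configuration.
#'
#' @param intercept,beta_ga,beta_bw,beta_wg finite logistic coefficients;
#'   `beta_ga` per unit of `ga_scale`, `beta_bw` per gram, `beta_wg` per
#'   g/day.
#' @param cutoff alarm cutoff on the risk scale, in (0, 1); alarm when
#'   risk >= cutoff.
#' @param ga_scale `"days"` or `"weeks"`: the GA unit the coefficients
#'   expect.
#' @param eligibility_ga_max_days,eligibility_bw_max_g entry gate
#'   (GA < 31 weeks OR BW < 1501 g), both exclusive.
#' @return list of class `choprop_model`.
#' @export
choprop_model <- function(intercept, beta_ga, beta_bw, beta_wg,
                          cutoff = 0.014, ga_scale = c("days", "weeks"),
                          eligibility_ga_max_days = 217L,
                          eligibility_bw_max_g = 1501) {
  ga_scale <- match.arg(ga_scale)
  co <- c(intercept = intercept, beta_ga = beta_ga,
          beta_bw = beta_bw, beta_wg = beta_wg)
  if (any(!is.finite(co))) {
    stop("CHOPROP coefficients must all be finite numbers", call. = FALSE)
  }
  stopifnot(cutoff > 0, cutoff < 1)
  structure(list(intercept = intercept, beta_ga = beta_ga, beta_bw = beta_bw,
                 beta_wg = beta_wg, cutoff = cutoff, ga_scale = ga_scale,
                 eligibility_ga_max_days = as.integer(eligibility_ga_max_days),
                 eligibility_bw_max_g = eligibility_bw_max_g),
            class = "choprop_model")
}

#' Read a CHOPROP model from YAML
#'
#' Expects keys `intercept`, `beta_ga`, `beta_bw`, `beta_wg` and optionally
#' `cutoff` (default 0.014) and `ga_scale` (`days` or `weeks`, default
#' `days`). The published coefficients are not distributed here; obtain
#' them from the model's original publication and transcribe them into the
#' YAML file together with their covariate scaling.
#'
#' @param path YAML file path.
#' @return a [choprop_model()].
#' @export
read_choprop_model <- function(path) {
  if (!file.exists(path)) {
    stop("CHOPROP model file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  need <- c("intercept", "beta_ga", "beta_bw", "beta_wg")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop("CHOPROP model configuration missing coefficient(s): ",
         paste(miss, collapse = ", "),
         "; transcribe them from the model's source publication",
         call. = FALSE)
  }
  choprop_model(intercept = y$intercept, beta_ga = y$beta_ga,
                beta_bw = y$beta_bw, beta_wg = y$beta_wg,
                cutoff = if (is.null(y$cutoff)) 0.014 else y$cutoff,
                ga_scale = if (is.null(y$ga_scale)) "days" else y$ga_scale)
}

#' CHOPROP risk score
#'
#' `plogis(intercept + beta_ga * GA + beta_bw * BW + beta_wg * rate)`, with
#' GA converted to the model's configured unit. Strictly inside (0, 1).
#'
#' @param ga_days GA at birth in days.
#' @param bw_g birth weight in grams.
#' @param wg_rate_g_per_day daily weight-gain rate (g/day), typically from
#'   [weekly_daily_rate()].
#' @param model a [choprop_model()].
#' @return risk in (0, 1); vectorized over the inputs.
#' @export
choprop_risk <- function(ga_days, bw_g, wg_rate_g_per_day, model) {
  if (!inherits(model, "choprop_model")) {
    stop("a choprop_model is required; see read_choprop_model()", call. = FALSE)
  }
  ga <- if (model$ga_scale == "weeks") ga_days / 7 else ga_days
  stats::plogis(model$intercept + model$beta_ga * ga +
                  model$beta_bw * bw_g + model$beta_wg * wg_rate_g_per_day)
}

#' Evaluate the CHOPROP alarm for one infant
#'
#' Entry gate: GA < 31 weeks OR BW < 1501 g. From the end of week 2
#' onwards (days 14, 21, 28, ...) the weekly daily-gain rate feeds the
#' risk score; the alarm fires at the first week whose risk reaches the
#' cutoff. The first week's weight change is never used. An infant whose
#' week-2 endpoint cannot be resolved is not evaluable (the score requires
#' a documented end-of-week-2 weight); later unresolvable weeks are
#' skipped.
#'
#' @inheritParams grop_evaluate
#' @param model a [choprop_model()].
#' @param tolerance_days nearest-day substitution tolerance for weekly
#'   endpoints.
#' @return an [alarm_result()].
#' @export
choprop_evaluate <- function(record, model, birth_day_index = 0L,
                             tolerance_days = 2L) {
  if (!inherits(model, "choprop_model")) {
    stop("a choprop_model is required; see read_choprop_model()", call. = FALSE)
  }
  eligible <- (!is.na(record$ga_days) && record$ga_days < model$eligibility_ga_max_days) ||
    (!is.na(record$bw_g) && record$bw_g < model$eligibility_bw_max_g)
  if (!eligible) {
    return(alarm_result("choprop", eligible = FALSE, evaluable = TRUE,
                        alarm = FALSE, infant_id = record$infant_id))
  }
  last_day <- max(record$weights$day, 0L)
  week_ends <- seq(rule_day(14L, birth_day_index), by = 7L,
                   length.out = max(1L, (last_day + tolerance_days) %/% 7L))
  week2 <- weekly_daily_rate(record$weights, week_ends[1L], tolerance_days)
  if (is.na(week2)) {
    return(alarm_result("choprop", eligible = TRUE, evaluable = FALSE,
                        alarm = FALSE, infant_id = record$infant_id))
  }
  for (d in week_ends) {
    rate <- weekly_daily_rate(record$weights, d, tolerance_days)
    if (is.na(rate)) next
    risk <- choprop_risk(record$ga_days, record$bw_g, rate, model)
    if (risk >= model$cutoff) {
      return(alarm_result("choprop", eligible = TRUE, evaluable = TRUE,
                          alarm = TRUE, triggered_criteria = "risk_cutoff",
                          alarm_day = d, infant_id = record$infant_id))
    }
  }
  alarm_result("choprop", eligible = TRUE, evaluable = TRUE, alarm = FALSE,
               infant_id = record$infant_id)
}

#' WINROP gate and external-label adapter
#'
#' WINROP itself is a proprietary online longitudinal model and is not
#' reimplemented here. This adapter applies its entry gate — GA strictly
#' below 32 weeks, irrespective of birth weight — and passes through an
#' externally obtained alarm label. An eligible infant without a label is
#' marked not evaluable.
#'
#' @inheritParams grop_evaluate
#' @param label `TRUE`/`FALSE` alarm label from the external service, or
#'   `NA`/`NULL` when absent.
#' @param ga_max_days exclusive GA entry bound (224 days = 32 weeks).
#' @return an [alarm_result()].
#' @export
winrop_gate <- function(record, label, ga_max_days = 224L) {
  eligible <- !is.na(record$ga_days) && record$ga_days < ga_max_days
  if (!eligible) {
    return(alarm_result("winrop", eligible = FALSE, evaluable = TRUE,
                        alarm = FALSE, infant_id = record$infant_id))
  }
  if (is.null(label) || is.na(label)) {
    return(alarm_result("winrop", eligible = TRUE, evaluable = FALSE,
                        alarm = FALSE, infant_id = record$infant_id))
  }
  alarm_result("winrop", eligible = TRUE, evaluable = TRUE,
               alarm = isTRUE(as.logical(label)),
               triggered_criteria = if (isTRUE(as.logical(label))) "external" else character(0),
               infant_id = record$infant_id)
}

#' Read external WINROP alarm labels
#'
#' @param path CSV with columns `infant_id`, `alarm` (0/1).
#' @return named logical vector keyed by `infant_id`.
#' @export
read_winrop_labels <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         infant_id = readr::col_character(),
                         alarm = readr::col_integer()))
  stats::setNames(as.logical(x$alarm), x$infant_id)
}

#' Export a weight series for external WINROP entry
#'
#' WINROP accepts postnatal weights only up to 40 weeks of postmenstrual
#' age; later measurements are dropped from the export.
#'
#' @inheritParams grop_evaluate
#' @param pma_cap_days PMA cap in days (280 = 40 weeks).
#' @return tibble of `(day, weight_g)` with PMA at or below the cap.
#' @export
winrop_export <- function(record, pma_cap_days = 280L) {
  w <- record$weights
  w[pma_days(record$ga_days, w$day) <= pma_cap_days, ]
}

#' Screen a whole cohort
#'
#' Runs the selected algorithms over every infant and returns one row per
#' (infant, algorithm): entered, ineligible or excluded — never silently
#' absent. Infants flagged by [validate_for_algorithms()] are carried with
#' `excluded = TRUE` and `evaluable = FALSE` so attrition stays auditable.
#'
#' @param cohort an [rop_cohort].
#' @param algorithms subset of `c("grop", "corop", "choprop", "winrop")`.
#' @param choprop_model a [choprop_model()]; required when `"choprop"` is
#'   selected.
#' @param winrop_labels named logical vector from [read_winrop_labels()];
#'   eligible infants without a label become `evaluable = FALSE` (with a
#'   warning when labels were omitted entirely).
#' @param grop,corop criteria objects (defaults [grop_criteria()],
#'   [corop_criteria()]).
#' @param birth_day_index day-numbering convention switch (see
#'   [grop_evaluate()]).
#' @param tolerance_days nearest-day tolerance for CHOPROP weekly
#'   endpoints and exclusion checks.
#' @return tibble with columns `algorithm`, `infant_id`, `eligible`,
#'   `evaluable`, `alarm`, `triggered_criteria` (comma-joined ids),
#'   `alarm_day`, `excluded`, `exclusion_flags`.
#' @export
screen_cohort <- function(cohort,
                          algorithms = c("grop", "corop", "choprop", "winrop"),
                          choprop_model = NULL, winrop_labels = NULL,
                          grop = grop_criteria(), corop = corop_criteria(),
                          birth_day_index = 0L, tolerance_days = 2L) {
  stopifnot(inherits(cohort, "rop_cohort"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if ("choprop" %in% algorithms && !inherits(choprop_model, "choprop_model")) {
    stop("CHOPROP selected but no choprop_model supplied; ",
         "see read_choprop_model()", call. = FALSE)
  }
  if ("winrop" %in% algorithms && is.null(winrop_labels)) {
    warning("WINROP selected without external labels; eligible infants are ",
            "marked not evaluable", call. = FALSE)
    winrop_labels <- stats::setNames(logical(0), character(0))
  }
  records <- as_infant_records(cohort)
  checks <- validate_for_algorithms(cohort, tolerance_days)
  rows <- vector("list", length(records) * length(algorithms))
  k <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    excl <- checks$flags[[i]]
    for (alg in algorithms) {
      res <- if (length(excl)) {
        alarm_result(alg, eligible = TRUE, evaluable = FALSE, alarm = FALSE,
                     infant_id = rec$infant_id)
      } else {
        switch(alg,
          grop = grop_evaluate(rec, grop, birth_day_index),
          corop = corop_evaluate(rec, corop, birth_day_index),
          choprop = choprop_evaluate(rec, choprop_model, birth_day_index,
                                     tolerance_days),
          winrop = winrop_gate(rec, winrop_labels[rec$infant_id])
        )
      }
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        algorithm = alg,
        infant_id = rec$infant_id,
        eligible = res$eligible,
        evaluable = res$evaluable,
        alarm = res$alarm,
        triggered_criteria = paste(res$triggered_criteria, collapse = ","),
        alarm_day = res$alarm_day,
        excluded = length(excl) > 0L,
        exclusion_flags = paste(excl, collapse = ",")
      )
    }
  }
  dplyr::bind_rows(rows)
}
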