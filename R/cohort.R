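#' Gestational-age parsing and formatting
#'
#' Gestational age (GA) is stored internally in completed days
#' (`weeks * 7 + days`), which keeps postmenstrual-age and day-window
#' arithmetic unambiguous. `parse_ga()` accepts the clinical `"w+d"` notation
#' (e.g. `"28+3"`) as well as plain integer days; `format_ga()` renders days
#' back as `"w+d"`.
#'
#' @param x character or numeric vector. Strings of the form `"28+3"` are
#'   weeks+days; bare numerics are taken as days.
#' @return `parse_ga()`: integer vector of GA in days; `format_ga()`:
#'   character vector like `"28+3"`.
#' @examples
#' parse_ga(c("28+3", "31+0"))
#' format_ga(199L)
#' @export
parse_ga <- function(x) {
  if (is.numeric(x)) {
    return(as.integer(round(x)))
  }
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  plus <- grepl("+", x, fixed = TRUE)
  if (any(plus)) {
    parts <- strsplit(x[plus], "+", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) {
      stop("malformed gestational age string(s): ",
           paste(x[plus][bad], collapse = ", "), call. = FALSE)
    }
    wk <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    dy <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (anyNA(wk) || anyNA(dy) || any(dy < 0 | dy > 6)) {
      stop("malformed gestational age string(s): expected 'weeks+days' with days in 0-6",
           call. = FALSE)
    }
    out[plus] <- as.integer(wk * 7 + dy)
  }
  num <- !plus & !is.na(x) & x != ""
  out[num] <- as.integer(round(suppressWarnings(as.numeric(x[num]))))
  if (any(!plus & num & is.na(out[num]))) {
    stop("unparseable gestational age value(s)", call. = FALSE)
  }
  out
}

#' @rdname parse_ga
#' @export
format_ga <- function(x) {
  sprintf("%d+%d", x %/% 7L, x %% 7L)
}

# GA plausibility window: 22+0 to 42+0 weeks.
GA_DAYS_MIN <- 154L
GA_DAYS_MAX <- 294L

# Birth-weight warning band from the study cohort's observed range (grams).
BW_WARN_MIN <- 420
BW_WARN_MAX <- 2600

OUTCOME_LEVELS <- c("none", "mild", "type2", "type1")

#' Cohort container
#'
#' An `rop_cohort` bundles the per-infant table and the longitudinal weight
#' table, validated against the invariants every downstream stage assumes:
#' GA within 22+0–42+0 weeks, positive birth weight, strictly increasing
#' measurement days with at most one weight per day, a day-0 entry equal to
#' the birth weight, all type-1 infants treated, and treatment restricted to
#' type-1/type-2 infants.
#'
#' @param infants tibble with columns `infant_id`, `ga_days`, `bw_g`, `sex`
#'   (`"male"`, `"female"` or `"unknown"`), `hydrocephalus`,
#'   `nonphysiologic_weight`, `outcome` (`"none"`, `"mild"`, `"type2"`,
#'   `"type1"`), `treated`, and optionally `pma_treatment_days` and
#'   `unstable_course`.
#' @param weights tibble with columns `infant_id`, `day` (postnatal day,
#'   birth = day 0), `weight_g`.
#' @return an object of class `rop_cohort`: a list with elements `infants`
#'   and `weights`.
#' @export
rop_cohort <- function(infants, weights) {
  infants <- tibble::as_tibble(infants)
  weights <- tibble::as_tibble(weights)
  req_i <- c("infant_id", "ga_days", "bw_g", "sex", "hydrocephalus",
             "nonphysiologic_weight", "outcome", "treated")
  miss <- setdiff(req_i, names(infants))
  if (length(miss)) {
    stop("cohort table missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  req_w <- c("infant_id", "day", "weight_g")
  miss <- setdiff(req_w, names(weights))
  if (length(miss)) {
    stop("weights table missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"pma_treatment_days" %in% names(infants)) {
    infants$pma_treatment_days <- NA_integer_
  }
  if (!"unstable_course" %in% names(infants)) {
    infants$unstable_course <- FALSE
  }
  if (anyDuplicated(infants$infant_id)) {
    stop("duplicate infant_id in cohort table", call. = FALSE)
  }
  stray <- setdiff(unique(weights$infant_id), infants$infant_id)
  if (length(stray)) {
    stop("weight rows reference unknown infant_id(s): ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  if (!all(infants$outcome %in% OUTCOME_LEVELS)) {
    stop("outcome must be one of: ", paste(OUTCOME_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(infants$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be 'male', 'female' or 'unknown'", call. = FALSE)
  }
  ga_ok <- is.na(infants$ga_days) |
    (infants$ga_days >= GA_DAYS_MIN & infants$ga_days <= GA_DAYS_MAX)
  if (!all(ga_ok)) {
    stop("gestational age outside 22+0 to 42+0 weeks for infant(s): ",
         paste(infants$infant_id[!ga_ok], collapse = ", "), call. = FALSE)
  }
  if (any(infants$bw_g <= 0, na.rm = TRUE)) {
    stop("birth weight must be positive", call. = FALSE)
  }
  outside <- !is.na(infants$bw_g) &
    (infants$bw_g < BW_WARN_MIN | infants$bw_g > BW_WARN_MAX)
  if (any(outside)) {
    warning("birth weight outside the expected ", BW_WARN_MIN, "-", BW_WARN_MAX,
            " g band for infant(s): ",
            paste(infants$infant_id[outside], collapse = ", "), call. = FALSE)
  }
  bad_t1 <- infants$outcome == "type1" & !infants$treated
  if (any(bad_t1)) {
    stop("type-1 ROP implies treated == TRUE; violated by: ",
         paste(infants$infant_id[bad_t1], collapse = ", "), call. = FALSE)
  }
  bad_tr <- infants$treated & !infants$outcome %in% c("type1", "type2")
  if (any(bad_tr)) {
    stop("treated == TRUE requires type-1 or type-2 ROP; violated by: ",
         paste(infants$infant_id[bad_tr], collapse = ", "), call. = FALSE)
  }
  if (any(weights$day < 0) || any(weights$weight_g <= 0)) {
    stop("weight measurements need non-negative day and positive weight", call. = FALSE)
  }
  if (nrow(weights)) {
    dup <- weights |>
      dplyr::count(.data$infant_id, .data$day) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(dup)) {
      stop("more than one weight on the same day for infant(s): ",
           paste(unique(dup$infant_id), collapse = ", "), call. = FALSE)
    }
  }
  weights <- dplyr::arrange(weights, .data$infant_id, .data$day)
  # day-0 entry must exist and equal the birth weight
  d0 <- dplyr::filter(weights, .data$day == 0L)
  d0 <- d0[match(infants$infant_id, d0$infant_id), ]
  no_d0 <- is.na(d0$weight_g)
  if (any(no_d0)) {
    stop("weight series lacks a day-0 (birth) entry for infant(s): ",
         paste(infants$infant_id[no_d0], collapse = ", "), call. = FALSE)
  }
  mismatch <- abs(d0$weight_g - infants$bw_g) > 1e-6
  if (any(mismatch)) {
    stop("day-0 weight differs from birth weight for infant(s): ",
         paste(infants$infant_id[mismatch], collapse = ", "), call. = FALSE)
  }
  structure(list(infants = infants, weights = weights), class = "rop_cohort")
}

#' @export
print.rop_cohort <- function(x, ...) {
  n <- nrow(x$infants)
  cat("<rop_cohort> ", n, " infants, ", nrow(x$weights),
      " weight measurements\n", sep = "")
  if (n) {
    tab <- table(factor(x$infants$outcome, levels = OUTCOME_LEVELS))
    cat("  outcomes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "; treated=", sum(x$infants$treated), "\n", sep = "")
    cat("  median GA ", format_ga(as.integer(stats::median(x$infants$ga_days))),
        ", median BW ", stats::median(x$infants$bw_g), " g\n", sep = "")
  }
  invisible(x)
}

#' Read a cohort from delimited files
#'
#' Reads the two-file cohort interchange format: `cohort.csv` (one row per
#' infant; GA as either a `ga_weeks_days` column like `"28+3"` or a
#' `ga_days` column) and `weights.csv` (`infant_id`, `day`, `weight_g`).
#' Rows failing type checks are reported in the error, never silently
#' dropped; weight rows referencing an unknown infant raise a referential
#' error naming the id. A header-only file yields an empty cohort with a
#' warning.
#'
#' @param cohort_path,weights_path paths to the delimited files (UTF-8,
#'   comma-separated, header required).
#' @return an [rop_cohort].
#' @export
read_cohort <- function(cohort_path, weights_path) {
  inf <- readr::read_csv(cohort_path, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols())
  wts <- readr::read_csv(weights_path, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(
                           infant_id = readr::col_character(),
                           day = readr::col_integer(),
                           weight_g = readr::col_double()))
  if (!any(c("ga_weeks_days", "ga_days") %in% names(inf))) {
    stop("cohort file must contain a 'ga_weeks_days' or 'ga_days' column",
         call. = FALSE)
  }
  req <- c("infant_id", "bw_g", "sex", "hydrocephalus",
           "nonphysiologic_weight", "outcome", "treated")
  miss <- setdiff(req, names(inf))
  if (length(miss)) {
    stop("cohort file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(inf) == 0L) {
    warning("cohort file contains a header but no rows", call. = FALSE)
  }
  ga <- if ("ga_days" %in% names(inf)) parse_ga(inf$ga_days) else parse_ga(inf$ga_weeks_days)
  infants <- tibble::tibble(
    infant_id = as.character(inf$infant_id),
    ga_days = ga,
    bw_g = as.numeric(inf$bw_g),
    sex = as.character(inf$sex),
    hydrocephalus = as.logical(as.integer(inf$hydrocephalus)),
    nonphysiologic_weight = as.logical(as.integer(inf$nonphysiologic_weight)),
    outcome = as.character(inf$outcome),
    treated = as.logical(as.integer(inf$treated)),
    pma_treatment_days =
      if ("pma_treatment_days" %in% names(inf)) as.integer(inf$pma_treatment_days) else NA_integer_,
    unstable_course =
      if ("unstable_course" %in% names(inf)) as.logical(as.integer(inf$unstable_course)) else FALSE
  )
  rop_cohort(infants, wts)
}

#' Write a cohort to delimited files
#'
#' Inverse of [read_cohort()]: writes `cohort.csv` (GA serialized as
#' `ga_days`) and `weights.csv` such that reading them back reproduces every
#' field exactly.
#'
#' @param cohort an [rop_cohort].
#' @param cohort_path,weights_path output paths.
#' @return the two paths, invisibly.
#' @export
write_cohort <- function(cohort, cohort_path, weights_path) {
  stopifnot(inherits(cohort, "rop_cohort"))
  inf <- cohort$infants
  out <- tibble::tibble(
    infant_id = inf$infant_id,
    ga_days = inf$ga_days,
    bw_g = inf$bw_g,
    sex = inf$sex,
    hydrocephalus = as.integer(inf$hydrocephalus),
    nonphysiologic_weight = as.integer(inf$nonphysiologic_weight),
    outcome = inf$outcome,
    treated = as.integer(inf$treated),
    pma_treatment_days = inf$pma_treatment_days,
    unstable_course = as.integer(inf$unstable_course)
  )
  readr::write_csv(out, cohort_path, progress = FALSE)
  readr::write_csv(cohort$weights, weights_path, progress = FALSE)
  invisible(c(cohort = cohort_path, weights = weights_path))
}

#' Screening eligibility rule
#'
#' The unit's conventional screening criteria: examine infants with GA below
#' `ga_max_days` (default 31+0 weeks, exclusive) and/or BW below `bw_max_g`
#' (default 1250 g, exclusive), plus any infant flagged by the neonatologist
#' for an unstable clinical course (the `unstable_course` column overrides
#' both thresholds).
#'
#' @param ga_max_days exclusive GA bound in days (default `217` = 31 weeks).
#' @param bw_max_g exclusive BW bound in grams (default `1250`).
#' @param override_col name of the logical clinician-override column.
#' @return a list of class `eligibility_rule`.
#' @export
eligibility_rule <- function(ga_max_days = 217L, bw_max_g = 1250,
                             override_col = "unstable_course") {
  stopifnot(ga_max_days > 0, bw_max_g > 0)
  structure(list(ga_max_days = as.integer(ga_max_days),
                 bw_max_g = bw_max_g,
                 override_col = override_col),
            class = "eligibility_rule")
}

#' Screening eligibility
#'
#' @param infants the `infants` tibble of an [rop_cohort] (or the cohort
#'   itself).
#' @param rule an [eligibility_rule()].
#' @return logical vector, `TRUE` where the infant meets the screening
#'   criteria (GA below bound OR BW below bound OR clinician override).
#' @export
screening_eligible <- function(infants, rule = eligibility_rule()) {
  if (inherits(infants, "rop_cohort")) infants <- infants$infants
  ga <- infants$ga_days
  bw <- infants$bw_g
  if (any(is.na(ga) & is.na(bw))) {
    stop("cannot determine eligibility: both GA and BW missing for infant(s): ",
         paste(infants$infant_id[is.na(ga) & is.na(bw)], collapse = ", "),
         call. = FALSE)
  }
  override <- if (rule$override_col %in% names(infants)) {
    isTRUE_v(infants[[rule$override_col]])
  } else rep(FALSE, nrow(infants))
  ga_ok <- !is.na(ga) & ga < rule$ga_max_days
  bw_ok <- !is.na(bw) & bw < rule$bw_max_g
  ga_ok | bw_ok | override
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

# Anchor days any algorithm needs to resolve (CHOPROP week-2 end, CO-ROP
# day 28, the G-ROP window endpoints); used by validate_for_algorithms.
ALGORITHM_ANCHOR_DAYS <- c(10L, 14L, 19L, 20L, 28L, 29L, 30L, 39L)

#' Pre-analysis exclusion flags
#'
#' Classifies each infant against the study-style exclusion rules without
#' deleting anyone: records are flagged, and downstream stages decide entry,
#' so data loss stays auditable. Flags are:
#' `nonphysiologic_weight` (conditions such as severe subcutaneous oedema
#' that distort weight gain), `insufficient_weights` (no post-birth
#' measurement resolves any algorithm's required anchor day within the
#' tolerance), and `missing_outcome` (final ROP outcome undetermined).
#'
#' @param cohort an [rop_cohort].
#' @param tolerance_days nearest-day substitution tolerance used when
#'   checking whether anchor days resolve (default 2).
#' @return tibble with `infant_id`, `flags` (list of character vectors; empty
#'   means analyzable) and `analyzable` (logical).
#' @export
validate_for_algorithms <- function(cohort, tolerance_days = 2L) {
  stopifnot(inherits(cohort, "rop_cohort"))
  inf <- cohort$infants
  wts_by_id <- split(cohort$weights[c("day", "weight_g")], cohort$weights$infant_id)
  flags <- lapply(seq_len(nrow(inf)), function(i) {
    f <- character(0)
    if (isTRUE(inf$nonphysiologic_weight[i])) f <- c(f, "nonphysiologic_weight")
    w <- wts_by_id[[inf$infant_id[i]]]
    resolvable <- any(vapply(ALGORITHM_ANCHOR_DAYS, function(d) {
      !is.null(weight_at(w, d, tolerance_days))
    }, logical(1)))
    if (!resolvable) f <- c(f, "insufficient_weights")
    if (is.na(inf$outcome[i])) f <- c(f, "missing_outcome")
    f
  })
  tibble::tibble(
    infant_id = inf$infant_id,
    flags = flags,
    analyzable = lengths(flags) == 0L
  )
}

#' Split a cohort into per-infant records
#'
#' @param cohort an [rop_cohort].
#' @return named list (by `infant_id`) of records; each record is a list with
#'   the infant's scalar fields plus `weights`, a tibble of that infant's
#'   `(day, weight_g)` measurements.
#' @export
as_infant_records <- function(cohort) {
  stopifnot(inherits(cohort, "rop_cohort"))
  inf <- cohort$infants
  wts_by_id <- split(cohort$weights[c("day", "weight_g")], cohort$weights$infant_id)
  recs <- lapply(seq_len(nrow(inf)), function(i) {
    r <- as.list(inf[i, setdiff(names(inf), "weights")])
    r$weights <- tibble::as_tibble(wts_by_id[[inf$infant_id[i]]])
    r
  })
  names(recs) <- inf$infant_id
  recs
}
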