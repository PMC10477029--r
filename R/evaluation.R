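#' Analysis endpoints
#'
#' Each endpoint partitions the cohort into positives and negatives:
#' `type1` (type-1 ROP), `type2` (type-2 ROP; type-1 infants count as
#' negatives here), `treated` (received treatment), `any_rop` (any ROP
#' category other than none).
#'
#' @param infants the `infants` tibble of an [rop_cohort] (or the cohort).
#' @param endpoint one of `"type1"`, `"type2"`, `"treated"`, `"any_rop"`.
#' @return logical vector of endpoint positivity.
#' @export
endpoint_positive <- function(infants, endpoint) {
  if (inherits(infants, "rop_cohort")) infants <- infants$infants
  endpoint <- match.arg(endpoint, c("type1", "type2", "treated", "any_rop"))
  switch(endpoint,
         type1 = infants$outcome == "type1",
         type2 = infants$outcome == "type2",
         treated = isTRUE_v(infants$treated),
         any_rop = infants$outcome != "none")
}

#' Confusion table
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @param endpoint,algorithm identifying labels.
#' @return list of class `confusion_table` with the counts and
#'   `n_entered = tp + fp + fn + tn`.
#' @export
confusion_table <- function(tp, fp, fn, tn, endpoint = NA_character_,
                            algorithm = NA_character_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 n_entered = tp + fp + fn + tn,
                 endpoint = endpoint, algorithm = algorithm),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table>", x$algorithm, "x", x$endpoint,
      sprintf("(n=%d): tp=%d fp=%d fn=%d tn=%d\n",
              x$n_entered, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Cross-classify alarms against an endpoint
#'
#' Only infants that were eligible, evaluable and not excluded are entered;
#' everyone else is left out of `n_entered` (e.g. the WINROP gate drops
#' GA >= 32-week infants from its denominator).
#'
#' @param cohort an [rop_cohort].
#' @param alarms the rows of a [screen_cohort()] result for ONE algorithm.
#' @param endpoint endpoint name (see [endpoint_positive()]).
#' @return a [confusion_table()].
#' @export
confusion <- function(cohort, alarms, endpoint) {
  stopifnot(inherits(cohort, "rop_cohort"))
  if (length(unique(alarms$algorithm)) > 1L) {
    stop("alarms must come from a single algorithm", call. = FALSE)
  }
  inf <- cohort$infants
  idx <- match(alarms$infant_id, inf$infant_id)
  if (anyNA(idx)) {
    stop("alarm rows reference infant_id(s) absent from the cohort: ",
         paste(alarms$infant_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  entered <- alarms$eligible & alarms$evaluable & !alarms$excluded
  pos <- endpoint_positive(inf, endpoint)[idx]
  alarm <- alarms$alarm
  confusion_table(
    tp = sum(entered & alarm & pos),
    fp = sum(entered & alarm & !pos),
    fn = sum(entered & !alarm & pos),
    tn = sum(entered & !alarm & !pos),
    endpoint = endpoint,
    algorithm = alarms$algorithm[1L]
  )
}

#' Wilson score interval
#'
#' The score interval for a binomial proportion, without continuity
#' correction: with \eqn{\hat p = k/n} and \eqn{z} the two-sided normal
#' quantile, center \eqn{(\hat p + z^2/2n)/(1 + z^2/n)} and half-width
#' \eqn{z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}/(1 + z^2/n)}.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, at least 1.
#' @param level confidence level (default 0.95).
#' @return tibble with `point`, `lower`, `upper`, `level`, `method`.
#' @examples
#' wilson_ci(20, 24) # (0.641, 0.933)
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (any(n < 1)) {
    stop("Wilson interval undefined for n = 0", call. = FALSE)
  }
  stopifnot(all(k >= 0), all(k <= n), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(point = p,
                 lower = pmax(0, center - half),
                 upper = pmin(1, center + half),
                 level = level, method = "wilson")
}

#' Likelihood-ratio confidence interval (log method)
#'
#' Delta-method interval on the log likelihood ratio:
#' `exp(log(LR) +/- z * se)` with, for LR+,
#' `se^2 = (1-sens)/(sens*(tp+fn)) + spec/((1-spec)*(tn+fp))`, and for
#' LR-, `se^2 = sens/((1-sens)*(tp+fn)) + (1-spec)/(spec*(tn+fp))`.
#' Boundary cases return one-sided intervals with the degenerate bound
#' pinned: sensitivity 1 gives LR- = 0 with lower bound 0 (the upper bound
#' uses a half-count-corrected sensitivity); specificity 1 gives an
#' infinite LR+, reported as absent with a reason.
#'
#' @param ct a [confusion_table()].
#' @param which `"positive"` or `"negative"`.
#' @param level confidence level.
#' @return tibble with `point`, `lower`, `upper`, `level`, `method`,
#'   `reason` (`NA` unless the ratio is undefined).
#' @export
lr_ci_log <- function(ct, which = c("positive", "negative"), level = 0.95) {
  which <- match.arg(which)
  z <- stats::qnorm(1 - (1 - level) / 2)
  n1 <- ct$tp + ct$fn
  n0 <- ct$tn + ct$fp
  out <- function(point, lower, upper, reason = NA_character_) {
    tibble::tibble(point = point, lower = lower, upper = upper,
                   level = level, method = "log_lr", reason = reason)
  }
  if (n1 == 0L || n0 == 0L) {
    return(out(NA_real_, NA_real_, NA_real_, "no positives or no negatives entered"))
  }
  sens <- ct$tp / n1
  spec <- ct$tn / n0
  if (which == "positive") {
    if (spec == 1) {
      return(out(Inf, NA_real_, Inf, "specificity 1: LR+ infinite"))
    }
    if (sens == 0) {
      return(out(0, 0, NA_real_, "sensitivity 0: LR+ degenerate at 0"))
    }
    lr <- sens / (1 - spec)
    se <- sqrt((1 - sens) / (sens * n1) + spec / ((1 - spec) * n0))
    if (sens == 1) {
      # variance term for sens vanishes at the boundary; pin the upper
      # bound with a half-count-corrected sensitivity
      s2 <- (ct$tp - 0.5) / n1
      lr_lo <- s2 / (1 - spec)
      se2 <- sqrt((1 - s2) / (s2 * n1) + spec / ((1 - spec) * n0))
      return(out(lr, exp(log(lr_lo) - z * se2), exp(log(lr) + z * se)))
    }
    return(out(lr, exp(log(lr) - z * se), exp(log(lr) + z * se)))
  }
  # negative likelihood ratio
  if (spec == 0) {
    return(out(NA_real_, NA_real_, NA_real_, "specificity 0: LR- undefined"))
  }
  lr <- (1 - sens) / spec
  if (sens == 1) {
    s2 <- (ct$tp - 0.5) / n1
    lr_up <- (1 - s2) / spec
    se2 <- sqrt(s2 / ((1 - s2) * n1) + (1 - spec) / (spec * n0))
    return(out(0, 0, exp(log(lr_up) + z * se2)))
  }
  se <- sqrt(sens / ((1 - sens) * n1) + (1 - spec) / (spec * n0))
  out(lr, exp(log(lr) - z * se), exp(log(lr) + z * se))
}

#' Diagnostic summary for one confusion table
#'
#' Sensitivity, specificity, PPV and NPV with Wilson intervals, and the
#' positive/negative likelihood ratios with log-method intervals. Metrics
#' whose denominator is zero are reported as `NA` with a reason rather
#' than dropped.
#'
#' @param ct a [confusion_table()].
#' @param level confidence level.
#' @return tibble with one row per metric: `algorithm`, `endpoint`,
#'   `n_entered`, `tp`, `fp`, `fn`, `tn`, `metric`, `point`, `lower`,
#'   `upper`, `level`, `method`, `reason`.
#' @export
diagnostic_metrics <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  prop_row <- function(metric, k, n, reason_if_empty) {
    if (n == 0L) {
      tibble::tibble(metric = metric, point = NA_real_, lower = NA_real_,
                     upper = NA_real_, level = level, method = "wilson",
                     reason = reason_if_empty)
    } else {
      ci <- wilson_ci(k, n, level)
      tibble::tibble(metric = metric, point = ci$point, lower = ci$lower,
                     upper = ci$upper, level = level, method = "wilson",
                     reason = NA_character_)
    }
  }
  lr_row <- function(metric, which) {
    ci <- lr_ci_log(ct, which, level)
    tibble::tibble(metric = metric, point = ci$point, lower = ci$lower,
                   upper = ci$upper, level = level, method = "log_lr",
                   reason = ci$reason)
  }
  rows <- dplyr::bind_rows(
    prop_row("sensitivity", ct$tp, ct$tp + ct$fn, "no endpoint positives entered"),
    prop_row("specificity", ct$tn, ct$tn + ct$fp, "no endpoint negatives entered"),
    prop_row("ppv", ct$tp, ct$tp + ct$fp, "no alarms"),
    prop_row("npv", ct$tn, ct$tn + ct$fn, "no non-alarms"),
    lr_row("lr_positive", "positive"),
    lr_row("lr_negative", "negative")
  )
  tibble::tibble(algorithm = ct$algorithm, endpoint = ct$endpoint,
                 n_entered = ct$n_entered, tp = ct$tp, fp = ct$fp,
                 fn = ct$fn, tn = ct$tn, rows)
}

#' Exam-reduction analysis
#'
#' If the alarm decided who gets eye examinations, every entered,
#' non-alarmed infant would be spared one. Reports the spared count, the
#' percentage of all entered infants, and which ROP outcomes (type 1,
#' type 2, treated) the non-alarmed group contains — the infants the
#' strategy would have missed.
#'
#' @param cohort an [rop_cohort].
#' @param alarms [screen_cohort()] rows for one algorithm.
#' @return list with `count`, `n_entered`, `percent`, and `breakdown`
#'   (tibble of missed type-1, type-2 and treated counts).
#' @export
exam_reduction <- function(cohort, alarms) {
  stopifnot(inherits(cohort, "rop_cohort"))
  if (length(unique(alarms$algorithm)) > 1L) {
    stop("alarms must come from a single algorithm", call. = FALSE)
  }
  inf <- cohort$infants
  idx <- match(alarms$infant_id, inf$infant_id)
  entered <- alarms$eligible & alarms$evaluable & !alarms$excluded
  spared <- entered & !alarms$alarm
  n_entered <- sum(entered)
  breakdown <- tibble::tibble(
    missed_type1 = sum(spared & inf$outcome[idx] == "type1"),
    missed_type2 = sum(spared & inf$outcome[idx] == "type2"),
    missed_treated = sum(spared & isTRUE_v(inf$treated[idx]))
  )
  list(count = sum(spared), n_entered = n_entered,
       percent = if (n_entered) 100 * sum(spared) / n_entered else 0,
       breakdown = breakdown)
}

#' Full evaluation report
#'
#' One [diagnostic_metrics()] block per (algorithm, endpoint), plus
#' exam-reduction rows per algorithm (`metric` values
#' `exam_reduction_count` and `exam_reduction_percent`, `endpoint = "all"`).
#'
#' @param cohort an [rop_cohort].
#' @param alarms full [screen_cohort()] output (any number of algorithms).
#' @param endpoints endpoints to evaluate.
#' @param level confidence level.
#' @return long tibble (see [diagnostic_metrics()] for columns).
#' @export
evaluate_all <- function(cohort, alarms,
                         endpoints = c("type1", "type2", "treated", "any_rop"),
                         level = 0.95) {
  stopifnot(inherits(cohort, "rop_cohort"))
  if (nrow(alarms) == 0L) {
    warning("no alarm rows supplied; empty report", call. = FALSE)
    return(tibble::tibble())
  }
  blocks <- list()
  for (alg in unique(alarms$algorithm)) {
    a <- alarms[alarms$algorithm == alg, ]
    for (ep in endpoints) {
      blocks[[length(blocks) + 1L]] <-
        diagnostic_metrics(confusion(cohort, a, ep), level)
    }
    red <- exam_reduction(cohort, a)
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      algorithm = alg, endpoint = "all", n_entered = red$n_entered,
      tp = NA_integer_, fp = NA_integer_, fn = NA_integer_, tn = NA_integer_,
      metric = c("exam_reduction_count", "exam_reduction_percent"),
      point = c(red$count, red$percent),
      lower = NA_real_, upper = NA_real_, level = NA_real_,
      method = NA_character_, reason = NA_character_)
  }
  dplyr::bind_rows(blocks)
}

#' Write / read an evaluation report
#'
#' The CSV and JSON serializations carry identical values; `read_report()`
#' restores the tibble losslessly.
#'
#' @param report tibble from [evaluate_all()].
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return paths written, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(report, csv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_report
#' @param path a CSV written by `write_report()`.
#' @export
read_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    algorithm = readr::col_character(),
                    endpoint = readr::col_character(),
                    metric = readr::col_character(),
                    method = readr::col_character(),
                    reason = readr::col_character(),
                    n_entered = readr::col_integer(),
                    tp = readr::col_integer(), fp = readr::col_integer(),
                    fn = readr::col_integer(), tn = readr::col_integer(),
                    .default = readr::col_double()))
}

#' Render a report as a compact text table
#'
#' Percentages to one decimal place and likelihood ratios to two, in the
#' `point (lower-upper)` style familiar from diagnostic-accuracy tables;
#' full precision is retained in the underlying report.
#'
#' @param report tibble from [evaluate_all()].
#' @return character vector of formatted lines, invisibly printed.
#' @export
format_report <- function(report) {
  fmt <- function(metric, point, lower, upper) {
    if (is.na(point)) return("--")
    if (metric %in% c("lr_positive", "lr_negative")) {
      sprintf("%.2f (%.2f-%.2f)", point, lower, upper)
    } else if (metric == "exam_reduction_count") {
      sprintf("%d", as.integer(point))
    } else if (metric == "exam_reduction_percent") {
      sprintf("%.1f%%", point)
    } else {
      sprintf("%.1f%% (%.1f-%.1f)", 100 * point, 100 * lower, 100 * upper)
    }
  }
  lines <- character(0)
  for (ep in unique(report$endpoint)) {
    sub <- report[report$endpoint == ep, ]
    lines <- c(lines, paste0("== endpoint: ", ep, " =="))
    for (alg in unique(sub$algorithm)) {
      s <- sub[sub$algorithm == alg, ]
      vals <- vapply(seq_len(nrow(s)), function(i) {
        paste0(s$metric[i], " ", fmt(s$metric[i], s$point[i], s$lower[i], s$upper[i]))
      }, character(1))
      lines <- c(lines, paste0("  ", alg, " (n=", s$n_entered[1L], "): ",
                               paste(vals, collapse = "; ")))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Reconstruct a confusion table from published summary statistics
#'
#' Validation studies usually print the entered denominator, the number of
#' endpoint positives, and sensitivity/specificity as rounded percentages.
#' Because the underlying counts are integers, rounding to one decimal
#' place at these sample sizes identifies them uniquely:
#' `tp = round(sens/100 * n_pos)` and `tn = round(spec/100 * n_neg)`.
#'
#' @param n_entered total entered infants.
#' @param n_pos endpoint positives among them.
#' @param sens_pct,spec_pct printed sensitivity and specificity (percent).
#' @param endpoint,algorithm labels for the resulting table.
#' @return a [confusion_table()].
#' @export
reconstruct_confusion <- function(n_entered, n_pos, sens_pct, spec_pct,
                                  endpoint = NA_character_,
                                  algorithm = NA_character_) {
  n_neg <- n_entered - n_pos
  tp <- round(sens_pct / 100 * n_pos)
  tn <- round(spec_pct / 100 * n_neg)
  confusion_table(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn,
                  endpoint = endpoint, algorithm = algorithm)
}
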