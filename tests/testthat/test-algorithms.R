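weights_for_gains <- function(bw, gains) {
  # exact-day series realizing the three window gains (day10-19, 20-29, 30-39)
  w10 <- bw + 120
  tibble::tibble(
    day = c(0L, 10L, 19L, 20L, 29L, 30L, 39L),
    weight_g = c(bw, w10, w10 + gains[1], w10 + gains[1] + 20,
                 w10 + gains[1] + 20 + gains[2],
                 w10 + gains[1] + 20 + gains[2] + 15,
                 w10 + gains[1] + 20 + gains[2] + 15 + gains[3]))
}

test_that("G-ROP alarms on any of the six criteria", {
  # criterion 1: birth weight below 1051 g
  r <- make_record(ga_days = parse_ga("30+0"), bw_g = 1050,
                   weights = weights_for_gains(1050, c(200, 200, 200)))
  res <- grop_evaluate(r)
  expect_true(res$alarm)
  expect_equal(res$triggered_criteria, "1")
  expect_equal(res$alarm_day, 0L)

  # criterion 3: day 10-19 gain below 120 g
  r <- make_record(ga_days = parse_ga("29+0"), bw_g = 1200,
                   weights = weights_for_gains(1200, c(110, 200, 200)))
  res <- grop_evaluate(r)
  expect_true(res$alarm)
  expect_equal(res$triggered_criteria, "3")
  expect_equal(res$alarm_day, 19L)

  # no criterion met
  r <- make_record(ga_days = parse_ga("29+0"), bw_g = 1200,
                   weights = weights_for_gains(1200, c(150, 200, 200)))
  res <- grop_evaluate(r)
  expect_false(res$alarm)
  expect_true(res$evaluable)
  expect_length(res$triggered_criteria, 0)

  # criterion 6: hydrocephalus alone
  r <- make_record(ga_days = parse_ga("29+0"), bw_g = 1200, hydrocephalus = TRUE,
                   weights = weights_for_gains(1200, c(150, 200, 200)))
  expect_equal(grop_evaluate(r)$triggered_criteria, "6")

  # unresolvable window with nothing fired -> not evaluable
  r <- make_record(ga_days = parse_ga("29+0"), bw_g = 1200,
                   weights = tibble::tibble(day = c(0L, 10L, 19L),
                                            weight_g = c(1200, 1350, 1500)))
  res <- grop_evaluate(r)
  expect_false(res$alarm)
  expect_false(res$evaluable)
})

test_that("G-ROP equals the brute-force six-criterion oracle on random records", {
  set.seed(31)
  for (i in 1:500) {
    r <- random_record(sprintf("R%04d", i))
    expect_equal(grop_evaluate(r)$alarm, grop_oracle(r), label = r$infant_id)
  }
})

test_that("G-ROP alarm is monotone under decreasing gains, BW and GA", {
  set.seed(32)
  for (i in 1:100) {
    gains <- runif(3, 100, 260)
    r <- make_record(ga_days = sample(196:240, 1), bw_g = runif(1, 1051, 2000),
                     weights = weights_for_gains(1300, gains))
    res <- grop_evaluate(r)
    # decrease one lever at a time
    r_bw <- r; r_bw$bw_g <- r$bw_g - runif(1, 0, 600)
    r_ga <- r; r_ga$ga_days <- r$ga_days - sample(0:40, 1)
    shrink <- runif(1, 0, 80)
    r_wg <- r; r_wg$weights <- weights_for_gains(1300, gains - shrink)
    for (worse in list(r_bw, r_ga, r_wg)) {
      if (res$alarm) expect_true(grop_evaluate(worse)$alarm)
    }
  }
  # any infant under 28 weeks GA alarms irrespective of weights
  for (i in 1:50) {
    r <- random_record(sprintf("S%03d", i))
    r$ga_days <- sample(154:195, 1)
    expect_true(grop_evaluate(r)$alarm)
  }
})

test_that("CO-ROP requires all three clauses, with stated boundary behavior", {
  w28 <- function(bw, w) tibble::tibble(day = c(0L, 28L), weight_g = c(bw, w))
  # all clauses hold: GA 30+0 (inclusive bound), gain 600 <= 650
  r <- make_record(ga_days = parse_ga("30+0"), bw_g = 1400,
                   weights = w28(1400, 2000))
  res <- corop_evaluate(r)
  expect_true(res$alarm)
  expect_equal(res$alarm_day, 28L)
  # GA clause fails one day over the inclusive bound
  r <- make_record(ga_days = parse_ga("30+1"), bw_g = 900,
                   weights = w28(900, 1200))
  res <- corop_evaluate(r)
  expect_false(res$alarm)
  expect_true(res$evaluable)
  # gain of exactly 650 alarms; 651+ does not ("not more than 650")
  r <- make_record(ga_days = parse_ga("28+0"), bw_g = 1200,
                   weights = w28(1200, 1850))
  expect_true(corop_evaluate(r)$alarm)
  r <- make_record(ga_days = parse_ga("28+0"), bw_g = 1200,
                   weights = w28(1200, 1900))
  expect_false(corop_evaluate(r)$alarm)
  # BW bound exclusive at 1501
  r <- make_record(ga_days = parse_ga("28+0"), bw_g = 1501,
                   weights = w28(1501, 1700))
  expect_false(corop_evaluate(r)$alarm)
  # unresolvable day-28 weight with clauses passing -> not evaluable
  r <- make_record(ga_days = parse_ga("28+0"), bw_g = 1200,
                   weights = tibble::tibble(day = 0L, weight_g = 1200))
  res <- corop_evaluate(r)
  expect_false(res$evaluable)
  expect_false(res$alarm)
})

test_that("CO-ROP alarm is monotone in decreasing day-28 gain", {
  set.seed(33)
  for (i in 1:100) {
    bw <- runif(1, 500, 1490)
    gain <- runif(1, 200, 900)
    r <- make_record(ga_days = sample(154:210, 1), bw_g = bw,
                     weights = tibble::tibble(day = c(0L, 28L),
                                              weight_g = c(bw, bw + gain)))
    if (corop_evaluate(r)$alarm) {
      r2 <- r
      r2$weights$weight_g[2] <- r$weights$weight_g[2] - runif(1, 0, 200)
      expect_true(corop_evaluate(r2)$alarm)
    }
  }
})

test_that("CHOPROP risk is the logistic of the linear predictor", {
  m0 <- choprop_model(0, 0, 0, 0)
  expect_equal(choprop_risk(200, 1000, 15, m0), 0.5)
  m4 <- choprop_model(-4, 0, 0, 0)
  expect_equal(choprop_risk(200, 1000, 15, m4), 1 / (1 + exp(4)))
  expect_equal(round(choprop_risk(180, 700, 5, m4), 4), 0.0180)
  # beta_wg < 0 makes risk strictly decreasing in the gain rate
  m <- choprop_model(0, 0, 0, -0.5)
  risks <- choprop_risk(200, 1000, c(0, 5, 10, 20), m)
  expect_true(all(diff(risks) < 0))
  expect_true(all(risks > 0 & risks < 1))
  # GA unit conversion
  mw <- choprop_model(0, 1, 0, 0, ga_scale = "weeks")
  expect_equal(choprop_risk(210, 1000, 0, mw), plogis(30))
  expect_error(choprop_model(Inf, 0, 0, 0), "finite")
})

test_that("CHOPROP alarms at the first weekly risk crossing, cutoff inclusive", {
  # rate-only model: risk 0.010 at day 14 (rate 10), 0.020 at day 21 (rate 20)
  b <- (qlogis(0.02) - qlogis(0.01)) / 10
  a <- qlogis(0.01) - 10 * b
  m <- choprop_model(a, 0, 0, b)
  r <- make_record(ga_days = parse_ga("28+0"), bw_g = 1000,
                   weights = tibble::tibble(day = c(0L, 7L, 14L, 21L),
                                            weight_g = c(1000, 1000, 1070, 1210)))
  res <- choprop_evaluate(r, m)
  expect_true(res$alarm)
  expect_equal(res$alarm_day, 21L)
  expect_equal(round(choprop_risk(r$ga_days, r$bw_g, 10, m), 3), 0.010)

  # risk exactly at the cutoff alarms (inclusive comparison)
  m_exact <- choprop_model(qlogis(0.014), 0, 0, 0)
  res <- choprop_evaluate(r, m_exact)
  expect_true(res$alarm)
  expect_equal(res$alarm_day, 14L)

  # entry gate: GA 32+0 and BW 1600 is ineligible
  r2 <- make_record(ga_days = parse_ga("32+0"), bw_g = 1600)
  res <- choprop_evaluate(r2, m)
  expect_false(res$eligible)
  expect_false(res$alarm)

  # no resolvable week-2 endpoint -> not evaluable
  r3 <- make_record(ga_days = parse_ga("28+0"), bw_g = 1000,
                    weights = tibble::tibble(day = c(0L, 21L, 28L),
                                             weight_g = c(1000, 1200, 1350)))
  expect_false(choprop_evaluate(r3, m)$evaluable)

  # week-1 change is never used: only days 7+ feed the score
  m_w1 <- choprop_model(qlogis(0.5), 0, 0, -10)
  r4 <- make_record(ga_days = parse_ga("28+0"), bw_g = 1000,
                    weights = tibble::tibble(day = c(0L, 7L, 14L),
                                             weight_g = c(1000, 400, 1800)))
  # day 0-7 collapse (rate -85.7) would alarm if week 1 counted; days 7-14
  # rebound strongly (rate 200) so the score stays quiet
  expect_false(choprop_evaluate(r4, m_w1)$alarm)
})

test_that("CHOPROP alarm day is non-decreasing in the cutoff", {
  set.seed(34)
  b <- -0.2
  for (i in 1:50) {
    bw <- runif(1, 500, 1400)
    days <- seq(0L, 49L, by = 7L)
    w <- tibble::tibble(day = days,
                        weight_g = round(bw + cumsum(c(0, runif(7, -20, 180)))))
    r <- make_record(ga_days = sample(154:216, 1), bw_g = bw, weights = w)
    day_at <- function(cut) {
      m <- choprop_model(qlogis(0.05), 0, 0, b, cutoff = cut)
      res <- choprop_evaluate(r, m)
      if (res$alarm) res$alarm_day else 9999 # never alarms: later than any day
    }
    cuts <- sort(runif(3, 0.005, 0.2))
    expect_true(all(diff(vapply(cuts, day_at, numeric(1))) >= 0))
  }
})

test_that("WINROP gate applies the 32-week bound and passes labels through", {
  r <- make_record(ga_days = parse_ga("32+0"), bw_g = 1000)
  res <- winrop_gate(r, TRUE)
  expect_false(res$eligible)
  expect_false(res$alarm)

  r <- make_record(ga_days = parse_ga("28+0"), bw_g = 1000)
  expect_true(winrop_gate(r, TRUE)$alarm)
  expect_false(winrop_gate(r, FALSE)$alarm)
  res <- winrop_gate(r, NA)
  expect_true(res$eligible)
  expect_false(res$evaluable)
})

test_that("WINROP export drops weights past 40 weeks postmenstrual age", {
  r <- make_record(ga_days = parse_ga("28+0"), bw_g = 1000,
                   weights = tibble::tibble(day = c(0L, 56L, 84L, 91L),
                                            weight_g = c(1000, 1800, 2600, 2800)))
  out <- winrop_export(r)
  expect_equal(out$day, c(0L, 56L, 84L))
})

test_that("screen_cohort yields one row per infant and algorithm", {
  ch <- sample_cohort(10, seed = 9)
  al <- screen_cohort(ch, c("grop", "corop"))
  expect_equal(nrow(al), 20L)
  expect_equal(sort(unique(al$algorithm)), c("corop", "grop"))
  expect_setequal(unique(al$infant_id), ch$infants$infant_id)
  # alarm implies eligible and evaluable
  expect_true(all(!al$alarm | (al$eligible & al$evaluable)))
  # rule-based algorithms: triggered criteria non-empty iff alarm
  expect_true(all((al$triggered_criteria != "") == al$alarm))
  # CHOPROP without a model is a configuration error
  expect_error(screen_cohort(ch, "choprop"), "choprop_model")
  # WINROP without labels: warn and mark eligible infants not evaluable
  expect_warning(alw <- screen_cohort(ch, "winrop"), "labels")
  expect_true(all(!alw$evaluable[alw$eligible]))
})
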