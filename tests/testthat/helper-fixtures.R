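# Shared fixtures and independent oracles for the test suite.

# A minimal per-infant record (the shape as_infant_records() produces).
make_record <- function(ga_days = 203L, bw_g = 1200, hydrocephalus = FALSE,
                        weights = NULL, infant_id = "T001",
                        outcome = "none", treated = FALSE) {
  if (is.null(weights)) {
    weights <- tibble::tibble(day = c(0L, 10L, 19L, 20L, 28L, 29L, 30L, 39L),
                              weight_g = bw_g + c(0, 150, 300, 320, 480, 500,
                                                  520, 700))
  }
  list(infant_id = infant_id, ga_days = ga_days, bw_g = bw_g,
       sex = "female", hydrocephalus = hydrocephalus,
       nonphysiologic_weight = FALSE, outcome = outcome, treated = treated,
       pma_treatment_days = NA_integer_, unstable_course = FALSE,
       weights = weights)
}

# A tiny valid two-infant cohort.
make_toy_cohort <- function() {
  infants <- tibble::tibble(
    infant_id = c("A", "B"),
    ga_days = c(parse_ga("28+3"), parse_ga("31+0")),
    bw_g = c(1100, 1400),
    sex = c("male", "female"),
    hydrocephalus = c(FALSE, FALSE),
    nonphysiologic_weight = c(FALSE, FALSE),
    outcome = c("type1", "none"),
    treated = c(TRUE, FALSE),
    pma_treatment_days = c(260L, NA_integer_),
    unstable_course = c(FALSE, FALSE)
  )
  weights <- tibble::tibble(
    infant_id = c("A", "A", "B", "B"),
    day = c(0L, 14L, 0L, 14L),
    weight_g = c(1100, 1210, 1400, 1560)
  )
  rop_cohort(infants, weights)
}

# Independent Wilson oracle: solve the score equation
# (phat - p)^2 = z^2 p (1-p) / n by root finding, not by the closed form.
wilson_oracle <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- k / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # p = 0 and p = 1 are trivial roots of the score equation when phat sits
  # on the boundary; bracket away from them so uniroot finds the score root
  eps <- 1e-9
  lo <- if (k == 0) 0 else
    uniroot(f, c(0, min(phat, 1 - eps)), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    uniroot(f, c(max(phat, eps), 1), tol = 1e-12)$root
  c(lower = lo, upper = hi)
}

# Independent G-ROP oracle: re-derives every criterion from scratch with
# its own nearest-day search (no calls into weight_at / window_gain).
grop_oracle <- function(record, tolerance = 2L) {
  nearest <- function(day) {
    d <- record$weights$day
    dist <- abs(d - day)
    ok <- which(dist <= tolerance)
    if (!length(ok)) return(NA_real_)
    best <- ok[order(dist[ok], d[ok])][1L]
    record$weights$weight_g[best]
  }
  gains <- c(nearest(19) - nearest(10),
             nearest(29) - nearest(20),
             nearest(39) - nearest(30))
  crit <- c(record$bw_g < 1051,
            record$ga_days < 196,
            !is.na(gains[1]) && gains[1] < 120,
            !is.na(gains[2]) && gains[2] < 180,
            !is.na(gains[3]) && gains[3] < 170,
            isTRUE(record$hydrocephalus))
  any(crit)
}

# Random record generator for property tests (sparse, irregular series).
random_record <- function(id) {
  ga <- sample(154:294, 1)
  bw <- runif(1, 450, 2500)
  days <- sort(sample(1:45, sample(3:12, 1)))
  weights <- tibble::tibble(
    day = c(0L, days),
    weight_g = round(bw + c(0, cumsum(runif(length(days), -30, 90))))
  )
  weights$weight_g <- pmax(weights$weight_g, 1)
  make_record(ga_days = ga, bw_g = bw,
              hydrocephalus = runif(1) < 0.05,
              weights = weights, infant_id = id)
}
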