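#' Outcome-group demographic parameters
#'
#' Default per-group parameters calibrated to the demographics of a
#' 531-infant screened NICU cohort: group frequencies 175/531 (no ROP),
#' 292/531 (mild), 40/531 (type 2), 24/531 (type 1); birth-weight
#' means/SDs 1257 (265), 1078 (301), 912.2 (248.0), 719.4 (201.8) g with
#' the observed group ranges as truncation bounds; GA means 29+6, 28+0,
#' 27+0, 25+0 weeks with SD 2 weeks (14 days) and the observed ranges.
#' All type-1 infants are treated; type-2 infants are treated with
#' probability 5/40. The per-group daily gain rates (`gain_mean_g_per_day`,
#' `gain_sd`) are *generator inventions* — chosen so that slower growth
#' accompanies worse outcomes and default cohorts qualitatively reproduce
#' the ordering of the algorithms' specificities — and are NOT published
#' values.
#'
#' @return tibble with one row per outcome group.
#' @export
group_params <- function() {
  tibble::tibble(
    outcome = c("none", "mild", "type2", "type1"),
    prob = c(175, 292, 40, 24) / 531,
    bw_mean_g = c(1257, 1078, 912.2, 719.4),
    bw_sd_g = c(265, 301, 248.0, 201.8),
    bw_min_g = c(610, 510, 475, 420),
    bw_max_g = c(2040, 2600, 1490, 1220),
    ga_mean_days = c(209, 196, 189, 175),
    ga_sd_days = c(14, 14, 14, 14),
    ga_min_days = c(177, 162, 165, 161),
    ga_max_days = c(241, 260, 219, 194),
    gain_mean_g_per_day = c(28, 23, 19, 12),
    gain_sd = c(4, 4, 4, 3),
    treated_prob = c(0, 0, 5 / 40, 1)
  )
}

#' Weight-trajectory parameters
#'
#' Shape of the simulated postnatal weight curve: an initial linear loss
#' of `nadir_fraction` of birth weight reaching its nadir at `nadir_day`,
#' linear regain of birth weight by `regain_day`, then steady growth at
#' the infant's daily gain rate with day-to-day noise
#' (`daily_noise_sd_g`). Measurements are charted every
#' `measurement_cadence_days` days and dropped independently with
#' probability `missingness_prob` (day 0 is never dropped).
#'
#' @param nadir_day day of maximum physiologic weight loss (default 4).
#' @param nadir_fraction fraction of birth weight lost, in (0, 0.2)
#'   (default 0.07, a typical 5–10% physiologic loss).
#' @param regain_day day birth weight is regained (default 12).
#' @param measurement_cadence_days charting interval in days (default 1;
#'   NICU weights are charted daily).
#' @param missingness_prob per-measurement drop probability (default 0.05).
#' @param daily_noise_sd_g SD of day-to-day weight fluctuation in grams
#'   (default 6).
#' @return list of class `trajectory_params`.
#' @export
trajectory_params <- function(nadir_day = 4L, nadir_fraction = 0.07,
                              regain_day = 12L, measurement_cadence_days = 1L,
                              missingness_prob = 0.05, daily_noise_sd_g = 6) {
  stopifnot(nadir_fraction > 0, nadir_fraction < 0.2,
            measurement_cadence_days >= 1, nadir_day < regain_day,
            missingness_prob >= 0, missingness_prob < 1)
  structure(list(nadir_day = as.integer(nadir_day),
                 nadir_fraction = nadir_fraction,
                 regain_day = as.integer(regain_day),
                 measurement_cadence_days = as.integer(measurement_cadence_days),
                 missingness_prob = missingness_prob,
                 daily_noise_sd_g = daily_noise_sd_g),
            class = "trajectory_params")
}

# Truncated-normal draw by rejection (avoids boundary atoms that clipping
# would create).
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

# Jointly truncated GA/BW pair from a Gaussian copula with latent
# correlation rho (positive GA-BW association within outcome group).
sample_ga_bw <- function(n, g, rho = 0.5) {
  ga <- numeric(n); bw <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    ga_try <- g$ga_mean_days + g$ga_sd_days * z1
    bw_try <- g$bw_mean_g + g$bw_sd_g * z2
    ok <- ga_try >= g$ga_min_days & ga_try <= g$ga_max_days &
      bw_try >= g$bw_min_g & bw_try <= g$bw_max_g
    ga[todo[ok]] <- ga_try[ok]
    bw[todo[ok]] <- bw_try[ok]
    todo <- todo[!ok]
  }
  list(ga_days = as.integer(round(ga)), bw_g = round(bw))
}

#' Simulate one postnatal weight series
#'
#' Piecewise trajectory: linear loss to `bw_g * (1 - nadir_fraction)` at
#' the nadir day, linear regain to birth weight by the regain day, then
#' daily increments drawn from `Normal(gain_rate, daily_noise_sd_g)`.
#' The daily curve is then sampled at the charting cadence and thinned by
#' the missingness probability; day 0 always remains and weights are kept
#' strictly positive.
#'
#' @param bw_g birth weight in grams.
#' @param gain_rate the infant's steady daily gain rate (g/day).
#' @param traj a [trajectory_params()].
#' @param n_days length of follow-up in days.
#' @return tibble of `(day, weight_g)`, weights rounded to whole grams.
#' @export
simulate_weights <- function(bw_g, gain_rate, traj = trajectory_params(),
                             n_days = 70L) {
  stopifnot(bw_g > 0, n_days >= 0)
  days <- 0:n_days
  nadir_w <- bw_g * (1 - traj$nadir_fraction)
  w <- numeric(n_days + 1L)
  pre <- days <= traj$nadir_day
  w[pre] <- bw_g + (nadir_w - bw_g) * days[pre] / traj$nadir_day
  mid <- days > traj$nadir_day & days <= traj$regain_day
  w[mid] <- nadir_w + (bw_g - nadir_w) *
    (days[mid] - traj$nadir_day) / (traj$regain_day - traj$nadir_day)
  post <- days > traj$regain_day
  if (any(post)) {
    incr <- stats::rnorm(sum(post), gain_rate, traj$daily_noise_sd_g)
    w[post] <- bw_g + cumsum(incr)
  }
  w <- pmax(round(w), 1)
  keep <- days %% traj$measurement_cadence_days == 0L
  if (traj$missingness_prob > 0) {
    keep <- keep & (days == 0L |
      stats::runif(n_days + 1L) >= traj$missingness_prob)
  }
  tibble::tibble(day = days[keep], weight_g = w[keep])
}

#' Draw one synthetic infant
#'
#' Draws the outcome group from the group frequencies, GA and BW from the
#' group's truncated (jointly correlated) normals, the treatment flag from
#' the group's treatment probability, and a weight series from
#' [simulate_weights()] with follow-up lasting to roughly 40 weeks
#' postmenstrual age. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param groups a [group_params()] tibble.
#' @param traj a [trajectory_params()].
#' @param infant_id id string for the record.
#' @param ga_bw_rho latent GA–BW correlation within group (default 0.5).
#' @return a record list matching [as_infant_records()] elements.
#' @export
sample_infant <- function(groups = group_params(), traj = trajectory_params(),
                          infant_id = "SIM00001", ga_bw_rho = 0.5) {
  ch <- sample_cohort(1L, groups, traj, ga_bw_rho = ga_bw_rho,
                      id_prefix = sub("[0-9]+$", "", infant_id))
  rec <- as_infant_records(ch)[[1L]]
  rec$infant_id <- infant_id
  rec
}

#' Draw a synthetic cohort
#'
#' Vectorized cohort draw; see [sample_infant()] for the per-infant model.
#' With a fixed `seed` the result is bit-identical across runs.
#'
#' @param n number of infants.
#' @param groups a [group_params()] tibble (probabilities must sum to 1).
#' @param traj a [trajectory_params()].
#' @param seed optional integer seed (set before all draws).
#' @param ga_bw_rho latent GA–BW correlation within group.
#' @param male_prob probability of male sex (default 296/531).
#' @param hydrocephalus_prob,nonphysiologic_prob probabilities of the
#'   exclusion-relevant flags (default 0: the study-style cohort excludes
#'   them upstream; raise to exercise the exclusion machinery).
#' @param id_prefix prefix for generated infant ids.
#' @return an [rop_cohort].
#' @export
sample_cohort <- function(n, groups = group_params(), traj = trajectory_params(),
                          seed = NULL, ga_bw_rho = 0.5,
                          male_prob = 296 / 531,
                          hydrocephalus_prob = 0, nonphysiologic_prob = 0,
                          id_prefix = "SIM") {
  stopifnot(n >= 1)
  if (abs(sum(groups$prob) - 1) > 1e-8 || any(groups$bw_sd_g <= 0) ||
      any(groups$ga_sd_days <= 0)) {
    stop("invalid group parameters: probabilities must sum to 1 and SDs be positive",
         call. = FALSE)
  }
  if (any(groups$bw_mean_g < groups$bw_min_g | groups$bw_mean_g > groups$bw_max_g) ||
      any(groups$ga_mean_days < groups$ga_min_days | groups$ga_mean_days > groups$ga_max_days)) {
    stop("invalid group parameters: truncation range must contain the mean",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  grp_idx <- sample.int(nrow(groups), n, replace = TRUE, prob = groups$prob)
  ga <- integer(n); bw <- numeric(n)
  for (k in seq_len(nrow(groups))) {
    sel <- grp_idx == k
    if (!any(sel)) next
    draw <- sample_ga_bw(sum(sel), groups[k, ], ga_bw_rho)
    ga[sel] <- draw$ga_days
    bw[sel] <- draw$bw_g
  }
  outcome <- groups$outcome[grp_idx]
  treated <- stats::runif(n) < groups$treated_prob[grp_idx]
  # treatment timing: type 1 around PMA 37 weeks; late-treated type 2
  # around PMA 45-55 weeks
  pma_tx <- rep(NA_integer_, n)
  t1 <- treated & outcome == "type1"
  pma_tx[t1] <- as.integer(round(stats::rnorm(sum(t1), 259, 10)))
  t2 <- treated & outcome == "type2"
  pma_tx[t2] <- as.integer(round(stats::runif(sum(t2), 315, 385)))
  sex <- ifelse(stats::runif(n) < male_prob, "male", "female")
  hydro <- stats::runif(n) < hydrocephalus_prob
  nonphys <- stats::runif(n) < nonphysiologic_prob
  rate <- stats::rnorm(n, groups$gain_mean_g_per_day[grp_idx],
                       groups$gain_sd[grp_idx])
  # follow-up to about PMA 40 weeks (at least through the day-39 window)
  n_days <- pmax(45L, as.integer(round(stats::rnorm(n, 280, 7))) - ga)
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  series <- vector("list", n)
  for (i in seq_len(n)) {
    s <- simulate_weights(bw[i], rate[i], traj, n_days[i])
    s$weight_g[s$day == 0L] <- bw[i]
    series[[i]] <- s
  }
  lens <- vapply(series, nrow, integer(1))
  weights <- tibble::tibble(
    infant_id = rep(ids, lens),
    day = unlist(lapply(series, `[[`, "day"), use.names = FALSE),
    weight_g = unlist(lapply(series, `[[`, "weight_g"), use.names = FALSE)
  )
  infants <- tibble::tibble(
    infant_id = ids, ga_days = ga, bw_g = bw, sex = sex,
    hydrocephalus = hydro, nonphysiologic_weight = nonphys,
    outcome = outcome, treated = treated, pma_treatment_days = pma_tx,
    unstable_course = FALSE
  )
  suppressWarnings(rop_cohort(infants, weights))
}

#' Generate a synthetic cohort and write the interchange files
#'
#' @param n number of infants.
#' @param groups,traj generator parameters.
#' @param seed integer seed; identical seeds give byte-identical files.
#' @param dir output directory (created if missing).
#' @param ... passed to [sample_cohort()].
#' @return named character vector of the `cohort` and `weights` paths.
#' @export
generate_cohort <- function(n, groups = group_params(),
                            traj = trajectory_params(), seed = 1L,
                            dir = tempdir(), ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ch <- sample_cohort(n, groups, traj, seed = seed, ...)
  write_cohort(ch, file.path(dir, "cohort.csv"), file.path(dir, "weights.csv"))
  c(cohort = file.path(dir, "cohort.csv"),
    weights = file.path(dir, "weights.csv"))
}
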