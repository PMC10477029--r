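#' Read a pipeline run configuration
#'
#' YAML (or JSON) configuration shared by the three pipeline stages.
#' Recognized keys:
#' \itemize{
#'   \item `simulate`: list with `n`, `seed` and optional generator
#'     overrides (`trajectory`, `male_prob`, `hydrocephalus_prob`,
#'     `nonphysiologic_prob`, `ga_bw_rho`).
#'   \item `inputs`: list with `cohort` and `weights` paths (alternative
#'     to `simulate`).
#'   \item `algorithms`: subset of grop/corop/choprop/winrop (default all
#'     that are runnable).
#'   \item `choprop_model`: path to the coefficient YAML.
#'   \item `winrop_labels`: path to the external label CSV (optional).
#'   \item `eligibility`: list with `ga_max_days`, `bw_max_g`.
#'   \item `tolerance_days`, `birth_day_index`, `confidence_level`,
#'     `out_dir`, `seed`.
#' }
#'
#' @param path configuration file path.
#' @return list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("cannot parse config ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  # YAML 1.1 parses a bare key `n` as the boolean FALSE; map it back so the
  # documented `simulate: {n: ...}` key round-trips
  fix_n_key <- function(x) {
    if (!is.list(x)) return(x)
    names(x)[names(x) %in% c("FALSE", "n")] <- "n"
    lapply(x, fix_n_key)
  }
  cfg <- fix_n_key(cfg)
  defaults <- list(
    algorithms = c("grop", "corop", "choprop", "winrop"),
    tolerance_days = 2L, birth_day_index = 0L,
    confidence_level = 0.95, out_dir = ".", seed = NULL,
    choprop_model = NULL, winrop_labels = NULL,
    eligibility = list(ga_max_days = 217L, bw_max_g = 1250)
  )
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  cfg$algorithms <- unlist(cfg$algorithms)
  bad <- setdiff(cfg$algorithms, c("grop", "corop", "choprop", "winrop"))
  if (length(bad)) {
    stop("unknown algorithm(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!length(cfg$algorithms)) {
    stop("config must select at least one algorithm", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

trajectory_from_config <- function(x) {
  if (is.null(x)) return(trajectory_params())
  do.call(trajectory_params, x)
}

ensure_out_dir <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
    message("created output directory ", cfg$out_dir)
  }
  cfg$out_dir
}

#' Pipeline stage: simulate
#'
#' Generates a synthetic cohort per the `simulate` block of the config and
#' writes `cohort.csv` / `weights.csv` into the output directory, logging
#' the seed and a digest of the generator parameters.
#'
#' @param config a [read_run_config()] result (or path to one).
#' @return named paths of the written files.
#' @export
run_simulate <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  sim <- cfg$simulate
  if (is.null(sim)) stop("config has no 'simulate' block", call. = FALSE)
  n <- if (is.null(sim$n)) 531L else as.integer(sim$n)
  seed <- if (!is.null(sim$seed)) as.integer(sim$seed) else
    if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  out <- ensure_out_dir(cfg)
  traj <- trajectory_from_config(sim$trajectory)
  extra <- sim[intersect(names(sim),
                         c("ga_bw_rho", "male_prob", "hydrocephalus_prob",
                           "nonphysiologic_prob", "id_prefix"))]
  paths <- do.call(generate_cohort,
                   c(list(n = n, traj = traj, seed = seed, dir = out), extra))
  message("simulated cohort: n=", n, ", seed=", seed,
          ", params_digest=", rlang_free_digest(c(n, seed, unlist(traj))))
  paths
}

# tiny stable parameter digest (sum-based; for log lines only)
rlang_free_digest <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v <- v[is.finite(v)]
  sprintf("%08x", as.integer(sum(v * seq_along(v)) %% 2^31))
}

locate_inputs <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    c(cohort = cfg$inputs$cohort, weights = cfg$inputs$weights)
  } else {
    c(cohort = file.path(cfg$out_dir, "cohort.csv"),
      weights = file.path(cfg$out_dir, "weights.csv"))
  }
}

#' Pipeline stage: screen
#'
#' Reads the cohort, runs the configured algorithms, writes `alarms.csv`
#' (one row per infant x algorithm), and logs the exclusion summary so
#' attrition is auditable.
#'
#' @inheritParams run_simulate
#' @return path of the written alarms file.
#' @export
run_screen <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  paths <- locate_inputs(cfg)
  cohort <- read_cohort(paths[["cohort"]], paths[["weights"]])
  cm <- if ("choprop" %in% cfg$algorithms) {
    if (is.null(cfg$choprop_model)) {
      stop("CHOPROP selected but config lacks 'choprop_model'", call. = FALSE)
    }
    read_choprop_model(cfg$choprop_model)
  } else NULL
  wl <- if (!is.null(cfg$winrop_labels)) read_winrop_labels(cfg$winrop_labels) else NULL
  alarms <- screen_cohort(
    cohort, algorithms = cfg$algorithms, choprop_model = cm,
    winrop_labels = wl,
    grop = grop_criteria(tolerance_days = cfg$tolerance_days),
    corop = corop_criteria(tolerance_days = cfg$tolerance_days),
    birth_day_index = cfg$birth_day_index,
    tolerance_days = cfg$tolerance_days)
  excl <- alarms[alarms$algorithm == cfg$algorithms[1L], ]
  flags <- unlist(strsplit(excl$exclusion_flags[excl$excluded], ","))
  message("screened ", nrow(cohort$infants), " infants; excluded ",
          sum(excl$excluded),
          if (length(flags)) paste0(" (",
            paste(names(table(flags)), table(flags), sep = "=", collapse = ", "),
            ")") else "")
  out <- ensure_out_dir(cfg)
  alarms_path <- file.path(out, "alarms.csv")
  readr::write_csv(alarms, alarms_path, progress = FALSE)
  invisible(alarms_path)
}

#' Pipeline stage: evaluate
#'
#' Joins alarms back to the cohort, computes the full diagnostic report
#' and writes `report.csv`, `report.json` and a human-readable
#' `report.txt` in the `point (lower-upper)` table style.
#'
#' @inheritParams run_simulate
#' @return the report tibble, invisibly.
#' @export
run_evaluate <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  alarms_path <- file.path(cfg$out_dir, "alarms.csv")
  if (!file.exists(alarms_path)) {
    stop("no alarms.csv in ", cfg$out_dir, "; run the screen stage first",
         call. = FALSE)
  }
  paths <- locate_inputs(cfg)
  cohort <- read_cohort(paths[["cohort"]], paths[["weights"]])
  alarms <- readr::read_csv(alarms_path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(
                              algorithm = readr::col_character(),
                              infant_id = readr::col_character(),
                              eligible = readr::col_logical(),
                              evaluable = readr::col_logical(),
                              alarm = readr::col_logical(),
                              triggered_criteria = readr::col_character(),
                              alarm_day = readr::col_integer(),
                              excluded = readr::col_logical(),
                              exclusion_flags = readr::col_character()))
  if (nrow(alarms) == 0L) {
    stop("alarms.csv is empty; nothing to evaluate", call. = FALSE)
  }
  report <- evaluate_all(cohort, alarms, level = cfg$confidence_level)
  out <- ensure_out_dir(cfg)
  write_report(report, file.path(out, "report.csv"),
               file.path(out, "report.json"))
  lines <- utils::capture.output(format_report(report))
  writeLines(lines, file.path(out, "report.txt"))
  invisible(report)
}
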