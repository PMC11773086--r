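# End-to-end orchestration: simulate -> preprocess/score -> motion QC ->
# fit -> report, as a pure function of a validated configuration.

run_config_defaults <- function() {
  list(
    master_seed = 1L,
    group_sizes = c(child = 36L, adolescent = 40L, adult = 44L),
    sampling_rate_hz = 1000,
    n_volumes = 200L,
    median_window_s = 0.010,
    band_low_hz = 0.03,
    band_high_hz = 5,
    filter_order = 1,
    target_rate_hz = 100,
    floor_uS = 0.01,
    ceiling_uS = 5,
    fd_threshold_mm = 0.9,
    iti_mean_s = 12,
    iti_sd_s = 1,
    reinforcement_rate = 0.8,
    null_effects = FALSE,
    fit_ratings = TRUE,
    fit_sensitivity = FALSE,
    clmm_nodes = 15,
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Fills study defaults (12 s mean ITI, 80\% reinforcement, FD threshold
#' 0.9 mm, the full preprocessing constants) into a partial configuration
#' read from a YAML/JSON file or given as a list. Unknown keys and
#' physically impossible settings (band edge at or above Nyquist) are
#' rejected.
#'
#' @param config path to a YAML or JSON file, a list, or `NULL` for all
#'   defaults.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(config = NULL) {
  defaults <- run_config_defaults()
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a path, a list, or NULL", call. = FALSE)
  }
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  if (cfg$band_high_hz >= cfg$target_rate_hz / 2) {
    stop("band_high_hz (", cfg$band_high_hz,
         ") must be below the Nyquist frequency of the target rate (",
         cfg$target_rate_hz / 2, " Hz)", call. = FALSE)
  }
  if (cfg$band_high_hz >= cfg$sampling_rate_hz / 2) {
    stop("band_high_hz must be below the native Nyquist frequency",
         call. = FALSE)
  }
  stopifnot(cfg$fd_threshold_mm > 0, all(cfg$group_sizes >= 1),
            cfg$reinforcement_rate >= 0, cfg$reinforcement_rate <= 1)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(substr(tools::md5sum(tf), 1, 12))
}

pipeline_protocol <- function(cfg) {
  proto <- default_protocol()
  for (ph in names(proto)) {
    proto[[ph]]$iti_mean_s <- cfg$iti_mean_s
    proto[[ph]]$iti_sd_s <- cfg$iti_sd_s
  }
  proto$acquisition$n_reinforced <-
    as.integer(round(cfg$reinforcement_rate * proto$acquisition$n_cs_plus))
  proto
}

#' Per-phase mean response profile
#'
#' Mean sqrt-SCR by phase, CS type, trial and age group: the standard
#' learning-curve summary plotted in differential-conditioning studies.
#'
#' @param trials trial table.
#' @return data.frame `phase`, `group`, `trial_type`, `trial_index`,
#'   `mean_scr_sqrt`, `se`, `n`.
#' @export
phase_profile <- function(trials) {
  d <- trials[trials$trial_type %in% c("CS+", "CS-") &
                !is.na(trials$scr_sqrt), , drop = FALSE]
  agg <- stats::aggregate(
    scr_sqrt ~ phase + group + trial_type + trial_index, data = d,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  out <- data.frame(agg[1:4],
                    mean_scr_sqrt = agg$scr_sqrt[, "mean"],
                    se = agg$scr_sqrt[, "sd"] / sqrt(agg$scr_sqrt[, "n"]),
                    n = agg$scr_sqrt[, "n"])
  out[order(out$phase, out$group, out$trial_type, out$trial_index), ]
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort, scores every recording through the preprocessing
#' chain, computes motion censoring summaries, fits the statistical models
#' (phase-wise LMMs, group LMMs under both reference groups, the retention
#' early-trial differential regression, US habituation, and the ratings
#' CLMMs), and assembles a report. Deterministic given the configuration.
#'
#' @param config a [validate_config()] result, or anything it accepts.
#' @return a `run_report` list: `profile`, `fits` (named list of
#'   `fear_fit`s), `retention`, `censoring`, `trials`, `ratings`,
#'   `exclusions`, `provenance`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else {
    validate_config(config)
  }
  gp <- default_group_params()
  gp <- gp[names(cfg$group_sizes)]
  for (g in names(gp)) gp[[g]]$n <- as.integer(cfg$group_sizes[[g]])
  amp <- if (isTRUE(cfg$null_effects)) {
    amplitude_model(acq_diff_slope = 0, ext_diff_start = 0,
                    ext_diff_slope = 0, ret_early_boost = 0, ret_diff = 0,
                    group_offsets = c(child = 0, adolescent = 0, adult = 0))
  } else {
    amplitude_model()
  }
  cohort <- simulate_cohort(
    cfg$master_seed, group_params = gp, amplitude = amp,
    sampling_rate_hz = cfg$sampling_rate_hz,
    protocol = pipeline_protocol(cfg), n_volumes = cfg$n_volumes)

  pre_cfg <- preprocess_config(
    median_window_s = cfg$median_window_s, band_low_hz = cfg$band_low_hz,
    band_high_hz = cfg$band_high_hz, filter_order = cfg$filter_order,
    target_rate_hz = cfg$target_rate_hz, floor_uS = cfg$floor_uS,
    ceiling_uS = cfg$ceiling_uS, score_us = TRUE)
  trials <- score_cohort(cohort, pre_cfg)
  censoring <- censoring_summary(cohort, cfg$fd_threshold_mm)

  fits <- list()
  for (ph in c("acquisition", "extinction", "retention")) {
    fits[[paste0("phase_", ph)]] <- fit_phase_lmm(trials, ph)
    fits[[paste0("group_adol_", ph)]] <-
      fit_group_lmm(trials, ph, reference_group = "adolescent")
    fits[[paste0("group_child_", ph)]] <-
      fit_group_lmm(trials, ph, reference_group = "child")
  }
  fits$us_habituation <- fit_us_habituation(trials)
  scores <- retention_scores(trials)
  fits$retention_group <- retention_group_test(scores)
  if (isTRUE(cfg$fit_ratings)) {
    fits$ratings <- fit_ratings_clmm(cohort$ratings, nodes = cfg$clmm_nodes)
    fits$ratings_group <- fit_ratings_clmm(cohort$ratings, by_group = TRUE,
                                           nodes = cfg$clmm_nodes)
  }
  sens <- if (isTRUE(cfg$fit_sensitivity)) sensitivity_suite(trials) else NULL

  n_missing <- sum(is.na(trials$scr_sqrt))
  exclusions <- data.frame(
    stage = c("trials_scored", "trials_missing", "subjects"),
    n = c(nrow(trials), n_missing, length(cohort$subjects)))

  report <- list(profile = phase_profile(trials),
                 fits = fits,
                 retention = scores,
                 censoring = censoring,
                 trials = trials,
                 ratings = cohort$ratings,
                 sensitivity = sens,
                 exclusions = exclusions,
                 provenance = list(config = unclass(cfg),
                                   config_hash = config_hash(cfg),
                                   master_seed = cfg$master_seed,
                                   package_version =
                                     as.character(utils::packageVersion("fearscr"))))
  class(report) <- "run_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d trials, %d subjects, %d fitted models (hash %s)\n",
              nrow(x$trials), length(unique(x$trials$subject)),
              length(x$fits), x$provenance$config_hash))
  invisible(x)
}

#' Write a run report to disk
#'
#' CSV tables (trial table, phase profile, coefficient tables, retention
#' scores, censoring summary), a Markdown summary, and a provenance JSON.
#' Regeneration from the same report object is idempotent.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(report$profile, file.path(dir, "phase_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(report$retention, file.path(dir, "retention_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$censoring, file.path(dir, "censoring_summary.csv"),
                   row.names = FALSE)
  coefs <- do.call(rbind, lapply(names(report$fits), function(nm) {
    f <- report$fits[[nm]]
    if (is.null(f$coefficients)) return(NULL)
    cbind(model = nm, f$coefficients)
  }))
  utils::write.csv(coefs, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  if (!is.null(report$sensitivity)) {
    utils::write.csv(report$sensitivity$comparison,
                     file.path(dir, "sensitivity_comparison.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  md <- c("# Pipeline run report", "",
          sprintf("- config hash: `%s`; master seed: %d",
                  report$provenance$config_hash,
                  report$provenance$master_seed),
          sprintf("- subjects: %d; scored trials: %d (%d missing)",
                  length(unique(report$trials$subject)), nrow(report$trials),
                  sum(is.na(report$trials$scr_sqrt))),
          sprintf("- mean censored volumes by group: %s",
                  paste(sprintf("%s=%.1f",
                                levels(factor(report$censoring$group)),
                                tapply(report$censoring$n_censored,
                                       report$censoring$group, mean)),
                        collapse = ", ")),
          "", "Coefficient tables in `coefficients.csv`;",
          "no multiple-testing correction applied.", "")
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
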