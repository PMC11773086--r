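# Synthetic cohorts with known, planted effects: event-locked electrodermal
# recordings built from a Bateman sudomotor kernel, zero-inflated log-normal
# response amplitudes with learning/extinction dynamics, ordinal fear ratings
# from a proportional-odds generative model, contingency reports, and
# random-walk head-motion traces.

#' Sudomotor response kernel parameters
#'
#' @param tau_rise_s,tau_decay_s rise and decay time constants (s); must
#'   satisfy `0 < tau_rise_s < tau_decay_s`.
#' @param latency_s onset latency after the stimulus (s).
#' @return a `sudomotor_kernel` list.
#' @export
sudomotor_kernel <- function(tau_rise_s = 0.75, tau_decay_s = 2,
                             latency_s = 1) {
  stopifnot(tau_rise_s > 0, latency_s >= 0)
  if (tau_rise_s >= tau_decay_s) {
    stop("`tau_rise_s` must be strictly less than `tau_decay_s`",
         call. = FALSE)
  }
  structure(list(tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
                 latency_s = latency_s),
            class = "sudomotor_kernel")
}

#' Evaluate a unit-peak Bateman kernel
#'
#' Difference of exponentials `exp(-t/tau_decay) - exp(-t/tau_rise)` shifted
#' by the latency and scaled so its maximum is exactly 1; zero before the
#' latency. The peak occurs at
#' `latency + log(tau_decay/tau_rise) * tau_rise * tau_decay /
#' (tau_decay - tau_rise)`.
#'
#' @param kernel a [sudomotor_kernel()].
#' @param t numeric vector of times (s), `t >= 0`.
#' @return numeric vector of kernel values in `[0, 1]`.
#' @export
bateman_kernel <- function(kernel, t) {
  stopifnot(inherits(kernel, "sudomotor_kernel"), all(t >= 0))
  tr <- kernel$tau_rise_s
  td <- kernel$tau_decay_s
  s <- t - kernel$latency_s
  out <- numeric(length(t))
  pos <- s > 0
  # closed-form peak height of the unnormalized difference of exponentials
  t_star <- log(td / tr) * tr * td / (td - tr)
  peak <- exp(-t_star / td) - exp(-t_star / tr)
  out[pos] <- (exp(-s[pos] / td) - exp(-s[pos] / tr)) / peak
  out
}

#' Closed-form peak time of a Bateman kernel
#'
#' @param kernel a [sudomotor_kernel()].
#' @return time (s) at which the kernel attains its maximum.
#' @export
bateman_peak_time <- function(kernel) {
  tr <- kernel$tau_rise_s
  td <- kernel$tau_decay_s
  kernel$latency_s + log(td / tr) * tr * td / (td - tr)
}

#' Generative amplitude model for phasic responses
#'
#' Log-scale generative model for trial amplitudes (microsiemens). For a CS
#' event in a given phase the log-mean is
#' `intercept + trial_slope * (trial_index - 1) [+ differential terms for
#' CS+] + group_offset + subject intercept`, realised as a zero-inflated
#' log-normal draw. Defaults plant the canonical differential-conditioning
#' pattern: CS+ responding grows relative to CS- across acquisition
#' (`acq_diff_slope` per trial), the differential decays across extinction,
#' early retention trials show a partial return of the differential, and
#' responses habituate within every phase. Children respond more strongly
#' overall; no group difference is planted in retention.
#'
#' @param base_log_uS log of the modal response amplitude (log-µS).
#' @param habituation_slope within-phase log-amplitude change per trial
#'   (negative = habituation), applied to all CS events.
#' @param acq_diff_slope additional per-trial log-amplitude growth for CS+
#'   during acquisition (the planted CS x trial interaction).
#' @param ext_diff_start CS+ minus CS- log-amplitude at the start of
#'   extinction.
#' @param ext_diff_slope per-trial decay of that differential during
#'   extinction (negative).
#' @param ret_early_boost extra CS+ log-amplitude on the first two retention
#'   trials (return of fear).
#' @param ret_diff residual CS+ minus CS- log-amplitude throughout retention.
#' @param us_log_uS log-amplitude of responses to the US itself.
#' @param us_slope per-trial log change of US responses (habituation).
#' @param group_offsets named log-amplitude offsets for
#'   `child`/`adolescent`/`adult`.
#' @param subject_sd SD of the subject random intercept (log scale).
#' @param noise_sd log-normal trial noise SD.
#' @param p_nonresponse probability a trial yields no measurable response.
#' @return an `amplitude_model` list.
#' @export
amplitude_model <- function(base_log_uS = log(0.4),
                            habituation_slope = -0.06,
                            acq_diff_slope = 0.10,
                            ext_diff_start = 0.8,
                            ext_diff_slope = -0.08,
                            ret_early_boost = 0.5,
                            ret_diff = 0.1,
                            us_log_uS = log(1.2),
                            us_slope = -0.08,
                            group_offsets = c(child = 0.25, adolescent = 0,
                                              adult = -0.10),
                            subject_sd = 0.4,
                            noise_sd = 0.4,
                            p_nonresponse = 0.15) {
  stopifnot(p_nonresponse >= 0, p_nonresponse <= 1,
            subject_sd >= 0, noise_sd >= 0,
            all(c("child", "adolescent", "adult") %in% names(group_offsets)))
  structure(as.list(environment()), class = "amplitude_model")
}

#' Expected log-amplitude for one event
#'
#' The deterministic part of the generative model (no subject intercept, no
#' noise): the value `draw_amplitude()` exponentiates.
#'
#' @param model an [amplitude_model()].
#' @param phase phase name.
#' @param trial_type `"CS+"`, `"CS-"` or `"US"`.
#' @param trial_index 1-based trial index within type.
#' @param age_group `"child"`, `"adolescent"` or `"adult"`.
#' @return scalar log-µS mean.
#' @export
amplitude_log_mean <- function(model, phase, trial_type, trial_index,
                               age_group) {
  k <- trial_index - 1
  g <- unname(model$group_offsets[[age_group]])
  if (trial_type == "US") {
    return(model$us_log_uS + model$us_slope * k + g)
  }
  mu <- model$base_log_uS + model$habituation_slope * k + g
  plus <- trial_type == "CS+"
  mu + switch(phase,
    habituation = 0,
    acquisition = if (plus) model$acq_diff_slope * k else 0,
    extinction = if (plus) {
      max(0, model$ext_diff_start + model$ext_diff_slope * k)
    } else 0,
    retention = if (plus) {
      model$ret_diff + if (trial_index <= 2) model$ret_early_boost else 0
    } else 0
  )
}

#' Subject specification for simulation
#'
#' @param subject_id character id.
#' @param age_group `"child"`, `"adolescent"` or `"adult"`.
#' @param intercept subject random intercept on the log-amplitude scale;
#'   drawn by [simulate_cohort()] as `N(0, subject_sd^2)`.
#' @param tonic_uS tonic skin-conductance level (µS), > 0.
#' @param drift_uS_per_s slow linear drift of the tonic level.
#' @param noise_sd_uS white measurement-noise SD on the recording (µS).
#' @param motion_level non-negative multiplier for head-motion step SDs
#'   (0 = perfectly still).
#' @param ses,us_sound_level,days_between_sessions subject covariates.
#' @param aware logical contingency awareness used to generate the
#'   post-experiment report.
#' @return a `subject_spec` list.
#' @export
subject_spec <- function(subject_id, age_group, intercept = 0,
                         tonic_uS = 5, drift_uS_per_s = 0,
                         noise_sd_uS = 0.02, motion_level = 0.5,
                         ses = NA_real_, us_sound_level = NA_real_,
                         days_between_sessions = NA_real_, aware = TRUE) {
  age_group <- match.arg(age_group, c("child", "adolescent", "adult"))
  stopifnot(tonic_uS > 0, motion_level >= 0)
  structure(as.list(environment()), class = "subject_spec")
}

#' Draw one trial amplitude
#'
#' Zero-inflated log-normal: with probability `p_nonresponse` returns 0,
#' otherwise `exp(mu + subject intercept + noise)` where `mu` is
#' [amplitude_log_mean()].
#'
#' @inheritParams amplitude_log_mean
#' @param subject a [subject_spec()].
#' @return amplitude in µS (>= 0).
#' @export
draw_amplitude <- function(model, subject, phase, trial_type, trial_index) {
  if (model$p_nonresponse > 0 && runif(1) < model$p_nonresponse) return(0)
  mu <- amplitude_log_mean(model, phase, trial_type, trial_index,
                           subject$age_group)
  exp(mu + subject$intercept + rnorm(1, 0, model$noise_sd))
}

#' Simulate a continuous skin-conductance recording for one phase
#'
#' Signal = tonic level + linear drift + sum over events of
#' amplitude x Bateman kernel(t - onset) + white noise, sampled uniformly.
#' The recording extends 15 s past the last event offset so late response
#' tails are captured.
#'
#' @param schedule a `task_schedule` from [make_schedule()].
#' @param subject a [subject_spec()].
#' @param model an [amplitude_model()].
#' @param kernel a [sudomotor_kernel()].
#' @param sampling_rate_hz sampling rate (Hz), >= 20.
#' @param seed optional integer seed.
#' @param score_us if `TRUE`, US events also elicit responses (they do by
#'   default; set amplitudes via the model).
#' @param pre_roll_s recording lead-in before the first event (s), as in a
#'   real session where acquisition starts before the task; keeps filter
#'   edge transients away from the scored windows.
#' @return a `physio_recording`: list with `samples` (µS), `sampling_rate_hz`,
#'   `start_time_s` (= `-pre_roll_s`), `subject_id`, `phase_name`, and the
#'   per-event planted amplitudes in `amplitudes`.
#' @export
simulate_recording <- function(schedule, subject, model = amplitude_model(),
                               kernel = sudomotor_kernel(),
                               sampling_rate_hz = 1000, seed = NULL,
                               score_us = TRUE, pre_roll_s = 10) {
  stopifnot(inherits(schedule, "task_schedule"),
            inherits(subject, "subject_spec"),
            sampling_rate_hz >= 20)
  ev <- schedule$events
  if (nrow(ev) == 0L) stop("schedule has no events", call. = FALSE)

  build <- function() {
    dur_s <- pre_roll_s + max(ev$onset + ev$duration) + 15
    n <- ceiling(dur_s * sampling_rate_hz)
    tt <- (seq_len(n) - 1) / sampling_rate_hz - pre_roll_s
    sig <- subject$tonic_uS + subject$drift_uS_per_s * tt

    # kernel support truncated at 20 s (amplitude < 1e-4 of peak by then)
    kt <- seq(0, 20, by = 1 / sampling_rate_hz)
    kv <- bateman_kernel(kernel, kt)

    amps <- numeric(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      if (ev$trial_type[i] == "US" && !score_us) next
      a <- draw_amplitude(model, subject, schedule$config$phase_name,
                          ev$trial_type[i], ev$trial_index[i])
      amps[i] <- a
      if (a == 0) next
      i0 <- floor((ev$onset[i] + pre_roll_s) * sampling_rate_hz) + 1L
      idx <- i0:min(n, i0 + length(kv) - 1L)
      sig[idx] <- sig[idx] + a * kv[seq_along(idx)]
    }
    if (subject$noise_sd_uS > 0) {
      sig <- sig + rnorm(n, 0, subject$noise_sd_uS)
    }
    list(sig = sig, amps = amps)
  }
  res <- if (is.null(seed)) build() else with_seed(seed, build())

  structure(list(samples = res$sig,
                 sampling_rate_hz = sampling_rate_hz,
                 start_time_s = -pre_roll_s,
                 subject_id = subject$subject_id,
                 phase_name = schedule$config$phase_name,
                 amplitudes = res$amps),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> %s/%s  %d samples @ %g Hz (%.1f s)\n",
              x$subject_id %||% "?", x$phase_name %||% "?",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Generative parameters for ordinal fear ratings
#'
#' Proportional-odds (cumulative-logit) generative model for 1-5 fear
#' ratings collected per CS before habituation, after acquisition and after
#' extinction. The latent predictor is
#' `beta_cs * [CS+] + beta_cs_acq * [CS+ & post-acquisition] +
#' beta_cs_ext * [CS+ & post-extinction] + group terms + subject intercept`,
#' and `P(rating <= k) = plogis(threshold_k - predictor)`.
#'
#' @param thresholds 4 strictly increasing cut points on the latent scale.
#' @param beta_cs baseline CS+ effect (pre-habituation).
#' @param beta_cs_acq,beta_cs_ext additional CS+ effect after acquisition /
#'   extinction (the planted CS x phase interactions).
#' @param group_offsets named latent-scale offsets per age group.
#' @param subject_sd SD of the subject random intercept.
#' @return a `rating_model` list.
#' @export
rating_model <- function(thresholds = c(0.5, 2.0, 3.5, 5.0),
                         beta_cs = 0.3, beta_cs_acq = 2.5, beta_cs_ext = 1.0,
                         group_offsets = c(child = 0, adolescent = 0,
                                           adult = 0),
                         subject_sd = 1.2) {
  if (any(diff(thresholds) <= 0) || length(thresholds) != 4L) {
    stop("`thresholds` must be 4 strictly increasing values", call. = FALSE)
  }
  stopifnot(subject_sd >= 0)
  structure(as.list(environment()), class = "rating_model")
}

# Latent predictor for one rating cell (no subject intercept).
rating_eta <- function(model, cs, phase, age_group) {
  eta <- unname(model$group_offsets[[age_group]])
  if (cs == "CS+") {
    eta <- eta + model$beta_cs +
      switch(phase, pre = 0, acquisition = model$beta_cs_acq,
             extinction = model$beta_cs_ext)
  }
  eta
}

#' Simulate ordinal fear ratings for one subject
#'
#' One rating per CS at each of the three rating points (`pre`,
#' `acquisition`, `extinction`), drawn from the cumulative-logit model with
#' the subject's random intercept.
#'
#' @param subject a [subject_spec()].
#' @param model a [rating_model()].
#' @param b_subject subject intercept on the latent scale; drawn by
#'   [simulate_cohort()].
#' @return data.frame with columns `subject`, `group`, `phase`, `cs`,
#'   `rating`.
#' @export
simulate_ratings <- function(subject, model = rating_model(), b_subject = 0) {
  grid <- expand.grid(phase = c("pre", "acquisition", "extinction"),
                      cs = c("CS-", "CS+"), stringsAsFactors = FALSE)
  rating <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    eta <- rating_eta(model, grid$cs[i], grid$phase[i], subject$age_group) +
      b_subject
    pk <- diff(c(0, plogis(model$thresholds - eta), 1))
    rating[i] <- sample.int(5L, 1L, prob = pk)
  }
  data.frame(subject = subject$subject_id, group = subject$age_group,
             phase = grid$phase, cs = grid$cs, rating = rating,
             stringsAsFactors = FALSE)
}

#' Simulate six-column realignment parameters
#'
#' Random-walk translations (mm, columns 1-3) and rotations (radians, columns
#' 4-6) whose step SDs scale with the subject's `motion_level`, plus
#' occasional abrupt movements ("spikes"). A motion level of 0 yields
#' all-zero parameters.
#'
#' @param n_volumes number of functional volumes, >= 2.
#' @param subject a [subject_spec()].
#' @param step_sd_mm,step_sd_rad baseline per-volume step SDs at motion
#'   level 1.
#' @param spike_prob per-volume probability of an abrupt movement at motion
#'   level 1 (scaled by the level).
#' @param spike_mm range of spike magnitudes (mm, uniform).
#' @return numeric matrix, `n_volumes` x 6.
#' @export
simulate_motion <- function(n_volumes, subject,
                            step_sd_mm = 0.05, step_sd_rad = 8e-4,
                            spike_prob = 0.04, spike_mm = c(0.8, 2.5)) {
  stopifnot(n_volumes >= 2, inherits(subject, "subject_spec"))
  lev <- subject$motion_level
  rp <- matrix(0, n_volumes, 6)
  if (lev == 0) return(rp)
  sds <- c(rep(step_sd_mm, 3), rep(step_sd_rad, 3)) * lev
  steps <- matrix(rnorm(6 * (n_volumes - 1), 0, rep(sds, each = n_volumes - 1)),
                  n_volumes - 1, 6)
  spikes <- which(runif(n_volumes - 1) < spike_prob * lev)
  for (v in spikes) {
    ax <- sample.int(3L, 1L)
    steps[v, ax] <- steps[v, ax] +
      sample(c(-1, 1), 1) * runif(1, spike_mm[1], spike_mm[2])
  }
  rp[-1, ] <- apply(steps, 2, cumsum)
  rp
}

#' Default per-group simulation parameters
#'
#' Group sizes, motion levels, awareness probabilities and covariate
#' distributions used by [simulate_cohort()]. Cohort structure follows the
#' study design: 36 children, 40 adolescents, 44 adults; awareness rates
#' 79/85/95\%; children move most in the scanner and adults least; the US
#' sound level is lowest for children (fixed conservative volume) and highest
#' for adults.
#'
#' @return named list of per-group parameter lists.
#' @export
default_group_params <- function() {
  list(
    child = list(n = 36L, motion_level = 1.0, p_aware = 0.79,
                 ses_mean = 7.0, ses_sd = 1.7,
                 sound_mean = 10.9, sound_sd = 3.8,
                 days_mean = 4.1, days_sd = 2.8),
    adolescent = list(n = 40L, motion_level = 0.45, p_aware = 0.85,
                      ses_mean = 7.7, ses_sd = 1.1,
                      sound_mean = 41.7, sound_sd = 10.2,
                      days_mean = 3.8, days_sd = 2.2),
    adult = list(n = 44L, motion_level = 0.15, p_aware = 0.95,
                 ses_mean = 7.1, ses_sd = 1.6,
                 sound_mean = 49.6, sound_sd = 8.0,
                 days_mean = 4.5, days_sd = 4.5)
  )
}

#' Simulate a full cohort specification
#'
#' Draws every subject's random intercepts, tonic level, covariates,
#' contingency report and per-phase schedule seeds, deterministically from
#' the master seed. Recordings themselves are generated lazily (see
#' [simulate_subject_phase()] and [score_cohort()]) so large cohorts never
#' have to be held in memory at once.
#'
#' @param master_seed integer master seed; the whole cohort is a pure
#'   function of it.
#' @param group_params per-group parameters, see [default_group_params()].
#' @param amplitude amplitude model, see [amplitude_model()].
#' @param ratings rating model, see [rating_model()].
#' @param kernel sudomotor kernel.
#' @param sampling_rate_hz native recording rate (Hz).
#' @param protocol named list of phase configs, see [default_protocol()].
#' @param n_volumes functional volumes for the motion traces.
#' @return a `cohort` list with `subjects` (list of per-subject entries:
#'   `spec`, `b_rating`, `schedule_seeds`, `recording_seeds`), `ratings`
#'   (data.frame), `contingency` (data.frame), `params`, and `master_seed`.
#' @export
simulate_cohort <- function(master_seed,
                            group_params = default_group_params(),
                            amplitude = amplitude_model(),
                            ratings = rating_model(),
                            kernel = sudomotor_kernel(),
                            sampling_rate_hz = 1000,
                            protocol = default_protocol(),
                            n_volumes = 200L) {
  subjects <- list()
  rating_rows <- list()
  conting_rows <- list()
  for (grp in names(group_params)) {
    gp <- group_params[[grp]]
    stopifnot(gp$n >= 1)
    for (i in seq_len(gp$n)) {
      prefix <- c(child = "ch", adolescent = "ad", adult = "au")[[grp]] %||%
        grp
      sid <- sprintf("sub-%s%03d", prefix, i)
      if (sid %in% names(subjects)) {
        stop("duplicate subject id: ", sid, call. = FALSE)
      }
      sseed <- derive_seed(master_seed, grp, i)
      entry <- with_seed(sseed, {
        spec <- subject_spec(
          subject_id = sid, age_group = grp,
          intercept = rnorm(1, 0, amplitude$subject_sd),
          tonic_uS = exp(rnorm(1, log(5), 0.25)),
          drift_uS_per_s = rnorm(1, 0, 5e-4),
          noise_sd_uS = 0.02,
          motion_level = gp$motion_level * exp(rnorm(1, 0, 0.3)),
          ses = pmin(9, pmax(0, rnorm(1, gp$ses_mean, gp$ses_sd))),
          us_sound_level = pmin(100, pmax(5, rnorm(1, gp$sound_mean,
                                                   gp$sound_sd))),
          days_between_sessions = max(1, round(rnorm(1, gp$days_mean,
                                                     gp$days_sd))),
          aware = runif(1) < gp$p_aware)
        b_rating <- rnorm(1, 0, ratings$subject_sd)
        list(spec = spec, b_rating = b_rating)
      })
      entry$schedule_seeds <- vapply(
        names(protocol), function(ph) derive_seed(master_seed, sid, ph, "sched"),
        integer(1))
      entry$recording_seeds <- vapply(
        names(protocol), function(ph) derive_seed(master_seed, sid, ph, "rec"),
        integer(1))
      entry$motion_seed <- derive_seed(master_seed, sid, "motion")
      subjects[[sid]] <- entry

      rating_rows[[sid]] <- with_seed(
        derive_seed(master_seed, sid, "ratings"),
        simulate_ratings(entry$spec, ratings, entry$b_rating))
      # aware subjects give the correct (yes, no) report; unaware subjects
      # give one of the three incorrect patterns at random
      conting_rows[[sid]] <- with_seed(
        derive_seed(master_seed, sid, "conting"), {
          if (entry$spec$aware) {
            ans <- c(TRUE, FALSE)
          } else {
            ans <- list(c(TRUE, TRUE), c(FALSE, FALSE),
                        c(FALSE, TRUE))[[sample.int(3L, 1L)]]
          }
          data.frame(subject = sid, group = grp,
                     cs_plus_screamed = ans[1], cs_minus_screamed = ans[2],
                     stringsAsFactors = FALSE)
        })
    }
  }
  structure(list(subjects = subjects,
                 ratings = do.call(rbind, c(rating_rows,
                                            make.row.names = FALSE)),
                 contingency = do.call(rbind, c(conting_rows,
                                                make.row.names = FALSE)),
                 params = list(group_params = group_params,
                               amplitude = amplitude, ratings = ratings,
                               kernel = kernel,
                               sampling_rate_hz = sampling_rate_hz,
                               protocol = protocol, n_volumes = n_volumes),
                 master_seed = as.integer(master_seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  grp <- vapply(x$subjects, function(s) s$spec$age_group, character(1))
  cat(sprintf("<cohort> %d subjects (%s)  master_seed=%d\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(table(grp)), table(grp)),
                    collapse = ", "),
              x$master_seed))
  invisible(x)
}

#' Generate one subject's schedule and recording for one phase
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param subject_id subject id present in the cohort.
#' @param phase phase name present in the cohort's protocol.
#' @return list with `schedule` and `recording`.
#' @export
simulate_subject_phase <- function(cohort, subject_id, phase) {
  entry <- cohort$subjects[[subject_id]]
  if (is.null(entry)) stop("unknown subject: ", subject_id, call. = FALSE)
  cfg <- cohort$params$protocol[[phase]]
  if (is.null(cfg)) stop("unknown phase: ", phase, call. = FALSE)
  schedule <- make_schedule(cfg, entry$schedule_seeds[[phase]])
  recording <- simulate_recording(
    schedule, entry$spec, cohort$params$amplitude, cohort$params$kernel,
    sampling_rate_hz = cohort$params$sampling_rate_hz,
    seed = entry$recording_seeds[[phase]])
  list(schedule = schedule, recording = recording)
}

#' Generate one subject's realignment parameters
#'
#' @inheritParams simulate_subject_phase
#' @return `n_volumes` x 6 matrix.
#' @export
simulate_subject_motion <- function(cohort, subject_id) {
  entry <- cohort$subjects[[subject_id]]
  if (is.null(entry)) stop("unknown subject: ", subject_id, call. = FALSE)
  with_seed(entry$motion_seed,
            simulate_motion(cohort$params$n_volumes, entry$spec))
}

#' Subject metadata table
#'
#' @param cohort a `cohort`.
#' @return data.frame with one row per subject: group, covariates, awareness.
#' @export
cohort_metadata <- function(cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    sp <- s$spec
    data.frame(subject = sp$subject_id, group = sp$age_group,
               ses = sp$ses, us_sound_level = sp$us_sound_level,
               days_between_sessions = sp$days_between_sessions,
               aware = sp$aware, motion_level = sp$motion_level,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a cohort to the on-disk layout
#'
#' Per subject and phase: `<sub>_<phase>_physio.tsv.gz` (one column,
#' microsiemens) with a `*_physio.json` sidecar (`SamplingFrequency`,
#' `StartTime`, `Columns`), and `<sub>_<phase>_events.tsv`; per subject:
#' `rp_<sub>.txt` realignment parameters; cohort-level `ratings.csv`,
#' `contingency.csv`, `metadata.csv` and a `manifest.json` with seeds and
#' generative parameters.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @param subjects optional subset of subject ids to write.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, subjects = names(cohort$subjects)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in subjects) {
    for (ph in names(cohort$params$protocol)) {
      sim <- simulate_subject_phase(cohort, sid, ph)
      stem <- file.path(dir, sprintf("%s_%s", sid, ph))
      write_physio(sim$recording, paste0(stem, "_physio.tsv.gz"))
      write_events(sim$schedule, paste0(stem, "_events.tsv"))
    }
    rp <- simulate_subject_motion(cohort, sid)
    utils::write.table(format(rp, digits = 8, scientific = TRUE),
                       file.path(dir, sprintf("rp_%s.txt", sid)),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$ratings[cohort$ratings$subject %in% subjects, ],
                   file.path(dir, "ratings.csv"), row.names = FALSE)
  utils::write.csv(cohort$contingency[cohort$contingency$subject %in%
                                        subjects, ],
                   file.path(dir, "contingency.csv"), row.names = FALSE)
  md <- cohort_metadata(cohort)
  utils::write.csv(md[md$subject %in% subjects, ],
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  manifest <- list(
    master_seed = cohort$master_seed,
    subjects = lapply(cohort$subjects[subjects], function(s) {
      list(schedule_seeds = as.list(s$schedule_seeds),
           recording_seeds = as.list(s$recording_seeds),
           motion_seed = s$motion_seed)
    }),
    sampling_rate_hz = cohort$params$sampling_rate_hz,
    n_volumes = cohort$params$n_volumes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read a physiological recording (tsv.gz + JSON sidecar)
#'
#' One-column gzipped TSV of conductance samples plus a JSON sidecar holding
#' `SamplingFrequency` (Hz), `StartTime` (s) and `Columns`.
#'
#' @param recording a `physio_recording`.
#' @param path path ending in `_physio.tsv.gz`; the sidecar replaces the
#'   extension with `.json`.
#' @return `path` invisibly / the recording.
#' @export
write_physio <- function(recording, path) {
  stopifnot(inherits(recording, "physio_recording"))
  con <- gzfile(path, "w")
  writeLines(formatC(recording$samples, digits = 6, format = "g"), con)
  close(con)
  sidecar <- sub("\\.tsv\\.gz$", ".json", path)
  jsonlite::write_json(
    list(SamplingFrequency = recording$sampling_rate_hz,
         StartTime = recording$start_time_s,
         Columns = list("skin_conductance")),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_physio
#' @export
read_physio <- function(path) {
  sidecar <- sub("\\.tsv\\.gz$", ".json", path)
  if (!file.exists(path)) stop("physio file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) {
    stop("physio sidecar not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar)
  samples <- as.numeric(readLines(gzfile(path)))
  if (any(!is.finite(samples))) {
    stop("non-finite samples in ", path, call. = FALSE)
  }
  structure(list(samples = samples,
                 sampling_rate_hz = meta$SamplingFrequency,
                 start_time_s = meta$StartTime %||% 0,
                 subject_id = NA_character_, phase_name = NA_character_,
                 amplitudes = NULL),
            class = "physio_recording")
}
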