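# Electrodermal preprocessing chain: median filter -> first-order Butterworth
# band-pass (zero-phase) -> downsample to 100 Hz -> baseline-corrected peak
# extraction 1-5 s post onset -> amplitude floor/ceiling rules -> square-root
# transform.

#' Preprocessing configuration
#'
#' Defaults follow the study pipeline: 10 ms median filter, first-order
#' Butterworth band-pass 0.03-5 Hz applied forward-backward (zero phase),
#' downsampling to 100 Hz, baseline window 0-1 s and peak window 1-5 s post
#' stimulus onset, responses below 0.01 microsiemens set to 0 and responses
#' above 5 microsiemens set missing, then square-root transformed.
#'
#' @param median_window_s median-filter window length (s).
#' @param band_low_hz,band_high_hz band-pass edges (Hz).
#' @param filter_order Butterworth order.
#' @param zero_phase apply the band-pass forward-backward (`TRUE`, default)
#'   or single-pass.
#' @param target_rate_hz output sampling rate (Hz).
#' @param baseline_window_s two-element window for the baseline mean,
#'   seconds post onset.
#' @param peak_window_s two-element window for the peak search, seconds post
#'   onset.
#' @param floor_uS amplitudes below this are set to 0 (µS).
#' @param ceiling_uS amplitudes above this are set missing (µS).
#' @param score_us also score US-locked responses in [score_phase()].
#' @param exclude_flagged drop recordings with QC flags in [score_phase()].
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(median_window_s = 0.010,
                              band_low_hz = 0.03, band_high_hz = 5,
                              filter_order = 1, zero_phase = TRUE,
                              target_rate_hz = 100,
                              baseline_window_s = c(0, 1),
                              peak_window_s = c(1, 5),
                              floor_uS = 0.01, ceiling_uS = 5,
                              score_us = FALSE,
                              exclude_flagged = FALSE) {
  stopifnot(band_low_hz > 0, band_low_hz < band_high_hz,
            filter_order >= 1, target_rate_hz > 0,
            length(baseline_window_s) == 2L, length(peak_window_s) == 2L,
            baseline_window_s[1] < baseline_window_s[2],
            peak_window_s[1] < peak_window_s[2],
            baseline_window_s[2] <= peak_window_s[2],
            floor_uS < ceiling_uS)
  structure(as.list(environment()), class = "preprocess_config")
}

as_recording <- function(samples, rate, start_time = 0, template = NULL) {
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = rate,
                 start_time_s = start_time,
                 subject_id = template$subject_id %||% NA_character_,
                 phase_name = template$phase_name %||% NA_character_,
                 amplitudes = template$amplitudes),
            class = "physio_recording")
}

#' Sliding-median filter
#'
#' Centered sliding median with window length `round(window_s * rate)`
#' samples, forced odd (+1 if even); edges handled by reflecting the signal.
#'
#' @param recording a `physio_recording`.
#' @param window_s window length in seconds.
#' @return filtered `physio_recording` at the same rate.
#' @export
median_filter <- function(recording, window_s = 0.010) {
  x <- recording$samples
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  k <- round(window_s * recording$sampling_rate_hz)
  if (k < 1) stop("median window spans less than one sample", call. = FALSE)
  if (k %% 2 == 0) k <- k + 1
  if (k == 1 || length(x) == 1L) return(recording)
  h <- (k - 1) / 2
  # reflect h samples at each edge (excluding the edge sample itself when
  # possible, mirroring x[2], x[3], ...)
  n <- length(x)
  left <- x[pmin(n, pmax(1, (h + 1):2))]
  right <- x[pmin(n, pmax(1, (n - 1):(n - h)))]
  padded <- c(left, x, right)
  med <- stats::runmed(padded, k, endrule = "keep")
  as_recording(med[(h + 1):(h + n)], recording$sampling_rate_hz,
               recording$start_time_s, recording)
}

#' Analytic Butterworth band-pass magnitude response
#'
#' Magnitude of the order-n analog Butterworth band-pass prototype at
#' frequency `f_hz`, i.e. `1 / sqrt(1 + W(f)^(2n))` with
#' `W = (f^2 - f_lo f_hi) / (f (f_hi - f_lo))`. For a zero-phase
#' (forward-backward) application the effective gain is this magnitude
#' squared.
#'
#' @param f_hz frequency (Hz).
#' @param low_hz,high_hz band edges (Hz).
#' @param order filter order.
#' @param zero_phase square the magnitude (forward-backward application).
#' @return gain at `f_hz`.
#' @export
butter_bandpass_gain <- function(f_hz, low_hz, high_hz, order = 1,
                                 zero_phase = TRUE) {
  w <- (f_hz^2 - low_hz * high_hz) / (f_hz * (high_hz - low_hz))
  g <- 1 / sqrt(1 + w^(2 * order))
  if (zero_phase) g^2 else g
}

#' Butterworth band-pass filter
#'
#' First-order (by default) Butterworth band-pass, applied forward-backward
#' for zero phase shift so event-relative response latencies are preserved.
#' Removes the tonic (DC) level.
#'
#' @param recording a `physio_recording`.
#' @param low_hz,high_hz band edges (Hz); `high_hz` must be below Nyquist.
#' @param order filter order.
#' @param zero_phase forward-backward application (default `TRUE`).
#' @return filtered `physio_recording`.
#' @export
bandpass <- function(recording, low_hz = 0.03, high_hz = 5, order = 1,
                     zero_phase = TRUE) {
  fs <- recording$sampling_rate_hz
  if (low_hz <= 0 || high_hz >= fs / 2) {
    stop("band edges must lie strictly inside (0, Nyquist = ", fs / 2, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  x <- recording$samples
  # pad long enough for the low-edge transient (3 time constants), with odd
  # reflection so the signal continues smoothly through the edges
  pad <- min(length(x) - 1L, ceiling(3 * fs / low_hz))
  y <- if (zero_phase) {
    xp <- c(2 * x[1] - x[(pad + 1L):2L], x,
            2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)])
    yp <- iir_filter(bf$b, bf$a, xp)
    yp <- rev(iir_filter(bf$b, bf$a, rev(yp)))
    yp[(pad + 1L):(pad + length(x))]
  } else {
    iir_filter(bf$b, bf$a, x)
  }
  as_recording(y, fs, recording$start_time_s, recording)
}

# direct-form II transposed IIR with zero initial conditions (compiled)
iir_filter <- function(b, a, x) {
  iir_filter_cpp(b, a, x)
}

#' Downsample a recording
#'
#' Decimation by sample selection when the rate ratio is an integer,
#' otherwise linear interpolation onto the target grid. Assumes the signal
#' is already band-limited below the target Nyquist (the 5 Hz band-pass edge
#' guarantees this in the standard chain).
#'
#' @param recording a `physio_recording`.
#' @param target_rate_hz output rate (Hz), at most the current rate.
#' @return `physio_recording` at `target_rate_hz`.
#' @export
downsample <- function(recording, target_rate_hz = 100) {
  fs <- recording$sampling_rate_hz
  if (target_rate_hz > fs) {
    stop("upsampling requested (", fs, " -> ", target_rate_hz,
         " Hz); downsample only", call. = FALSE)
  }
  if (target_rate_hz == fs) return(recording)
  ratio <- fs / target_rate_hz
  x <- recording$samples
  if (abs(ratio - round(ratio)) < 1e-9) {
    y <- x[seq(1L, length(x), by = round(ratio))]
  } else {
    t_old <- (seq_along(x) - 1) / fs
    t_new <- seq(0, t_old[length(t_old)], by = 1 / target_rate_hz)
    y <- stats::approx(t_old, x, xout = t_new)$y
  }
  as_recording(y, target_rate_hz, recording$start_time_s, recording)
}

#' Baseline-corrected peak extraction for one event
#'
#' Returns `max(signal on [onset+1, onset+5)) - mean(signal on
#' [onset, onset+1))` (window bounds from the config), with windows converted
#' to sample indices as closed-open intervals and the onset mapped to the
#' nearest sample at-or-after the onset time. May be negative; the amplitude
#' rules are applied separately.
#'
#' @param recording a `physio_recording` (typically already filtered and
#'   downsampled).
#' @param onset_s event onset in the recording's time coordinates.
#' @param config a [preprocess_config()].
#' @return list with `raw_peak_uS` (or `NA`) and `missing_reason`
#'   (`"none"` or `"window_out_of_range"`).
#' @export
extract_peak <- function(recording, onset_s, config = preprocess_config()) {
  fs <- recording$sampling_rate_hz
  x <- recording$samples
  rel <- onset_s - recording$start_time_s
  i0 <- ceiling(rel * fs - 1e-9) + 1L  # 1-based, at-or-after onset
  b_idx <- (i0 + floor(config$baseline_window_s[1] * fs)):
    (i0 + ceiling(config$baseline_window_s[2] * fs) - 1L)
  p_idx <- (i0 + floor(config$peak_window_s[1] * fs)):
    (i0 + ceiling(config$peak_window_s[2] * fs) - 1L)
  if (min(b_idx) < 1L || max(p_idx) > length(x)) {
    return(list(raw_peak_uS = NA_real_,
                missing_reason = "window_out_of_range"))
  }
  list(raw_peak_uS = max(x[p_idx]) - mean(x[b_idx]), missing_reason = "none")
}

#' Amplitude floor/ceiling rules
#'
#' Values below `floor_uS` (including negative baseline-corrected peaks) are
#' set to 0; values above `ceiling_uS` are set missing as physiologically
#' implausible. Missing input propagates.
#'
#' @param raw_peak_uS numeric vector of raw peak amplitudes (µS).
#' @param config a [preprocess_config()].
#' @return list with `scr_uS` and `missing_reason` vectors.
#' @export
apply_amplitude_rules <- function(raw_peak_uS, config = preprocess_config()) {
  scr <- raw_peak_uS
  reason <- rep("none", length(scr))
  reason[is.na(scr)] <- "window_out_of_range"
  ceil <- !is.na(scr) & scr > config$ceiling_uS
  scr[ceil] <- NA_real_
  reason[ceil] <- "ceiling"
  low <- !is.na(scr) & scr < config$floor_uS
  scr[low] <- 0
  list(scr_uS = scr, missing_reason = reason)
}

#' Square-root transform
#'
#' @param scr_uS non-negative amplitudes (µS); missing propagates.
#' @return `sqrt(scr_uS)`.
#' @export
sqrt_transform <- function(scr_uS) {
  if (any(scr_uS < 0, na.rm = TRUE)) {
    stop("negative amplitude after rules: contract violation", call. = FALSE)
  }
  sqrt(scr_uS)
}

#' Automated recording quality flags
#'
#' Replaces manual visual inspection with reproducible checks: a flat-lined
#' signal (near-zero variance), railing (many samples pinned at the signal
#' extremes), and gaps (non-finite samples).
#'
#' @param recording a `physio_recording` (raw, before filtering).
#' @return character vector of flags, empty when the recording is clean.
#' @export
qc_flags <- function(recording) {
  x <- recording$samples
  flags <- character(0)
  if (any(!is.finite(x))) flags <- c(flags, "gap")
  xf <- x[is.finite(x)]
  flat <- length(xf) == 0L || stats::sd(xf) < 1e-6
  if (flat) flags <- c(flags, "flat_line")
  if (!flat) {
    at_rail <- mean(xf == max(xf)) + mean(xf == min(xf))
    if (at_rail > 0.05) flags <- c(flags, "railing")
  }
  flags
}

#' Preprocess a recording (filter chain only)
#'
#' Median filter, band-pass, downsample, in the fixed study order.
#'
#' @param recording raw `physio_recording`.
#' @param config a [preprocess_config()].
#' @return preprocessed `physio_recording` at `target_rate_hz`.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  rec <- median_filter(recording, config$median_window_s)
  rec <- bandpass(rec, config$band_low_hz, config$band_high_hz,
                  config$filter_order, config$zero_phase)
  downsample(rec, config$target_rate_hz)
}

#' Score every trial of one phase
#'
#' Runs the full chain (median filter, band-pass, downsample, per-event
#' baseline-corrected peak, amplitude rules, square-root transform) over all
#' CS events of a schedule, and over US events when `config$score_us` is
#' set. Events whose windows fall outside the recording are returned as
#' missing rather than aborting the phase.
#'
#' @param recording raw `physio_recording` for the phase.
#' @param schedule matching `task_schedule` (or events data.frame).
#' @param config a [preprocess_config()].
#' @return data.frame with one row per scored event: `subject`, `phase`,
#'   `trial_type`, `trial_index`, `raw_peak_uS`, `scr_uS`, `scr_sqrt`,
#'   `missing_reason`, plus a `qc` attribute with the recording's QC flags.
#' @export
score_phase <- function(recording, schedule, config = preprocess_config()) {
  ev <- if (inherits(schedule, "task_schedule")) schedule$events else schedule
  phase <- if (inherits(schedule, "task_schedule")) {
    schedule$config$phase_name
  } else {
    recording$phase_name
  }
  flags <- qc_flags(recording)
  if (length(flags) && isTRUE(config$exclude_flagged)) {
    ev <- ev[0, ]
  }
  keep <- ev$trial_type %in% c("CS+", "CS-") |
    (config$score_us & ev$trial_type == "US")
  ev <- ev[keep, , drop = FALSE]

  proc <- preprocess_recording(recording, config)
  raw <- rep(NA_real_, nrow(ev))
  reason <- rep("window_out_of_range", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    pk <- extract_peak(proc, ev$onset[i], config)
    raw[i] <- pk$raw_peak_uS
    reason[i] <- pk$missing_reason
  }
  rules <- apply_amplitude_rules(raw, config)
  out <- data.frame(
    subject = recording$subject_id %||% NA_character_,
    phase = phase,
    trial_type = ev$trial_type,
    trial_index = ev$trial_index,
    raw_peak_uS = raw,
    scr_uS = rules$scr_uS,
    scr_sqrt = sqrt_transform(rules$scr_uS),
    missing_reason = rules$missing_reason,
    stringsAsFactors = FALSE)
  attr(out, "qc") <- flags
  out
}

#' Score a whole synthetic cohort into a trial table
#'
#' Generates, preprocesses and scores each subject's recordings one phase at
#' a time (recordings are never all held in memory), joining group labels and
#' covariates. This is the long-format input to all statistical models.
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param config a [preprocess_config()]; `score_us = TRUE` adds US-locked
#'   rows for the acquisition phase.
#' @param phases phases to score (default: all in the cohort's protocol).
#' @param subjects subject ids to score (default: all).
#' @param progress print a line per subject.
#' @return data.frame trial table: one row per
#'   (subject, phase, trial_type, trial_index) with `scr_uS`, `scr_sqrt`,
#'   `missing_reason`, group label and covariates.
#' @export
score_cohort <- function(cohort, config = preprocess_config(),
                         phases = names(cohort$params$protocol),
                         subjects = names(cohort$subjects),
                         progress = FALSE) {
  md <- cohort_metadata(cohort)
  rows <- vector("list", length(subjects) * length(phases))
  k <- 0L
  for (sid in subjects) {
    for (ph in phases) {
      sim <- simulate_subject_phase(cohort, sid, ph)
      k <- k + 1L
      rows[[k]] <- score_phase(sim$recording, sim$schedule, config)
    }
    if (progress) message("scored ", sid)
  }
  trials <- do.call(rbind, c(rows[seq_len(k)], make.row.names = FALSE))
  merge(trials, md, by = "subject", sort = FALSE)
}
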