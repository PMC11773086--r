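test_that("median filter matches the brute-force sliding median", {
  set.seed(101)
  for (case in 1:6) {
    fs <- sample(c(100, 250, 1000), 1)
    n <- sample(200:600, 1)
    x <- cumsum(rnorm(n, 0, 0.1)) + 5
    rec <- structure(list(samples = x, sampling_rate_hz = fs,
                          start_time_s = 0),
                     class = "physio_recording")
    win <- sample(c(0.01, 0.03, 0.05), 1)
    k <- round(win * fs); if (k %% 2 == 0) k <- k + 1
    got <- median_filter(rec, win)$samples
    expect_equal(got, naive_sliding_median(x, max(k, 1)), tolerance = 1e-12)
  }

  # constant signal unchanged
  rec <- flat_recording(3, fs = 1000, dur = 1)
  expect_equal(median_filter(rec, 0.01)$samples, rec$samples)

  # single-sample spike removed by the 10 ms window at 1000 Hz
  x <- rep(5, 1000); x[500] <- 15
  rec <- structure(list(samples = x, sampling_rate_hz = 1000,
                        start_time_s = 0), class = "physio_recording")
  y <- median_filter(rec, 0.01)$samples
  expect_true(all(abs(y - 5) < 1e-12))
})

test_that("band-pass matches the analytic Butterworth response", {
  lo <- 0.03; hi <- 5
  # DC is removed entirely
  y <- bandpass(flat_recording(3, fs = 1000, dur = 60))$samples
  interior <- y[(20 * 1000):(40 * 1000)]
  expect_lt(mean(abs(interior)), 1e-3 * 3)

  # gains at 0.03, 1, 5, 50 Hz match the closed-form forward-backward
  # magnitude response within 5%
  for (f in c(0.03, 1, 5, 50)) {
    rec <- sine_recording(f, fs = 1000, dur = max(60, ceiling(6 / f)))
    y <- bandpass(rec)$samples
    n <- length(y)
    measured <- fitted_sine_amp(y, f, 1000, floor(n / 3):floor(2 * n / 3))
    expected <- analytic_bp_gain(f, lo, hi)
    expect_lt(abs(measured - expected) / expected, 0.05)
  }

  # band edges must be inside (0, Nyquist)
  expect_error(bandpass(flat_recording(1, fs = 100), high_hz = 60), "Nyquist")
})

test_that("downsampling: counts, identity, and waveform fidelity", {
  rec <- sine_recording(2, fs = 1000, dur = 60)
  down <- downsample(rec, 100)
  expect_equal(down$sampling_rate_hz, 100)
  expect_equal(length(down$samples), 6000L)

  # 1000 Hz, 60 s -> 6000 samples at 100 Hz; a 2 Hz sine survives
  t_new <- (0:5999) / 100
  expect_lt(max(abs(down$samples - sin(2 * pi * 2 * t_new))), 0.01)

  same <- downsample(rec, 1000)
  expect_identical(same$samples, rec$samples)

  expect_error(downsample(down, 1000), "upsampling")

  # non-integer ratio goes through interpolation
  odd <- downsample(rec, 300)
  expect_equal(odd$sampling_rate_hz, 300)
  expect_lt(max(abs(odd$samples - sin(2 * pi * 2 * (0:(length(odd$samples) - 1)) / 300))),
            0.01)
})

test_that("peak extraction equals the index-arithmetic oracle", {
  set.seed(33)
  for (case in 1:8) {
    fs <- sample(c(50, 100), 1)
    x <- cumsum(rnorm(20 * fs, 0, 0.05))
    rec <- structure(list(samples = x, sampling_rate_hz = fs,
                          start_time_s = 0), class = "physio_recording")
    onset <- runif(1, 0, 12)
    got <- extract_peak(rec, onset)
    want <- naive_peak(x, fs, onset)
    expect_equal(got$raw_peak_uS, want, tolerance = 1e-12)
  }

  # hand-built cases: bump of 0.5 above a zero baseline, then a 0.2 offset
  fs <- 100
  tt <- (0:(15 * fs - 1)) / fs
  bump <- 0.5 * exp(-((tt - 3)^2) / 0.1)
  rec <- structure(list(samples = bump, sampling_rate_hz = fs,
                        start_time_s = 0), class = "physio_recording")
  expect_equal(extract_peak(rec, 0)$raw_peak_uS, 0.5, tolerance = 1e-6)

  rec2 <- structure(list(samples = bump + 0.2, sampling_rate_hz = fs,
                         start_time_s = 0), class = "physio_recording")
  expect_equal(extract_peak(rec2, 0)$raw_peak_uS, 0.5, tolerance = 1e-6)

  # window beyond the recording end is missing, not an error
  out <- extract_peak(rec, 14)
  expect_true(is.na(out$raw_peak_uS))
  expect_equal(out$missing_reason, "window_out_of_range")
})

test_that("scoring is invariant to the recording's start-time offset", {
  fs <- 100
  tt <- (0:(30 * fs - 1)) / fs
  x <- 0.4 * exp(-((tt - 12)^2) / 0.5)
  rec_a <- structure(list(samples = x, sampling_rate_hz = fs,
                          start_time_s = 0), class = "physio_recording")
  rec_b <- structure(list(samples = x, sampling_rate_hz = fs,
                          start_time_s = -7.5), class = "physio_recording")
  a <- extract_peak(rec_a, 9)$raw_peak_uS
  b <- extract_peak(rec_b, 9 - 7.5)$raw_peak_uS
  expect_equal(a, b)
})

test_that("amplitude rules implement the floor/ceiling conventions exactly", {
  cfg <- preprocess_config()
  r <- apply_amplitude_rules(c(0.005, 6.2, 0.25, -0.3, NA, 0.01, 5), cfg)
  expect_equal(r$scr_uS, c(0, NA, 0.25, 0, NA, 0.01, 5))
  expect_equal(r$missing_reason,
               c("none", "ceiling", "none", "none", "window_out_of_range",
                 "none", "none"))

  # missingness is monotone in the ceiling
  set.seed(9)
  raw <- runif(200, 0, 10)
  n_missing <- vapply(c(2, 5, 8), function(ceil) {
    sum(is.na(apply_amplitude_rules(raw,
                                    preprocess_config(ceiling_uS = ceil))$scr_uS))
  }, numeric(1))
  expect_true(all(diff(n_missing) <= 0))
})

test_that("square-root transform handles 0, exact squares, and missing", {
  expect_equal(sqrt_transform(c(0, 4, NA)), c(0, 2, NA))
  expect_error(sqrt_transform(-1), "contract")
})

test_that("score_phase runs the whole chain and respects trial structure", {
  p <- default_protocol()
  s <- make_schedule(p$acquisition, 6)
  sub <- quiet_subject()

  rec <- simulate_recording(s, sub, model = noiseless_model(0.5),
                            sampling_rate_hz = 250, seed = 1)
  tr <- score_phase(rec, s)
  expect_equal(nrow(tr), 20L)
  expect_equal(sum(tr$trial_type == "CS+"), 10L)

  tr_us <- score_phase(rec, s, preprocess_config(score_us = TRUE))
  expect_equal(nrow(tr_us), 28L)
  expect_equal(sum(tr_us$trial_type == "US"), 8L)

  # zero-amplitude simulation: everything floors to 0
  rec0 <- simulate_recording(s, sub, model = amplitude_model(p_nonresponse = 1),
                             sampling_rate_hz = 250, seed = 2)
  tr0 <- score_phase(rec0, s)
  expect_true(all(tr0$scr_uS == 0))
  expect_true(all(tr0$scr_sqrt == 0))

  # planted amplitudes above the 5 uS ceiling come back missing
  rec_big <- simulate_recording(s, sub, model = noiseless_model(8),
                                sampling_rate_hz = 250, seed = 3)
  tr_big <- score_phase(rec_big, s)
  expect_true(all(tr_big$missing_reason == "ceiling"))
  expect_true(all(is.na(tr_big$scr_uS)))
})

test_that("noise-free scored amplitude tracks the planted amplitude", {
  # the chain attenuates every response by the same filter-dependent factor;
  # scored/planted must be constant across amplitudes and within 5% of 1
  cfg2 <- phase_config("habituation", 2, 2, 7, 7)
  s <- make_schedule(cfg2, 3)
  ratios <- vapply(c(0.2, 1, 3), function(A) {
    rec <- simulate_recording(s, quiet_subject(), model = noiseless_model(A),
                              sampling_rate_hz = 500, seed = 1)
    tr <- score_phase(rec, s)
    mean(tr$raw_peak_uS) / A
  }, numeric(1))
  expect_lt(max(abs(ratios - 1)), 0.05)
  expect_lt(diff(range(ratios)), 1e-3)
})

test_that("stage order matters: skipping the band-pass changes the scores", {
  p <- default_protocol()
  s <- make_schedule(p$habituation, 4)
  sub <- subject_spec("n", "adult", noise_sd_uS = 0.05,
                      drift_uS_per_s = 2e-3)
  rec <- simulate_recording(s, sub, sampling_rate_hz = 250, seed = 5)
  full <- score_phase(rec, s)

  # peak on the raw (unfiltered, undownsampled) signal differs: the tonic
  # level and drift leak into the baseline-corrected peaks
  raw_peaks <- vapply(seq_len(nrow(s$events)), function(i) {
    naive_peak(rec$samples, 250, s$events$onset[i] - rec$start_time_s)
  }, numeric(1))
  cs <- s$events$trial_type != "US"
  expect_gt(max(abs(raw_peaks[cs] - full$raw_peak_uS)), 0.01)
})

test_that("QC flags catch flat-lined, railed and gapped recordings", {
  expect_equal(qc_flags(flat_recording(2)), "flat_line")

  x <- rnorm(3000, 5, 0.5)
  x[x > 5.5] <- 5.5
  rec <- structure(list(samples = x, sampling_rate_hz = 100,
                        start_time_s = 0), class = "physio_recording")
  expect_true("railing" %in% qc_flags(rec))

  x2 <- rnorm(3000, 5, 0.5); x2[100:200] <- NA
  rec2 <- structure(list(samples = x2, sampling_rate_hz = 100,
                         start_time_s = 0), class = "physio_recording")
  expect_true("gap" %in% qc_flags(rec2))

  clean <- structure(list(samples = rnorm(3000, 5, 0.5),
                          sampling_rate_hz = 100, start_time_s = 0),
                     class = "physio_recording")
  expect_length(qc_flags(clean), 0)
})
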