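# Independent brute-force oracles used across test files. These re-derive
# quantities from first principles (explicit loops, index arithmetic) and
# must stay independent of the package's implementations.

# naive centered sliding median with reflection padding (window k odd)
naive_sliding_median <- function(x, k) {
  h <- (k - 1) / 2
  n <- length(x)
  left <- x[pmin(n, pmax(1, (h + 1):2))]
  right <- x[pmin(n, pmax(1, (n - 1):(n - h)))]
  padded <- c(left, x, right)
  vapply(seq_len(n), function(i) {
    stats::median(padded[i:(i + k - 1)])
  }, numeric(1))
}

# naive baseline-corrected peak: explicit index arithmetic, closed-open
# sample windows, onset mapped to first sample at-or-after onset
naive_peak <- function(x, fs, onset_rel, baseline = c(0, 1), window = c(1, 5)) {
  i0 <- ceiling(onset_rel * fs - 1e-9) + 1
  b <- (i0 + floor(baseline[1] * fs)):(i0 + ceiling(baseline[2] * fs) - 1)
  p <- (i0 + floor(window[1] * fs)):(i0 + ceiling(window[2] * fs) - 1)
  if (min(b) < 1 || max(p) > length(x)) return(NA_real_)
  mx <- -Inf
  for (i in p) mx <- max(mx, x[i])
  s <- 0
  for (i in b) s <- s + x[i]
  mx - s / length(b)
}

# analytic magnitude of an order-n Butterworth band-pass at f (Hz);
# forward-backward application squares it
analytic_bp_gain <- function(f, lo, hi, order = 1, zero_phase = TRUE) {
  W <- (f^2 - lo * hi) / (f * (hi - lo))
  g <- (1 + W^(2 * order))^(-0.5)
  if (zero_phase) g^2 else g
}

# least-squares amplitude of the f-Hz component of y over sample range idx
fitted_sine_amp <- function(y, f, fs, idx) {
  tt <- (idx - 1) / fs
  co <- stats::coef(stats::lm(y[idx] ~ sin(2 * pi * f * tt) +
                                cos(2 * pi * f * tt)))
  sqrt(co[2]^2 + co[3]^2)
}

# enumerate all distinct CS+/CS- type orderings and keep those whose longest
# run of identical labels is within the bound
enumerate_valid_orders <- function(n_plus, n_minus, bound) {
  n <- n_plus + n_minus
  pos <- utils::combn(n, n_plus)
  keep <- character(0)
  for (j in seq_len(ncol(pos))) {
    lab <- rep("CS-", n)
    lab[pos[, j]] <- "CS+"
    if (max(rle(lab)$lengths) <= bound) {
      keep <- c(keep, paste(lab, collapse = ""))
    }
  }
  keep
}

# pure-sine test recording
sine_recording <- function(f, fs = 1000, dur = 60, amp = 1) {
  n <- dur * fs
  structure(list(samples = amp * sin(2 * pi * f * (0:(n - 1)) / fs),
                 sampling_rate_hz = fs, start_time_s = 0,
                 subject_id = "test", phase_name = "test"),
            class = "physio_recording")
}

flat_recording <- function(level, fs = 100, dur = 30) {
  structure(list(samples = rep(level, fs * dur), sampling_rate_hz = fs,
                 start_time_s = 0, subject_id = "test", phase_name = "test"),
            class = "physio_recording")
}

# deterministic noise-free simulation settings for single-event checks
noiseless_model <- function(amp_uS) {
  amplitude_model(base_log_uS = log(amp_uS), habituation_slope = 0,
                  subject_sd = 0, noise_sd = 0, p_nonresponse = 0,
                  group_offsets = c(child = 0, adolescent = 0, adult = 0))
}

quiet_subject <- function(id = "sub-test", group = "adult") {
  subject_spec(id, group, intercept = 0, tonic_uS = 5, drift_uS_per_s = 0,
               noise_sd_uS = 0, motion_level = 0)
}

# direct marginal Gaussian log-likelihood of a random-intercept model
direct_lmm_loglik <- function(y_by_subject, X_by_subject, beta, sb2, se2) {
  ll <- 0
  for (i in seq_along(y_by_subject)) {
    y <- y_by_subject[[i]]
    X <- X_by_subject[[i]]
    m <- length(y)
    V <- matrix(sb2, m, m) + diag(se2, m)
    r <- y - drop(X %*% beta)
    ll <- ll - 0.5 * (m * log(2 * pi) + determinant(V)$modulus +
                        drop(t(r) %*% solve(V, r)))
  }
  as.numeric(ll)
}

tiny_group_params <- function(n = 2) {
  gp <- default_group_params()
  for (g in names(gp)) gp[[g]]$n <- n
  gp
}
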