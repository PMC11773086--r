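# Four-phase differential fear-conditioning protocol: phase configurations,
# pseudorandom trial orderings, truncated-Gaussian inter-trial intervals, and
# tab-separated events files.

#' Phase configuration for the conditioning protocol
#'
#' @param phase_name one of `"habituation"`, `"acquisition"`, `"extinction"`,
#'   `"retention"`.
#' @param n_cs_plus,n_cs_minus number of CS+ / CS- presentations.
#' @param cs_plus_duration_s,cs_minus_duration_s stimulus durations (s).
#' @param us_duration_s duration of the unconditioned stimulus (s); only
#'   meaningful when `n_reinforced > 0`.
#' @param n_reinforced number of CS+ trials directly followed by the US.
#' @param iti_mean_s,iti_sd_s mean and SD of the Gaussian inter-trial-interval
#'   distribution (s), truncated at plus/minus 3 SD.
#' @param max_run_length maximum number of identical consecutive CS types.
#' @param reinforced_positions optional integer vector of CS+ trial indices to
#'   reinforce; `NULL` means choose `n_reinforced` uniformly at random.
#' @return a `phase_config` list.
#' @export
phase_config <- function(phase_name,
                         n_cs_plus, n_cs_minus,
                         cs_plus_duration_s, cs_minus_duration_s,
                         us_duration_s = 0,
                         n_reinforced = 0,
                         iti_mean_s = 12, iti_sd_s = 1,
                         max_run_length = 2,
                         reinforced_positions = NULL) {
  phase_name <- match.arg(phase_name,
                          c("habituation", "acquisition", "extinction",
                            "retention"))
  stopifnot(n_cs_plus >= 0, n_cs_minus >= 0,
            cs_plus_duration_s > 0, cs_minus_duration_s > 0,
            n_reinforced >= 0, n_reinforced <= n_cs_plus,
            max_run_length >= 1, iti_sd_s >= 0)
  if (n_reinforced > 0 && us_duration_s <= 0) {
    stop("`us_duration_s` must be > 0 when trials are reinforced",
         call. = FALSE)
  }
  if (!is.null(reinforced_positions)) {
    reinforced_positions <- as.integer(reinforced_positions)
    if (length(reinforced_positions) != n_reinforced ||
        anyDuplicated(reinforced_positions) ||
        any(reinforced_positions < 1L | reinforced_positions > n_cs_plus)) {
      stop("`reinforced_positions` must be ", n_reinforced,
           " distinct CS+ trial indices in 1..", n_cs_plus, call. = FALSE)
    }
  }
  structure(
    list(phase_name = phase_name,
         n_cs_plus = as.integer(n_cs_plus),
         n_cs_minus = as.integer(n_cs_minus),
         cs_plus_duration_s = cs_plus_duration_s,
         cs_minus_duration_s = cs_minus_duration_s,
         us_duration_s = us_duration_s,
         n_reinforced = as.integer(n_reinforced),
         iti_mean_s = iti_mean_s,
         iti_sd_s = iti_sd_s,
         max_run_length = as.integer(max_run_length),
         reinforced_positions = reinforced_positions),
    class = "phase_config")
}

#' Default four-phase protocol
#'
#' Habituation: 4 CS+ and 4 CS- for 7 s each. Acquisition: 10 CS+ and 10 CS-,
#' CS+ for 6 s, CS- for 7 s, with 8 of the 10 CS+ directly followed by a 1 s
#' US (80\% reinforcement). Extinction and retention: 10 CS+ and 10 CS- for
#' 7 s each with no US. All phases use inter-trial intervals drawn from a
#' Gaussian with mean 12 s and SD 1 s, and pseudorandom orderings with no more
#' than two identical CS types in a row.
#'
#' @return named list of four [phase_config()] objects.
#' @export
default_protocol <- function() {
  list(
    habituation = phase_config("habituation", 4, 4, 7, 7),
    acquisition = phase_config("acquisition", 10, 10, 6, 7,
                               us_duration_s = 1, n_reinforced = 8),
    extinction  = phase_config("extinction", 10, 10, 7, 7),
    retention   = phase_config("retention", 10, 10, 7, 7)
  )
}

#' Sample inter-trial intervals
#'
#' Draws from a normal distribution truncated to mean plus/minus 3 SD by
#' resampling. With `sd = 0` every draw equals the mean.
#'
#' @param n number of draws.
#' @param mean_s,sd_s distribution parameters (s).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector of `n` intervals, all positive.
#' @export
sample_iti <- function(n, mean_s = 12, sd_s = 1, seed = NULL) {
  assert_scalar_number(mean_s, "mean_s")
  assert_scalar_number(sd_s, "sd_s")
  stopifnot(sd_s >= 0, mean_s > 3 * sd_s || mean_s > 0)
  draw <- function() {
    if (sd_s == 0) return(rep(mean_s, n))
    x <- rnorm(n, mean_s, sd_s)
    bad <- abs(x - mean_s) > 3 * sd_s
    while (any(bad)) {
      x[bad] <- rnorm(sum(bad), mean_s, sd_s)
      bad <- abs(x - mean_s) > 3 * sd_s
    }
    x
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (any(out <= 0)) {
    stop("truncated ITI distribution produced non-positive interval; ",
         "check mean/SD", call. = FALSE)
  }
  out
}

# Longest run of identical values in a character vector.
max_run <- function(x) {
  if (length(x) == 0L) return(0L)
  max(rle(x)$lengths)
}

# One uniform shuffle of CS+/CS- labels satisfying the run-length bound,
# by rejection; NULL if `attempts` exhausted.
sample_order <- function(n_plus, n_minus, max_run_length, attempts = 10000L) {
  labels <- c(rep("CS+", n_plus), rep("CS-", n_minus))
  if (length(labels) == 0L) return(character(0))
  for (i in seq_len(attempts)) {
    cand <- sample(labels)
    if (max_run(cand) <= max_run_length) return(cand)
  }
  NULL
}

#' Build a timed event schedule for one phase
#'
#' Orders the CS+ and CS- presentations pseudorandomly (uniform over orderings
#' with no run of identical types longer than `max_run_length`, via rejection
#' sampling of shuffles), assigns reinforcement to the configured number of
#' CS+ trials (uniformly at random unless pinned in the config), inserts US
#' events at the offset of each reinforced CS+, and lays events out in time
#' with truncated-Gaussian inter-trial intervals. Onsets are phase-relative,
#' starting at 0.
#'
#' @param config a [phase_config()].
#' @param seed integer seed; schedules are a pure function of (config, seed).
#' @param max_attempts rejection-sampling budget for the ordering.
#' @return a `task_schedule`: list with `config`, `seed`, and `events`
#'   (data.frame with columns `onset`, `duration`, `trial_type`,
#'   `trial_index`, `reinforced`).
#' @export
make_schedule <- function(config, seed, max_attempts = 10000L) {
  stopifnot(inherits(config, "phase_config"))
  assert_scalar_number(seed, "seed")

  build <- function() {
    ord <- sample_order(config$n_cs_plus, config$n_cs_minus,
                        config$max_run_length, max_attempts)
    if (is.null(ord)) {
      stop("no ordering of ", config$n_cs_plus, " CS+ and ",
           config$n_cs_minus, " CS- satisfies max run length ",
           config$max_run_length, " within ", max_attempts, " attempts",
           call. = FALSE)
    }
    reinforced_idx <- config$reinforced_positions %||%
      sort(sample(config$n_cs_plus, config$n_reinforced))
    itis <- sample_iti(length(ord), config$iti_mean_s, config$iti_sd_s)

    onset <- numeric(length(ord))
    duration <- numeric(length(ord))
    trial_index <- integer(length(ord))
    reinforced <- logical(length(ord))
    us_rows <- list()
    t_cur <- 0
    n_seen <- c("CS+" = 0L, "CS-" = 0L)
    for (i in seq_along(ord)) {
      type <- ord[i]
      n_seen[type] <- n_seen[type] + 1L
      dur <- if (type == "CS+") config$cs_plus_duration_s else
        config$cs_minus_duration_s
      onset[i] <- t_cur
      duration[i] <- dur
      trial_index[i] <- n_seen[[type]]
      reinforced[i] <- type == "CS+" && n_seen[["CS+"]] %in% reinforced_idx
      if (reinforced[i]) {
        us_rows[[length(us_rows) + 1L]] <- data.frame(
          onset = t_cur + dur, duration = config$us_duration_s,
          trial_type = "US", trial_index = length(us_rows) + 1L,
          reinforced = NA)
      }
      t_cur <- t_cur + dur + itis[i]
    }
    events <- data.frame(onset = onset, duration = duration, trial_type = ord,
                         trial_index = trial_index, reinforced = reinforced,
                         stringsAsFactors = FALSE)
    events$reinforced[events$trial_type == "CS-"] <- NA
    events <- rbind(events, do.call(rbind, us_rows))
    events <- events[order(events$onset, events$trial_type != "US"), ]
    rownames(events) <- NULL
    events
  }

  events <- with_seed(seed, build())
  structure(list(config = config, seed = as.integer(seed), events = events),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule> phase=%s  %d events  seed=%d\n",
              x$config$phase_name, nrow(x$events), x$seed))
  invisible(x)
}

#' Write a schedule to a tab-separated events file
#'
#' Columns `onset`, `duration`, `trial_type`, `trial_index`, `reinforced`;
#' onsets in seconds with three decimals (BIDS events convention).
#'
#' @param schedule a `task_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "task_schedule"))
  ev <- schedule$events
  out <- data.frame(
    onset = sprintf("%.3f", ev$onset),
    duration = sprintf("%.3f", ev$duration),
    trial_type = ev$trial_type,
    trial_index = ev$trial_index,
    reinforced = ifelse(is.na(ev$reinforced), "n/a",
                        ifelse(ev$reinforced, "true", "false")))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events file
#'
#' Parses a tab-separated events file written by [write_events()] (or any
#' file following the same column convention), validating every row.
#'
#' @param path events file path.
#' @return data.frame with columns `onset`, `duration`, `trial_type`,
#'   `trial_index`, `reinforced`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("numeric", "numeric", "character",
                                         "integer", "character"))
  required <- c("onset", "duration", "trial_type", "trial_index", "reinforced")
  if (!identical(names(ev), required)) {
    stop("events file must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  # data rows start at line 2 (header is line 1)
  bad_onset <- which(!is.finite(ev$onset) | ev$onset < 0)
  if (length(bad_onset)) {
    stop("invalid onset at line ", bad_onset[1] + 1L, " of ", path,
         call. = FALSE)
  }
  bad_type <- which(!ev$trial_type %in% c("CS+", "CS-", "US"))
  if (length(bad_type)) {
    stop("unknown trial_type '", ev$trial_type[bad_type[1]], "' at line ",
         bad_type[1] + 1L, " of ", path, call. = FALSE)
  }
  bad_dur <- which(!is.finite(ev$duration) | ev$duration <= 0)
  if (length(bad_dur)) {
    stop("invalid duration at line ", bad_dur[1] + 1L, " of ", path,
         call. = FALSE)
  }
  ev$reinforced <- ifelse(ev$reinforced == "n/a", NA, ev$reinforced == "true")
  ev
}

#' Validate a schedule against its configuration
#'
#' Checks trial counts per type, the run-length bound, the reinforcement
#' count, US placement at CS+ offset, and the inter-trial-interval truncation
#' bounds.
#'
#' @param schedule a `task_schedule`.
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_schedule <- function(schedule) {
  cfg <- schedule$config
  ev <- schedule$events
  cs <- ev[ev$trial_type != "US", ]
  us <- ev[ev$trial_type == "US", ]
  if (sum(cs$trial_type == "CS+") != cfg$n_cs_plus ||
      sum(cs$trial_type == "CS-") != cfg$n_cs_minus) {
    stop("trial counts do not match config", call. = FALSE)
  }
  if (max_run(cs$trial_type) > cfg$max_run_length) {
    stop("run-length bound violated", call. = FALSE)
  }
  if (sum(cs$reinforced, na.rm = TRUE) != cfg$n_reinforced ||
      nrow(us) != cfg$n_reinforced) {
    stop("reinforcement count does not match config", call. = FALSE)
  }
  if (nrow(us)) {
    plus <- cs[cs$trial_type == "CS+" & cs$reinforced %in% TRUE, ]
    offsets <- sort(plus$onset + plus$duration)
    if (max(abs(sort(us$onset) - offsets)) > 1e-9) {
      stop("US events must start exactly at CS+ offset", call. = FALSE)
    }
  }
  gaps <- diff(cs$onset) - cs$duration[-nrow(cs)]
  lo <- cfg$iti_mean_s - 3 * cfg$iti_sd_s
  hi <- cfg$iti_mean_s + 3 * cfg$iti_sd_s
  if (length(gaps) && (any(gaps < lo - 1e-9) || any(gaps > hi + 1e-9))) {
    stop("inter-trial gap outside truncation bounds", call. = FALSE)
  }
  invisible(TRUE)
}
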