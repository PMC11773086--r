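# Framewise displacement and motion censoring from six-column realignment
# parameters (translations mm, rotations radians).

#' Read SPM-style realignment parameters
#'
#' Six whitespace-delimited columns: translations in mm (1-3), rotations in
#' radians (4-6), one row per volume.
#'
#' @param path `rp_*.txt` file.
#' @return numeric matrix, n_volumes x 6.
#' @export
read_realignment <- function(path) {
  if (!file.exists(path)) {
    stop("realignment file not found: ", path, call. = FALSE)
  }
  rp <- as.matrix(utils::read.table(path))
  if (ncol(rp) != 6L) {
    stop("expected 6 columns in ", path, ", found ", ncol(rp), call. = FALSE)
  }
  if (any(!is.finite(rp))) {
    stop("non-finite realignment parameters in ", path, call. = FALSE)
  }
  dimnames(rp) <- NULL
  rp
}

#' Framewise displacement
#'
#' Per-volume head-motion summary: the absolute sum of the volume-to-volume
#' changes of the six realignment parameters, with rotations converted to arc
#' length on a sphere of `head_radius_mm`:
#' `FD_t = sum_i |d trans_i| + radius * sum_i |d rot_i|`, and `FD_1 = 0`.
#'
#' @param rp n_volumes x 6 matrix (translations mm, rotations radians).
#' @param head_radius_mm rotation-to-displacement conversion radius.
#' @return numeric vector of FD values (mm), one per volume.
#' @export
compute_fd <- function(rp, head_radius_mm = 50) {
  rp <- as.matrix(rp)
  if (ncol(rp) != 6L) stop("`rp` must have 6 columns", call. = FALSE)
  if (any(!is.finite(rp))) {
    stop("non-finite realignment parameters", call. = FALSE)
  }
  if (nrow(rp) == 1L) return(0)
  d <- abs(diff(rp))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Censor high-motion volumes
#'
#' Volumes with FD strictly above the threshold are marked as outliers. Also
#' builds the one-indicator-column-per-censored-volume regressor matrix used
#' in scrubbing-style first-level models.
#'
#' @param fd FD vector from [compute_fd()].
#' @param threshold_mm censoring threshold (mm); strict inequality.
#' @return a `censor_result`: list with `fd`, `mask` (TRUE = censored),
#'   `n_censored`, `threshold_mm`, and `regressors` (n_volumes x n_censored
#'   0/1 matrix).
#' @export
censor <- function(fd, threshold_mm = 0.9) {
  stopifnot(all(is.finite(fd)), all(fd >= 0))
  mask <- fd > threshold_mm
  reg <- matrix(0, length(fd), sum(mask))
  if (sum(mask)) reg[cbind(which(mask), seq_len(sum(mask)))] <- 1
  structure(list(fd = fd, mask = mask, n_censored = sum(mask),
                 threshold_mm = threshold_mm, regressors = reg),
            class = "censor_result")
}

#' @export
print.censor_result <- function(x, ...) {
  cat(sprintf("<censor_result> %d/%d volumes censored (FD > %g mm)\n",
              x$n_censored, length(x$fd), x$threshold_mm))
  invisible(x)
}

#' Motion/censoring summary for a cohort
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param threshold_mm censoring threshold (mm).
#' @param head_radius_mm rotation conversion radius.
#' @return data.frame with one row per subject: `mean_fd`, `max_fd`,
#'   `n_censored`, group label.
#' @export
censoring_summary <- function(cohort, threshold_mm = 0.9,
                              head_radius_mm = 50) {
  rows <- lapply(names(cohort$subjects), function(sid) {
    rp <- simulate_subject_motion(cohort, sid)
    fd <- compute_fd(rp, head_radius_mm)
    cr <- censor(fd, threshold_mm)
    data.frame(subject = sid,
               group = cohort$subjects[[sid]]$spec$age_group,
               mean_fd = mean(fd), max_fd = max(fd),
               n_censored = cr$n_censored, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
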