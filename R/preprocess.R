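# Time-series preprocessing and participant-level quality control.
#
# Fixed stage order: discard initial frames -> nuisance regression ->
# band-pass -> scrubbing. Censored frames are removed (never interpolated)
# before any correlation downstream.

#' Construct a time-series object
#'
#' @param values Numeric frames x channels matrix (a vector is treated as a
#'   single channel).
#' @param tr_seconds Repetition time in seconds (default 2.0).
#' @param frame_retained Optional logical vector, one entry per frame; frames
#'   marked `FALSE` are excluded from downstream statistics.
#' @return An object of class `wm_time_series`.
#' @export
wm_time_series <- function(values, tr_seconds = 2, frame_retained = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("time series needs at least one frame", call. = FALSE)
  if (is.null(frame_retained)) frame_retained <- rep(TRUE, nrow(values))
  stopifnot(is.logical(frame_retained), length(frame_retained) == nrow(values),
            tr_seconds > 0)
  structure(list(values = values, tr_seconds = tr_seconds,
                 frame_retained = frame_retained),
            class = "wm_time_series")
}

#' @export
print.wm_time_series <- function(x, ...) {
  cat(sprintf("<wm_time_series> %d frames x %d channels, TR = %gs, %d retained\n",
              nrow(x$values), ncol(x$values), x$tr_seconds,
              sum(x$frame_retained)))
  invisible(x)
}

#' Construct a motion trace
#'
#' @param params Frames x 6 matrix: 3 translations (mm) then 3 rotations.
#' @param rotation_units `"radians"` (default) or `"degrees"`; degrees are
#'   converted to radians on construction so FD is always computed in
#'   consistent units.
#' @param tr_seconds Repetition time (metadata).
#' @return An object of class `motion_trace`; `fd` and `mean_fd` are filled
#'   by [compute_fd()].
#' @export
motion_trace <- function(params, rotation_units = c("radians", "degrees"),
                         tr_seconds = 2) {
  params <- as.matrix(params)
  storage.mode(params) <- "double"
  if (ncol(params) != 6L) {
    stop("motion parameters must have 6 columns (3 translations, 3 rotations)",
         call. = FALSE)
  }
  rotation_units <- match.arg(rotation_units)
  if (rotation_units == "degrees") {
    params[, 4:6] <- params[, 4:6] * pi / 180
  }
  structure(list(params = params, fd = NULL, mean_fd = NULL,
                 tr_seconds = tr_seconds),
            class = "motion_trace")
}

#' Discard initial frames
#'
#' Drops the first `n_discard` frames (dummy scans acquired before
#' steady-state magnetization), e.g. 242 acquired volumes minus the first 7
#' leaves 235.
#'
#' @param ts A [wm_time_series()].
#' @param n_discard Number of leading frames to drop; must be < frame count.
#' @return The shortened `wm_time_series`.
#' @export
discard_initial <- function(ts, n_discard = 7) {
  stopifnot(inherits(ts, "wm_time_series"), n_discard >= 0)
  n <- nrow(ts$values)
  if (n_discard >= n) {
    stop(sprintf("cannot discard %d of %d frames", n_discard, n), call. = FALSE)
  }
  if (n_discard == 0) return(ts)
  keep <- (n_discard + 1L):n
  wm_time_series(ts$values[keep, , drop = FALSE], ts$tr_seconds,
                 ts$frame_retained[keep])
}

#' Compute framewise displacement (FD)
#'
#' Power-style FD: for frame i >= 2,
#' `fd[i] = sum(|delta translations|) + head_radius * sum(|delta rotations|)`
#' with rotations converted to arc length on a sphere of `head_radius_mm`
#' (default 50 mm); `fd[1] = 0`. `mean_fd` is the mean over all frames.
#'
#' @param motion A [motion_trace()] (rotations in radians).
#' @param head_radius_mm Sphere radius for the rotation arc length.
#' @return The `motion_trace` with `fd` and `mean_fd` filled in.
#' @export
compute_fd <- function(motion, head_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  p <- motion$params
  if (nrow(p) < 2L) stop("FD needs at least 2 frames", call. = FALSE)
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  motion$fd <- fd
  motion$mean_fd <- mean(fd)
  motion
}

#' Build the 24-parameter motion regressor set
#'
#' Columns are the 6 rigid-body parameters, their temporal derivatives
#' (backward differences, first row 0), their squares, and the squared
#' derivatives.
#'
#' @param motion A [motion_trace()].
#' @return Frames x 24 numeric matrix.
#' @export
build_motion24 <- function(motion) {
  stopifnot(inherits(motion, "motion_trace"))
  p <- motion$params
  if (nrow(p) < 2L) stop("motion24 needs at least 2 frames", call. = FALSE)
  dp <- rbind(0, diff(p))
  cbind(p, dp, p^2, dp^2)
}

#' Regress nuisance signals out of a time series
#'
#' Each channel is replaced by its least-squares residual against an
#' intercept plus the supplied regressors (e.g. the CSF mean signal and the
#' 24 motion parameters). Rank-deficient designs are handled by pivoting:
#' redundant columns are dropped with a warning.
#'
#' @param ts A [wm_time_series()].
#' @param regressors Frames x p numeric matrix.
#' @return The residual `wm_time_series` (frames unchanged).
#' @export
regress_nuisance <- function(ts, regressors) {
  stopifnot(inherits(ts, "wm_time_series"))
  regressors <- as.matrix(regressors)
  n <- nrow(ts$values)
  if (nrow(regressors) != n) {
    stop("regressor rows must equal time-series frames", call. = FALSE)
  }
  design <- cbind(1, regressors)
  fit <- stats::lm.fit(design, ts$values)
  if (fit$rank < ncol(design)) {
    warning(sprintf("rank-deficient nuisance design: dropped %d redundant column(s)",
                    ncol(design) - fit$rank), call. = FALSE)
  }
  res <- as.matrix(fit$residuals)
  wm_time_series(res, ts$tr_seconds, ts$frame_retained)
}

# squared magnitude response of a cascaded 4th-order Butterworth
# high-pass/low-pass pair, applied zero-phase in the frequency domain
butter_bp_gain2 <- function(freq, low_hz, high_hz, order = 4) {
  hp <- ifelse(freq == 0, 0, 1 / (1 + (low_hz / pmax(freq, .Machine$double.eps))^(2 * order)))
  lp <- 1 / (1 + (freq / high_hz)^(2 * order))
  hp * lp
}

#' Band-pass filter a time series
#'
#' Zero-phase band-pass with 4th-order Butterworth magnitude response,
#' applied in the frequency domain (forward-backward, i.e. the squared
#' magnitude). The default 0.01-0.10 Hz band retains low-frequency BOLD
#' fluctuations and removes drift (DC gain is exactly 0) and respiratory-band
#' power. Channels are linearly detrended before the FFT to limit leakage.
#'
#' @param ts A [wm_time_series()].
#' @param low_hz,high_hz Band edges; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * tr_seconds)`.
#' @return Filtered `wm_time_series` (frame count unchanged).
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.10) {
  stopifnot(inherits(ts, "wm_time_series"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop(sprintf("band [%g, %g] Hz invalid for Nyquist %g Hz",
                 low_hz, high_hz, nyquist), call. = FALSE)
  }
  x <- ts$values
  n <- nrow(x)
  t_idx <- seq_len(n)
  # remove linear trend per channel
  trend_fit <- stats::lm.fit(cbind(1, t_idx), x)
  x <- as.matrix(trend_fit$residuals)
  freq <- seq_len(n) - 1L
  freq <- pmin(freq, n - freq) / (n * ts$tr_seconds)
  gain <- butter_bp_gain2(freq, low_hz, high_hz)
  y <- apply(x, 2, function(col) Re(stats::fft(stats::fft(col) * gain,
                                               inverse = TRUE)) / n)
  wm_time_series(matrix(y, nrow = n), ts$tr_seconds, ts$frame_retained)
}

#' Scrub high-motion frames
#'
#' Frames whose FD exceeds `fd_threshold` are censored together with one
#' forward frame and two previous frames (the window `{i-2, i-1, i, i+1}`,
#' clipped at the series boundaries; overlapping windows are unioned).
#' Censored frames are marked not-retained; downstream statistics drop them
#' rather than interpolate.
#'
#' @param ts A [wm_time_series()].
#' @param motion A [motion_trace()] with FD computed ([compute_fd()]).
#' @param fd_threshold FD threshold in mm (default 0.5).
#' @return The `wm_time_series` with updated `frame_retained`; attribute
#'   `retention` holds the retained fraction.
#' @export
scrub <- function(ts, motion, fd_threshold = 0.5) {
  stopifnot(inherits(ts, "wm_time_series"), inherits(motion, "motion_trace"))
  if (is.null(motion$fd)) stop("compute_fd() must be run before scrub()", call. = FALSE)
  n <- nrow(ts$values)
  if (length(motion$fd) != n) {
    stop("motion trace and time series have different frame counts", call. = FALSE)
  }
  spikes <- which(motion$fd > fd_threshold)
  censored <- unique(unlist(lapply(spikes, function(i) {
    w <- (i - 2L):(i + 1L)
    w[w >= 1L & w <= n]
  })))
  retained <- ts$frame_retained
  retained[censored] <- FALSE
  out <- wm_time_series(ts$values, ts$tr_seconds, retained)
  attr(out, "retention") <- mean(retained)
  out
}

#' Participant-level QC limits
#'
#' The default limits are the study's printed exclusion rules: maximum
#' absolute translation 2 mm, maximum absolute rotation 2 degrees, mean FD
#' 0.15 mm, and at least 80% of frames retained after scrubbing.
#'
#' @param max_translation_mm,max_rotation_deg,max_mean_fd,min_retention
#'   Thresholds; a participant exceeding any is excluded.
#' @return A named list of limits.
#' @export
qc_limits <- function(max_translation_mm = 2, max_rotation_deg = 2,
                      max_mean_fd = 0.15, min_retention = 0.80) {
  list(max_translation_mm = max_translation_mm,
       max_rotation_deg = max_rotation_deg,
       max_mean_fd = max_mean_fd, min_retention = min_retention)
}

#' Quality-control a participant's motion and retention
#'
#' @param motion A [motion_trace()] with FD computed.
#' @param retention Fraction of frames retained after scrubbing.
#' @param limits A [qc_limits()] list.
#' @param id Participant identifier carried into the report.
#' @param gf_outlier Logical flag from cohort-level [exclude_outliers()]
#'   screening (default `FALSE`).
#' @return A one-row data frame: id, the individual flags, and `included`
#'   (`TRUE` iff no flag is set).
#' @export
qc_participant <- function(motion, retention, limits = qc_limits(),
                           id = NA_character_, gf_outlier = FALSE) {
  stopifnot(inherits(motion, "motion_trace"))
  if (is.null(motion$mean_fd)) stop("compute_fd() must be run first", call. = FALSE)
  max_trans <- max(abs(motion$params[, 1:3]))
  max_rot_deg <- max(abs(motion$params[, 4:6])) * 180 / pi
  flags <- c(
    max_translation_exceeded = max_trans > limits$max_translation_mm,
    max_rotation_exceeded = max_rot_deg > limits$max_rotation_deg,
    mean_fd_exceeded = motion$mean_fd > limits$max_mean_fd,
    retention_below_threshold = retention < limits$min_retention,
    gf_outlier = isTRUE(gf_outlier)
  )
  data.frame(id = id, t(flags), included = !any(flags),
             stringsAsFactors = FALSE)
}

#' Exclude behavioral-score outliers
#'
#' Retains scores within `k_sd` standard deviations of the sample mean; mean
#' and SD are computed once on the full sample (no iterative re-screening).
#' A zero-SD sample retains everyone.
#'
#' @param scores Numeric vector of Gf scores (length >= 2).
#' @param k_sd Cutoff in SD units (default 2).
#' @return Integer indices of retained scores.
#' @export
exclude_outliers <- function(scores, k_sd = 2) {
  stopifnot(is.numeric(scores), length(scores) >= 2)
  s <- stats::sd(scores)
  if (s == 0) return(seq_along(scores))
  which(abs(scores - mean(scores)) <= k_sd * s)
}
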