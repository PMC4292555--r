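#' Construct a signal trace
#'
#' Light container for a uniformly sampled single-channel signal.
#'
#' @param x numeric samples.
#' @param rate sampling rate, Hz.
#' @param t0 time of the first sample, seconds.
#' @return A list of class `signal_trace` with elements `x`, `rate`, `t0`.
#' @export
signal_trace <- function(x, rate, t0 = 0) {
  stopifnot(is.numeric(x), length(x) > 0L, rate > 0)
  structure(list(x = as.numeric(x), rate = rate, t0 = t0),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("signal_trace: %d samples @ %g Hz, t = [%.3f, %.3f) s\n",
              length(x$x), x$rate, x$t0, x$t0 + length(x$x) / x$rate))
  invisible(x)
}

# sample times of a signal_trace
signal_times <- function(sig) sig$t0 + (seq_along(sig$x) - 1L) / sig$rate

# moving average with shrinking window at the edges (centered, width w)
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Differentiate a kinematic trace into velocity and speed
#'
#' Central-difference differentiation of each position coordinate (one-sided
#' at the endpoints), followed by centered moving-average smoothing of each
#' velocity component. Speed is the Euclidean norm of the smoothed velocity
#' vector, so `speed >= |vx|` at every sample.
#'
#' @param trace a kinematic trace: `data.frame` with columns `time`, `x`,
#'   `y`, `z` (seconds, cm), timestamps strictly increasing.
#' @param smooth_window moving-average width in samples (default 5; use 1
#'   for no smoothing).
#' @return A `data.frame` of class `velocity_series` with columns `time`,
#'   `vx`, `vy`, `vz`, `speed` (cm/s).
#' @export
compute_velocity <- function(trace, smooth_window = 5L) {
  stopifnot(is.data.frame(trace), all(c("time", "x", "y", "z") %in% names(trace)))
  n <- nrow(trace)
  if (n < 3L) stop("need at least 3 kinematic samples to differentiate")
  tt <- trace$time
  if (any(diff(tt) <= 0)) stop("kinematic timestamps must be strictly increasing")
  deriv <- function(p) {
    v <- numeric(n)
    v[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) / (tt[3:n] - tt[1:(n - 2L)])
    v[1L] <- (p[2L] - p[1L]) / (tt[2L] - tt[1L])
    v[n] <- (p[n] - p[n - 1L]) / (tt[n] - tt[n - 1L])
    moving_average(v, as.integer(smooth_window))
  }
  vx <- deriv(trace$x); vy <- deriv(trace$y); vz <- deriv(trace$z)
  out <- data.frame(time = tt, vx = vx, vy = vy, vz = vz,
                    speed = sqrt(vx^2 + vy^2 + vz^2))
  class(out) <- c("velocity_series", "data.frame")
  out
}

#' Detect movement onset by a speed threshold
#'
#' Returns the timestamp of the first sample whose speed exceeds the
#' threshold (0.5 cm/s by convention); that instant becomes `t = 0` for the
#' trial. When a cue time is given the search starts at the cue, so
#' pre-cue movement cannot trigger detection.
#'
#' @param vel a `velocity_series` on absolute time (see
#'   [compute_velocity()]).
#' @param threshold cm/s, strictly positive.
#' @param from optional absolute time (e.g., the auditory cue) at which the
#'   search begins.
#' @param axis `"speed"` (default, 3-D speed) or `"x"` to threshold the
#'   absolute X-velocity only.
#' @return Onset time in seconds (absolute).
#' @export
detect_onset <- function(vel, threshold = 0.5, from = NULL, axis = c("speed", "x")) {
  axis <- match.arg(axis)
  if (threshold <= 0) stop("threshold must be > 0")
  s <- if (axis == "speed") vel$speed else abs(vel$vx)
  keep <- if (is.null(from)) rep(TRUE, length(s)) else vel$time >= from
  idx <- which(keep & s > threshold)
  if (length(idx) == 0L)
    stop("no movement detected: speed never exceeds ", threshold, " cm/s")
  vel$time[idx[1L]]
}

#' Cut a trial epoch around movement onset
#'
#' Extracts the window `[onset + window[1], onset + window[2])` (half-open)
#' from every signal channel and the kinematics, re-expressing all times
#' relative to onset. With the default window, a 1200 Hz channel yields
#' exactly 14,400 samples and 40 Hz kinematics exactly 480.
#'
#' @param signals named list of `signal_trace` objects (e.g., `ecog`,
#'   `emg`).
#' @param kin kinematic trace on absolute time.
#' @param onset absolute onset time, seconds.
#' @param window epoch limits relative to onset, seconds (default
#'   `c(-4, 8)`).
#' @param id optional trial identifier used in error messages.
#' @return A list of class `ecog_epoch`: `signals` (list of `signal_trace`
#'   with `t0` relative to onset), `kin` (times relative to onset),
#'   `onset`, `window`.
#' @export
extract_epoch <- function(signals, kin, onset, window = c(-4, 8), id = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  lab <- if (is.null(id)) "" else paste0(" (trial ", id, ")")
  a <- onset + window[1]; b <- onset + window[2]
  cut_sig <- function(sig) {
    tt <- signal_times(sig)
    if (a < tt[1L] - 1e-9 || b > tt[length(tt)] + 1 / sig$rate + 1e-9)
      stop("epoch window [", signif(a, 6), ", ", signif(b, 6),
           ") exceeds the recording extent", lab)
    keep <- which(tt >= a - 1e-9 & tt < b - 1e-9)
    signal_trace(sig$x[keep], sig$rate, t0 = tt[keep[1L]] - onset)
  }
  out_signals <- lapply(signals, cut_sig)
  dtk <- median(diff(kin$time))
  if (kin$time[1L] > a + 1e-9 || kin$time[nrow(kin)] < b - dtk - 1e-9)
    stop("epoch window exceeds the kinematic extent", lab)
  keepk <- which(kin$time >= a - 1e-9 & kin$time < b - 1e-9)
  kin_ep <- kin[keepk, , drop = FALSE]
  segs <- attr(kin, "segments"); spd <- attr(kin, "speed")
  kin_ep$time <- kin_ep$time - onset
  rownames(kin_ep) <- NULL
  if (!is.null(spd)) attr(kin_ep, "speed") <- spd[keepk]
  if (!is.null(segs)) attr(kin_ep, "segments") <- segs
  structure(list(signals = out_signals, kin = kin_ep, onset = onset,
                 window = window, id = id),
            class = "ecog_epoch")
}

#' Resample a velocity series onto spectrogram frame times
#'
#' Linear interpolation of every velocity column onto the requested frame
#' times (typically the 10 ms spectrogram frame grid). Extrapolation
#' outside the kinematic extent is refused.
#'
#' @param vel a `velocity_series`.
#' @param frame_times target times, seconds, within `range(vel$time)`.
#' @return A `velocity_series` on `frame_times`.
#' @export
resample_to_frames <- function(vel, frame_times) {
  if (min(frame_times) < vel$time[1L] - 1e-9 ||
      max(frame_times) > vel$time[nrow(vel)] + 1e-9)
    stop("frame_times extend beyond the kinematic extent; refusing to extrapolate")
  cols <- lapply(vel[c("vx", "vy", "vz", "speed")], function(y)
    approx(vel$time, y, frame_times)$y)
  out <- data.frame(time = frame_times, vx = cols$vx, vy = cols$vy,
                    vz = cols$vz, speed = cols$speed)
  class(out) <- c("velocity_series", "data.frame")
  out
}
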