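#' Parameters of a synthetic reach-and-retrieve session
#'
#' Bundles and validates every knob of the synthetic-session generator:
#' trial counts, phase-duration distributions, movement geometry, sampling
#' rates, and the spectral model of the simulated ECoG/EMG channels.
#' Defaults emulate a typical reach-pause-retrieve session: reach
#' 1.2 +/- 0.3 s, pause 1.3 +/- 0.4 s, retrieval 1.0 +/- 0.3 s, a 40 cm
#' target distance, 40 Hz motion tracking and 1200 Hz electrophysiology.
#'
#' Durations are drawn per trial from normal distributions truncated at
#' mean +/- 3 sd; parameter sets whose mean - 3 sd is not strictly positive
#' are rejected, so every trial has physically meaningful phases.
#'
#' The simulated ECoG is a sum of independent stationary processes shaped in
#' the frequency domain: a 1/f broadband background, a beta-band
#' (`beta_band`) oscillation whose amplitude is multiplied by `erd_depth`
#' while the hand moves (event-related desynchronization), and gamma-band
#' (`gamma_band`) noise whose instantaneous power grows linearly with hand
#' speed at `ers_gain` per cm/s (event-related synchronization). EMG is
#' zero-mean broadband noise gated by movement.
#'
#' @param n_trials number of trials in the session.
#' @param reach_duration_mean,reach_duration_sd seconds; outward-reach
#'   duration distribution.
#' @param pause_duration_mean,pause_duration_sd seconds; hold between reach
#'   and retrieval.
#' @param retrieve_duration_mean,retrieve_duration_sd seconds; return
#'   movement duration distribution.
#' @param onset_jitter_sd seconds; sd of the cue-to-movement latency.
#' @param onset_latency_mean seconds; mean cue-to-movement latency.
#' @param reach_amplitude cm; distance from rest to target along X.
#' @param overshoot_prob probability that a trial overshoots the target and
#'   adds a corrective reversal.
#' @param kin_rate Hz; motion-tracker sampling rate.
#' @param sig_rate Hz; electrophysiology sampling rate.
#' @param beta_band,gamma_band Hz; two-element intervals for the modulated
#'   oscillatory components.
#' @param erd_depth multiplicative amplitude factor applied to the beta
#'   component during movement; 1 disables the suppression.
#' @param ers_gain gamma power gain per cm/s of hand speed; 0 disables it.
#' @param line_noise_hz mains frequency of an optional additive sinusoid,
#'   or `NULL` (default) for none.
#' @param bg_amp,beta_amp,gamma_amp spectral amplitude scales of the
#'   background (at 1 Hz), beta and gamma components.
#' @param emg_noise_sd EMG sensor noise floor (sd at rest).
#' @param emg_gain EMG amplitude gain per cm/s of hand speed.
#' @param kin_noise_sd cm; additive position noise on the tracker channels
#'   (0 keeps the kinematics noiseless).
#' @param cue_time seconds; auditory "go" cue time within each recording.
#' @param trial_duration seconds; length of each continuous trial recording.
#' @param seed integer seed making the whole session reproducible.
#'
#' @return An object of class `session_params` (a validated named list).
#' @export
#' @examples
#' p <- session_params(n_trials = 4, seed = 7)
#' s <- simulate_session(p)
session_params <- function(n_trials = 50,
                           reach_duration_mean = 1.2, reach_duration_sd = 0.3,
                           pause_duration_mean = 1.3, pause_duration_sd = 0.4,
                           retrieve_duration_mean = 1.0, retrieve_duration_sd = 0.3,
                           onset_jitter_sd = 0.3,
                           onset_latency_mean = 0.5,
                           reach_amplitude = 40,
                           overshoot_prob = 0,
                           kin_rate = 40,
                           sig_rate = 1200,
                           beta_band = c(12, 30),
                           gamma_band = c(65, 140),
                           erd_depth = 0.6,
                           ers_gain = 0.05,
                           line_noise_hz = NULL,
                           bg_amp = 1,
                           beta_amp = 0.15,
                           gamma_amp = 0.05,
                           emg_noise_sd = 0.01,
                           emg_gain = 0.02,
                           kin_noise_sd = 0,
                           cue_time = 4.5,
                           trial_duration = 15,
                           seed = 1L) {
  p <- list(
    n_trials = as.integer(n_trials),
    reach_duration_mean = reach_duration_mean, reach_duration_sd = reach_duration_sd,
    pause_duration_mean = pause_duration_mean, pause_duration_sd = pause_duration_sd,
    retrieve_duration_mean = retrieve_duration_mean, retrieve_duration_sd = retrieve_duration_sd,
    onset_jitter_sd = onset_jitter_sd,
    onset_latency_mean = onset_latency_mean,
    reach_amplitude = reach_amplitude,
    overshoot_prob = overshoot_prob,
    kin_rate = kin_rate,
    sig_rate = sig_rate,
    beta_band = as.numeric(beta_band),
    gamma_band = as.numeric(gamma_band),
    erd_depth = erd_depth,
    ers_gain = ers_gain,
    line_noise_hz = line_noise_hz,
    bg_amp = bg_amp, beta_amp = beta_amp, gamma_amp = gamma_amp,
    emg_noise_sd = emg_noise_sd, emg_gain = emg_gain,
    kin_noise_sd = kin_noise_sd,
    cue_time = cue_time,
    trial_duration = trial_duration,
    seed = as.integer(seed)
  )
  class(p) <- "session_params"
  validate_session_params(p)
  p
}

validate_session_params <- function(p) {
  stopifnot(inherits(p, "session_params"))
  if (p$n_trials < 1L) stop("n_trials must be >= 1")
  durs <- rbind(
    reach    = c(p$reach_duration_mean, p$reach_duration_sd),
    pause    = c(p$pause_duration_mean, p$pause_duration_sd),
    retrieve = c(p$retrieve_duration_mean, p$retrieve_duration_sd)
  )
  if (any(durs[, 1] <= 0) || any(durs[, 2] < 0))
    stop("phase duration means must be positive and sds non-negative")
  floor3 <- durs[, 1] - 3 * durs[, 2]
  if (any(floor3 <= 0))
    stop("invalid durations: mean - 3*sd must be strictly positive for ",
         paste(rownames(durs)[floor3 <= 0], collapse = ", "),
         " (truncation floor would be non-positive)")
  if (p$onset_jitter_sd < 0) stop("onset_jitter_sd must be >= 0")
  if (p$reach_amplitude <= 0) stop("reach_amplitude must be > 0")
  if (p$overshoot_prob < 0 || p$overshoot_prob > 1)
    stop("overshoot_prob must lie in [0, 1]")
  if (p$kin_rate <= 0 || p$sig_rate <= 0) stop("sampling rates must be > 0")
  nyq <- p$sig_rate / 2
  for (bname in c("beta_band", "gamma_band")) {
    b <- p[[bname]]
    if (length(b) != 2L || b[1] >= b[2] || b[1] <= 0 || b[2] >= nyq)
      stop(bname, " must be a non-empty interval inside (0, sig_rate/2)")
  }
  if (!is.null(p$line_noise_hz) && (p$line_noise_hz <= 0 || p$line_noise_hz >= nyq))
    stop("line_noise_hz must lie in (0, sig_rate/2)")
  if (p$erd_depth <= 0 || p$erd_depth > 1)
    stop("erd_depth must lie in (0, 1]")
  if (p$ers_gain < 0) stop("ers_gain must be >= 0")
  if (any(c(p$bg_amp, p$beta_amp, p$gamma_amp) < 0))
    stop("component amplitudes must be >= 0")
  if (p$onset_latency_mean <= 0) stop("onset_latency_mean must be > 0")
  # movement plus the 4 s pre / 8 s post epoch must fit inside the recording
  if (p$cue_time < 4)
    stop("cue_time must leave >= 4 s of pre-onset recording")
  latest_onset <- p$cue_time + p$onset_latency_mean + 3 * p$onset_jitter_sd + 0.2
  if (latest_onset + 8 > p$trial_duration)
    stop("trial_duration too short for the -4/+8 s epoch around the latest onset")
  invisible(p)
}

#' @export
print.session_params <- function(x, ...) {
  cat("Synthetic session parameters\n")
  cat(sprintf("  trials: %d, seed: %d\n", x$n_trials, x$seed))
  cat(sprintf("  reach %.2f +/- %.2f s, pause %.2f +/- %.2f s, retrieve %.2f +/- %.2f s\n",
              x$reach_duration_mean, x$reach_duration_sd,
              x$pause_duration_mean, x$pause_duration_sd,
              x$retrieve_duration_mean, x$retrieve_duration_sd))
  cat(sprintf("  amplitude %.0f cm, overshoot prob %.2f, onset jitter sd %.2f s\n",
              x$reach_amplitude, x$overshoot_prob, x$onset_jitter_sd))
  cat(sprintf("  rates: kinematics %g Hz, signals %g Hz\n", x$kin_rate, x$sig_rate))
  cat(sprintf("  beta %g-%g Hz (erd_depth %.2f), gamma %g-%g Hz (ers_gain %.3f)\n",
              x$beta_band[1], x$beta_band[2], x$erd_depth,
              x$gamma_band[1], x$gamma_band[2], x$ers_gain))
  invisible(x)
}
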