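#' @section Synthetic sessions:
#' The generator produces, per trial, a continuous recording containing a
#' rest period, an auditory cue, a reach to a target, a hold, and a
#' self-paced retrieval, with per-trial phase durations drawn from truncated
#' normal distributions. Hand kinematics follow a minimum-jerk speed profile
#' per phase; ECoG and EMG channels are synthesized from the kinematics.
#' @name synthetic
NULL

# normal draw truncated (by rejection) to mean +/- 3 sd
trunc_norm1 <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    x <- rnorm(1L, mean, sd)
    if (abs(x - mean) <= 3 * sd) return(x)
  }
}

# minimum-jerk unit displacement and its time derivative on tau in [0,1]
mj_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
mj_vel <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4

# piecewise minimum-jerk profile: segments = list(t0, T, dx)
profile_eval <- function(t, segments) {
  x <- numeric(length(t))
  v <- numeric(length(t))
  for (s in segments) {
    tau <- (t - s$t0) / s$T
    inside <- tau > 0 & tau < 1
    after <- tau >= 1
    x[inside] <- x[inside] + s$dx * mj_pos(tau[inside])
    x[after] <- x[after] + s$dx
    v[inside] <- v[inside] + (s$dx / s$T) * mj_vel(tau[inside])
  }
  list(x = x, v = v)
}

#' Generate one trial's hand-position trace
#'
#' Draws phase durations and cue-to-movement latency for one trial and
#' builds the 3-D hand position at the tracker rate. The X axis (orthogonal
#' to the chest) carries the reach: a minimum-jerk displacement of
#' `reach_amplitude` cm outward, a stationary hold, and a minimum-jerk
#' return. With probability `overshoot_prob` the reach overshoots the
#' target by 15% and adds a corrective reversal. Consumes the current R
#' random-number stream; seed control normally happens in
#' [simulate_session()].
#'
#' @param params a [session_params()] object.
#' @param trial_index trial number (bookkeeping only).
#' @return A `data.frame` with columns `time`, `x`, `y`, `z` (seconds, cm)
#'   at `kin_rate`, with attributes: `speed` (noiseless analytic speed per
#'   sample), `segments` (the piecewise profile), `true_onset` (movement
#'   onset per the operational definition — velocity estimation plus the
#'   0.5 cm/s threshold — applied to the noiseless trace), `phases`
#'   (named vector: `move_start`, `reach_end`, `retrieve_start`,
#'   `retrieve_end`), `durations` (drawn reach/pause/retrieve durations)
#'   and `cue_time`.
#' @export
gen_velocity_profile <- function(params, trial_index = 1L) {
  validate_session_params(params)
  d_reach <- trunc_norm1(params$reach_duration_mean, params$reach_duration_sd)
  d_pause <- trunc_norm1(params$pause_duration_mean, params$pause_duration_sd)
  d_retr  <- trunc_norm1(params$retrieve_duration_mean, params$retrieve_duration_sd)
  latency <- max(0.05, trunc_norm1(params$onset_latency_mean, params$onset_jitter_sd))
  overshoot <- runif(1L) < params$overshoot_prob

  A <- params$reach_amplitude
  t_move <- params$cue_time + latency
  segments <- list()
  if (overshoot) {
    over <- 0.15 * A
    corr_T <- 0.4
    segments[[1]] <- list(t0 = t_move, T = d_reach, dx = A + over)
    segments[[2]] <- list(t0 = t_move + d_reach, T = corr_T, dx = -over)
    reach_end <- t_move + d_reach + corr_T
  } else {
    segments[[1]] <- list(t0 = t_move, T = d_reach, dx = A)
    reach_end <- t_move + d_reach
  }
  retr_start <- reach_end + d_pause
  segments[[length(segments) + 1L]] <- list(t0 = retr_start, T = d_retr, dx = -A)
  retr_end <- retr_start + d_retr

  n <- round(params$trial_duration * params$kin_rate)
  tt <- (seq_len(n) - 1L) / params$kin_rate
  prof <- profile_eval(tt, segments)
  x <- prof$x
  y <- numeric(n)
  z <- numeric(n)
  # ground-truth onset: the study's operational definition (velocity
  # estimation + 0.5 cm/s threshold) applied to the noiseless trace
  kin0 <- data.frame(time = tt, x = x, y = y, z = z)
  onset0 <- detect_onset(compute_velocity(kin0), 0.5, from = params$cue_time)
  if (params$kin_noise_sd > 0) {
    x <- x + rnorm(n, 0, params$kin_noise_sd)
    y <- y + rnorm(n, 0, params$kin_noise_sd)
    z <- z + rnorm(n, 0, params$kin_noise_sd)
  }
  kin <- data.frame(time = tt, x = x, y = y, z = z)
  attr(kin, "speed") <- abs(prof$v)
  attr(kin, "segments") <- segments
  attr(kin, "true_onset") <- onset0
  attr(kin, "phases") <- c(move_start = t_move, reach_end = reach_end,
                           retrieve_start = retr_start, retrieve_end = retr_end)
  attr(kin, "durations") <- c(reach = d_reach, pause = d_pause, retrieve = d_retr)
  attr(kin, "cue_time") <- params$cue_time
  attr(kin, "trial_index") <- as.integer(trial_index)
  kin
}

# band-shaped stationary Gaussian process by spectral synthesis:
# amplitude[k] at frequency k*fs/n, random phases, hermitian inverse FFT
spectral_synth <- function(n, amplitude) {
  nhalf <- length(amplitude)                 # bins 0 .. floor(n/2)
  phases <- runif(nhalf, 0, 2 * pi)
  spec <- complex(modulus = amplitude, argument = phases)
  spec[1] <- 0
  full <- complex(length.out = n)
  full[seq_len(nhalf)] <- spec
  if (n %% 2 == 0) {
    full[nhalf] <- complex(real = amplitude[nhalf] * cos(phases[nhalf]), imaginary = 0)
    if (nhalf > 2) full[n:(nhalf + 1)][seq_len(nhalf - 2)] <- Conj(spec[2:(nhalf - 1)])
  } else {
    full[n:(nhalf + 1)][seq_len(nhalf - 1)] <- Conj(spec[2:nhalf])
  }
  Re(fft(full, inverse = TRUE)) / sqrt(n)
}

# component amplitude shapes shared by the generator and the expected
# (ground-truth) spectrogram template
component_amplitudes <- function(freqs, params) {
  list(
    bg = params$bg_amp / pmax(freqs, 1),
    beta = params$beta_amp *
      as.numeric(freqs >= params$beta_band[1] & freqs <= params$beta_band[2]),
    gamma = params$gamma_amp *
      as.numeric(freqs >= params$gamma_band[1] & freqs <= params$gamma_band[2])
  )
}

# movement envelopes from a speed series (any grid)
erd_envelope <- function(speed, params) 1 - (1 - params$erd_depth) * (speed > 1e-9)
ers_envelope <- function(speed, params) sqrt(1 + params$ers_gain * pmax(speed, 0))

#' Synthesize an ECoG channel from a kinematic trace
#'
#' Builds the simulated cortical signal as a sum of three independent
#' stationary Gaussian processes shaped in the frequency domain — a 1/f
#' broadband background, a beta-band oscillation, and gamma-band noise —
#' plus an optional mains sinusoid. The beta amplitude is multiplied by
#' `erd_depth` whenever the (noiseless) hand speed is non-zero and the
#' gamma power scales as `1 + ers_gain * speed`. Envelopes are computed on
#' the 40 Hz kinematic grid and linearly resampled to the signal rate.
#'
#' @param kin a kinematic trace from [gen_velocity_profile()].
#' @param params a [session_params()] object.
#' @return A `signal_trace`: list with elements `x` (samples), `rate` (Hz)
#'   and `t0` (time of the first sample, seconds).
#' @export
gen_ecog_from_velocity <- function(kin, params) {
  validate_session_params(params)
  if (params$sig_rate < 2 * params$gamma_band[2])
    stop("sig_rate must be at least twice the upper gamma edge")
  speed_kin <- kin_speed(kin)
  dur <- nrow(kin) / params$kin_rate
  n <- round(dur * params$sig_rate)
  t_sig <- (seq_len(n) - 1L) / params$sig_rate
  freqs <- (0:floor(n / 2)) * params$sig_rate / n
  amps <- component_amplitudes(freqs, params)

  env_b <- approx(kin$time, erd_envelope(speed_kin, params), t_sig, rule = 2)$y
  env_g <- approx(kin$time, ers_envelope(speed_kin, params), t_sig, rule = 2)$y

  x <- spectral_synth(n, amps$bg) +
    env_b * spectral_synth(n, amps$beta) +
    env_g * spectral_synth(n, amps$gamma)
  if (!is.null(params$line_noise_hz))
    x <- x + params$bg_amp * sin(2 * pi * params$line_noise_hz * t_sig)
  signal_trace(x, params$sig_rate, t0 = 0)
}

#' Synthesize a surface-EMG channel from a kinematic trace
#'
#' Zero-mean broadband noise whose amplitude is the sensor noise floor at
#' rest plus `emg_gain` per cm/s of hand speed during movement, mirroring a
#' muscle that is silent at rest and bursts with the reach and retrieval.
#'
#' @inheritParams gen_ecog_from_velocity
#' @return A `signal_trace` at `sig_rate`.
#' @export
gen_emg_from_velocity <- function(kin, params) {
  validate_session_params(params)
  speed_kin <- kin_speed(kin)
  dur <- nrow(kin) / params$kin_rate
  n <- round(dur * params$sig_rate)
  t_sig <- (seq_len(n) - 1L) / params$sig_rate
  amp <- approx(kin$time, params$emg_noise_sd + params$emg_gain * speed_kin,
                t_sig, rule = 2)$y
  signal_trace(rnorm(n) * amp, params$sig_rate, t0 = 0)
}

# noiseless speed of a generated trace (attribute), or numeric fallback
kin_speed <- function(kin) {
  s <- attr(kin, "speed")
  if (!is.null(s)) return(s)
  v <- compute_velocity(kin)
  v$speed
}

#' Simulate a full reach-and-retrieve session
#'
#' Generates `params$n_trials` trials (kinematics + ECoG + EMG), each a
#' continuous `trial_duration`-second recording, fully determined by
#' `params$seed`: identical parameters give bit-identical sessions. The
#' caller's random-number state is preserved.
#'
#' @param params a [session_params()] object.
#' @return An `ecog_session`: list with `params` and `trials`; each trial
#'   holds `kin`, `ecog`, `emg`, `true_onset` (seconds, absolute),
#'   `phases` and `durations` ground truth.
#' @export
simulate_session <- function(params) {
  validate_session_params(params)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(params$seed)
  trials <- vector("list", params$n_trials)
  for (i in seq_len(params$n_trials)) {
    kin <- gen_velocity_profile(params, i)
    trials[[i]] <- list(
      kin = kin,
      ecog = gen_ecog_from_velocity(kin, params),
      emg = gen_emg_from_velocity(kin, params),
      true_onset = attr(kin, "true_onset"),
      phases = attr(kin, "phases"),
      durations = attr(kin, "durations")
    )
  }
  structure(list(params = params, trials = trials), class = "ecog_session")
}

#' @export
print.ecog_session <- function(x, ...) {
  cat(sprintf("Synthetic ECoG session: %d trials, seed %d\n",
              length(x$trials), x$params$seed))
  d <- t(vapply(x$trials, function(tr) tr$durations, numeric(3)))
  cat(sprintf("  reach %.2f +/- %.2f s, pause %.2f +/- %.2f s, retrieve %.2f +/- %.2f s (realized)\n",
              mean(d[, 1]), sd(d[, 1]), mean(d[, 2]), sd(d[, 2]),
              mean(d[, 3]), sd(d[, 3])))
  invisible(x)
}

#' Expected normalized spectrogram of a synthetic trial
#'
#' The analytic percent-change-from-baseline spectrogram implied by the
#' generator model for one trial's (noiseless) kinematics: at frame time
#' `t` with hand speed `s(t)`, expected power is the sum of the component
#' spectral densities with the beta density scaled by the squared
#' desynchronization envelope and the gamma density by `1 + ers_gain *
#' s(t)`. Serves as the ground-truth template that trial averages are
#' compared against in simulation studies; window-smearing of the
#' short-time Fourier estimator is not modelled, and the optional mains
#' line is ignored.
#'
#' @param trial one element of `simulate_session(...)$trials`.
#' @param params the session's [session_params()].
#' @param frame_times frame-center times, seconds relative to `onset`.
#' @param freqs frequency-bin centers, Hz.
#' @param onset absolute onset time the frames are referenced to; defaults
#'   to the trial's `true_onset`.
#' @return A normalized spectrogram (`ecog_tfr`, percent change).
#' @export
ground_truth_template <- function(trial, params, frame_times, freqs,
                                  onset = trial$true_onset) {
  segs <- attr(trial$kin, "segments")
  speed <- abs(profile_eval(frame_times + onset, segs)$v)
  amps <- component_amplitudes(freqs, params)
  s_bg <- amps$bg^2; s_be <- amps$beta^2; s_ga <- amps$gamma^2
  rest <- s_bg + s_be + s_ga
  eb2 <- erd_envelope(speed, params)^2
  eg2 <- ers_envelope(speed, params)^2
  vals <- 100 * (outer(eb2 - 1, s_be) + outer(eg2 - 1, s_ga)) /
    matrix(rest, nrow = length(frame_times), ncol = length(freqs), byrow = TRUE)
  new_tfr(vals, frame_times, freqs, normalized = TRUE)
}
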