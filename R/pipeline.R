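#' Analysis configuration
#'
#' Bundles every analysis parameter of the pipeline with the conventional
#' defaults: 100 ms Hamming window advanced by 10 ms, percent-change
#' baseline over 1-2 s before onset, 0.5 cm/s onset threshold, a -4/+8 s
#' epoch, beta 12-30 Hz, gamma 65-140 Hz, and 65-90 Hz for neural
#' (gamma-derived) registration paths.
#'
#' @param window_ms,hop_ms spectrogram framing, ms.
#' @param baseline_window seconds relative to onset.
#' @param onset_threshold cm/s.
#' @param epoch_window seconds relative to onset.
#' @param beta_band,gamma_band,gamma_warp_band Hz intervals.
#' @param movement_window seconds; window used by the band-change test.
#' @param max_analysis_freq Hz; spectrograms are cropped here before
#'   cross-trial statistics (well above the gamma band, keeps the
#'   permutation evaluation light).
#' @param reference `"medoid"` or a trial index.
#' @param warp_on `"vx"` (signed X-velocity, default) or `"speed"`.
#' @param seed integer; seeds any simulation embedded in a run.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(window_ms = 100, hop_ms = 10,
                       baseline_window = c(-2, -1),
                       onset_threshold = 0.5,
                       epoch_window = c(-4, 8),
                       beta_band = c(12, 30),
                       gamma_band = c(65, 140),
                       gamma_warp_band = c(65, 90),
                       movement_window = c(0, 1),
                       max_analysis_freq = 200,
                       reference = "medoid",
                       warp_on = c("vx", "speed"),
                       seed = 1L) {
  cfg <- list(window_ms = window_ms, hop_ms = hop_ms,
              baseline_window = baseline_window,
              onset_threshold = onset_threshold,
              epoch_window = epoch_window,
              beta_band = as.numeric(beta_band),
              gamma_band = as.numeric(gamma_band),
              gamma_warp_band = as.numeric(gamma_warp_band),
              movement_window = movement_window,
              max_analysis_freq = max_analysis_freq,
              reference = reference,
              warp_on = match.arg(warp_on),
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg, sig_rate = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$window_ms <= 0 || cfg$hop_ms <= 0 || cfg$hop_ms > cfg$window_ms)
    stop("need 0 < hop_ms <= window_ms")
  if (cfg$onset_threshold <= 0) stop("onset_threshold must be > 0")
  win_ok <- function(w) length(w) == 2L && w[1] < w[2]
  if (!win_ok(cfg$baseline_window) || !win_ok(cfg$epoch_window) ||
      !win_ok(cfg$movement_window))
    stop("windows must be increasing two-element intervals")
  if (cfg$baseline_window[1] < cfg$epoch_window[1] ||
      cfg$baseline_window[2] > cfg$epoch_window[2])
    stop("baseline window must lie inside the epoch window")
  for (b in list(cfg$beta_band, cfg$gamma_band, cfg$gamma_warp_band))
    if (length(b) != 2L || b[1] >= b[2] || b[1] < 0)
      stop("frequency bands must be increasing non-negative intervals")
  if (!is.null(sig_rate)) {
    nyq <- sig_rate / 2
    if (cfg$gamma_band[2] >= nyq || cfg$beta_band[2] >= nyq ||
        cfg$gamma_warp_band[2] >= nyq)
      stop("analysis band exceeds the Nyquist frequency (", nyq, " Hz)")
    if (cfg$max_analysis_freq >= nyq)
      stop("max_analysis_freq exceeds the Nyquist frequency")
  }
  invisible(cfg)
}

#' Epoch and transform every trial of a session
#'
#' Shared front half of the pipeline: velocity computation, cue-gated
#' onset detection, epoching, spectrogram + normalization, and velocity
#' resampled onto the spectrogram frame grid.
#'
#' @param session an `ecog_session` (or the result of [read_session()]
#'   passed through [session_from_files()]).
#' @param config a [run_config()].
#' @return List of per-trial records: `epoch`, `spec` (normalized,
#'   cropped), `vel_frames` (series used for warping), `speed_frames`,
#'   `onset`, `emg` epoch.
#' @export
prepare_trials <- function(session, config = run_config()) {
  validate_run_config(config, sig_rate = session$trials[[1L]]$ecog$rate)
  lapply(seq_along(session$trials), function(i) {
    tr <- session$trials[[i]]
    vel <- compute_velocity(tr$kin)
    onset <- detect_onset(vel, threshold = config$onset_threshold,
                          from = attr(tr$kin, "cue_time"))
    ep <- extract_epoch(list(ecog = tr$ecog, emg = tr$emg), tr$kin, onset,
                        window = config$epoch_window, id = i)
    spec <- compute_spectrogram(ep$signals$ecog, window_ms = config$window_ms,
                                hop_ms = config$hop_ms,
                                fmax = config$max_analysis_freq)
    nspec <- baseline_normalize(spec, config$baseline_window)
    vel_ep <- compute_velocity(ep$kin)
    velf <- resample_to_frames(vel_ep, nspec$times)
    list(epoch = ep, spec = nspec,
         vel_frames = if (config$warp_on == "vx") velf$vx else velf$speed,
         speed_frames = velf$speed, onset = onset, emg = ep$signals$emg)
  })
}

#' Run the full time-warped averaging pipeline
#'
#' Epochs every trial around detected movement onset, computes normalized
#' spectrograms, selects a reference trial, forms the conventional and the
#' time-warped averages, tests the beta/gamma band changes, runs the
#' permutation evaluation of warping efficacy, and summarizes the
#' kinematic warp error. Deterministic given the session and config.
#'
#' @param session an `ecog_session`.
#' @param config a [run_config()].
#' @param evaluate run the (quadratic-cost) permutation evaluation.
#' @return A report list of class `warp_report`: `config`, `onsets`,
#'   `reference`, `conventional`, `warped` (both `ecog_tfr`), `emg_onset`,
#'   `emg_warped`, `ks_beta`, `ks_gamma`, `evaluation` (a `warp_eval` or
#'   `NULL`), `kinematic_errors`.
#' @export
run_pipeline <- function(session, config = run_config(), evaluate = TRUE) {
  trials <- prepare_trials(session, config)
  specs <- lapply(trials, `[[`, "spec")
  vels <- lapply(trials, `[[`, "vel_frames")
  reference <- if (identical(config$reference, "medoid"))
    select_reference(vels, "medoid") else
    select_reference(vels, "index", index = config$reference)
  conventional <- conventional_average(specs)
  warped <- warped_average(specs, vels, reference)
  emg_signals <- lapply(trials, `[[`, "emg")
  report <- list(
    config = config,
    onsets = vapply(trials, `[[`, numeric(1L), "onset"),
    reference = reference,
    conventional = conventional,
    warped = warped,
    emg_onset = average_rectified_emg(emg_signals, "onset",
                                      window_ms = config$window_ms,
                                      hop_ms = config$hop_ms),
    emg_warped = average_rectified_emg(emg_signals, "paths",
                                       velocities = vels,
                                       reference = reference,
                                       window_ms = config$window_ms,
                                       hop_ms = config$hop_ms),
    ks_beta = band_change_ks_test(specs, config$beta_band,
                                  config$movement_window,
                                  config$baseline_window),
    ks_gamma = band_change_ks_test(specs, config$gamma_band,
                                   config$movement_window,
                                   config$baseline_window),
    evaluation = if (evaluate) permutation_evaluation(specs, vels) else NULL,
    kinematic_errors = kinematic_warp_error_report(vels)
  )
  class(report) <- "warp_report"
  report
}

#' @export
print.warp_report <- function(x, ...) {
  cat(sprintf("Time-warped averaging report: %d trials, reference trial %d\n",
              length(x$onsets), x$reference))
  cat(sprintf("  beta band change:  direction %+d, KS p = %.3g\n",
              x$ks_beta$direction, x$ks_beta$p_value))
  cat(sprintf("  gamma band change: direction %+d, KS p = %.3g\n",
              x$ks_gamma$direction, x$ks_gamma$p_value))
  if (!is.null(x$evaluation))
    cat(sprintf("  warping evaluation: t = %.3f, p = %.3g\n",
                x$evaluation$t_statistic, x$evaluation$p_value))
  cat(sprintf("  median kinematic warp error: %.4g cm/s\n",
              x$kinematic_errors$median_error))
  invisible(x)
}

#' Write the scalar part of a report to JSON
#'
#' Serializes the configuration echo, onsets, test results and error
#' distributions (the averaged spectrogram matrices are omitted; persist
#' those with your own writer if needed).
#'
#' @param report a `warp_report`.
#' @param file destination file.
#' @export
write_report <- function(report, file) {
  ev <- report$evaluation
  jsonlite::write_json(list(
    config = unclass(report$config),
    onsets = report$onsets,
    reference = report$reference,
    ks_beta = report$ks_beta[c("p_value", "statistic", "direction")],
    ks_gamma = report$ks_gamma[c("p_value", "statistic", "direction")],
    evaluation = if (is.null(ev)) NULL else
      list(t_statistic = ev$t_statistic, p_value = ev$p_value,
           warped_errors = ev$warped_errors,
           unwarped_errors = ev$unwarped_errors),
    kinematic_median_error = report$kinematic_errors$median_error
  ), file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Assemble a session object from files read back from disk
#'
#' Wraps the output of [read_session()] into the `ecog_session` shape the
#' pipeline consumes (ground-truth fields are taken from the manifest when
#' present).
#'
#' @param loaded result of [read_session()].
#' @return An `ecog_session`.
#' @export
session_from_files <- function(loaded) {
  n <- length(loaded$trials)
  cue <- loaded$manifest$params$cue_time
  trials <- lapply(seq_len(n), function(i) {
    tr <- loaded$trials[[i]]
    if (!is.null(cue)) attr(tr$kin, "cue_time") <- cue
    gt <- loaded$manifest$ground_truth[[i]]
    list(kin = tr$kin, ecog = tr$ecog, emg = tr$emg,
         true_onset = gt$true_onset,
         phases = unlist(gt$phases), durations = unlist(gt$durations))
  })
  structure(list(params = loaded$manifest$params, trials = trials),
            class = "ecog_session")
}
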