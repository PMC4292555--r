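#' Choose the reference ("gold standard") trial
#'
#' All other trials are warped onto the reference before averaging. The
#' `medoid` strategy picks the trial minimizing the summed normalized DTW
#' cost to all others (a robust central exemplar); `index` fixes it by
#' hand; `permute_all` returns every trial in turn, the scheme used by the
#' permutation evaluation.
#'
#' @param velocities list of numeric frame-grid velocity series, one per
#'   trial.
#' @param strategy `"medoid"`, `"index"` or `"permute_all"`.
#' @param index trial number when `strategy = "index"`.
#' @return Integer vector of reference trial id(s).
#' @export
select_reference <- function(velocities, strategy = c("medoid", "index", "permute_all"),
                             index = NULL) {
  strategy <- match.arg(strategy)
  n <- length(velocities)
  if (n < 2L) stop("need at least 2 trials to choose a reference")
  switch(strategy,
    index = {
      if (is.null(index) || index < 1L || index > n)
        stop("strategy 'index' needs a valid trial index")
      as.integer(index)
    },
    permute_all = seq_len(n),
    medoid = {
      costs <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        nc <- dtw_path(velocities[[i]], velocities[[j]])$normalized_cost
        costs[i, j] <- nc
        costs[j, i] <- nc             # symmetric step weights => symmetric cost
      }
      which.min(rowSums(costs))
    }
  )
}

#' Conventional (onset-aligned) trial average
#'
#' Cell-wise arithmetic mean of normalized spectrograms aligned only at
#' movement onset, with no time transformation: the standard way trial
#' spectrograms are averaged, and the baseline the time-warped average is
#' compared against.
#'
#' @param specs list of `ecog_tfr` objects on identical grids.
#' @return An `ecog_tfr`, the cell-wise mean.
#' @export
conventional_average <- function(specs) {
  stopifnot(length(specs) >= 1L)
  for (s in specs[-1L]) check_same_grid(specs[[1L]], s)
  avg <- Reduce(`+`, lapply(specs, function(s) s$power)) / length(specs)
  new_tfr(avg, specs[[1L]]$times, specs[[1L]]$freqs,
          normalized = specs[[1L]]$normalized)
}

#' Time-warped trial average
#'
#' For each non-reference trial, a registration path is computed by
#' warping the trial's velocity profile onto the reference trial's
#' velocity profile; the path is then applied to the trial's normalized
#' spectrogram, and the registered spectrograms (including the untouched
#' reference) are averaged cell-wise. After warping, each time point of
#' every trial corresponds to the same arm velocity, so movement-locked
#' spectral components line up instead of smearing.
#'
#' @param specs list of `ecog_tfr` objects on identical grids.
#' @param velocities list of numeric frame-grid velocity series (signed
#'   X-velocity by convention), same length as `specs`.
#' @param reference reference trial index.
#' @return An `ecog_tfr` on the reference trial's frame grid.
#' @export
warped_average <- function(specs, velocities, reference) {
  n <- length(specs)
  if (length(velocities) != n) {
    missing <- setdiff(seq_len(n), seq_len(length(velocities)))
    stop("missing kinematics for trial(s) ", paste(missing, collapse = ", "))
  }
  if (any(vapply(velocities, is.null, logical(1L))))
    stop("missing kinematics for trial(s) ",
         paste(which(vapply(velocities, is.null, logical(1L))), collapse = ", "))
  stopifnot(reference >= 1L, reference <= n)
  for (s in specs[-1L]) check_same_grid(specs[[1L]], s)
  acc <- specs[[reference]]$power
  for (q in seq_len(n)[-reference]) {
    path <- dtw_path(velocities[[reference]], velocities[[q]])
    acc <- acc + warp_spectrogram(specs[[q]], path,
                                  ref_times = specs[[reference]]$times)$power
  }
  new_tfr(acc / n, specs[[reference]]$times, specs[[reference]]$freqs,
          normalized = specs[[reference]]$normalized)
}

#' Average of rectified EMG across trials
#'
#' Rectifies each trial's EMG, aggregates it onto the spectrogram frame
#' grid (mean absolute value per analysis window), optionally warps each
#' frame series onto a reference trial via kinematic registration paths,
#' and averages across trials. With onset alignment only, the average
#' decays toward the end of the movement as trials desynchronize; warping
#' keeps the burst envelope sharp.
#'
#' @param emg_signals list of `signal_trace` epochs.
#' @param alignment `"onset"` (plain average) or `"paths"` (warp first).
#' @param velocities,reference as in [warped_average()]; required for
#'   `alignment = "paths"`.
#' @param window_ms,hop_ms framing parameters matching the spectrograms.
#' @return A list with `times` (frame centers) and `mean` (average
#'   rectified EMG per frame).
#' @export
average_rectified_emg <- function(emg_signals, alignment = c("onset", "paths"),
                                  velocities = NULL, reference = NULL,
                                  window_ms = 100, hop_ms = 10) {
  alignment <- match.arg(alignment)
  framed <- lapply(emg_signals, function(sig) {
    rx <- abs(sig$x)
    fs <- sig$rate
    win <- round(window_ms / 1000 * fs); hop <- round(hop_ms / 1000 * fs)
    n <- length(rx)
    n_frames <- (n - win) %/% hop + 1L
    starts <- (seq_len(n_frames) - 1L) * hop
    idx <- outer(seq_len(win), starts, `+`)
    vals <- colMeans(matrix(rx[idx], nrow = win))
    list(times = sig$t0 + (starts + (win - 1) / 2) / fs, vals = vals)
  })
  n_frames <- length(framed[[1L]]$vals)
  if (any(vapply(framed, function(f) length(f$vals), integer(1L)) != n_frames))
    stop("EMG epochs have mismatched lengths")
  mats <- vapply(framed, `[[`, numeric(n_frames), "vals")
  if (alignment == "paths") {
    if (is.null(velocities) || is.null(reference))
      stop("alignment = 'paths' needs velocities and a reference trial")
    for (q in seq_along(framed)[-reference]) {
      path <- dtw_path(velocities[[reference]], velocities[[q]])
      mats[, q] <- warp_series(mats[, q], path)
    }
  }
  list(times = framed[[if (alignment == "paths") reference else 1L]]$times,
       mean = rowMeans(mats))
}

#' Kolmogorov-Smirnov test of movement-related band-power change
#'
#' For each trial, the mean normalized band value is computed inside a
#' movement window and inside a baseline window; the two across-trial
#' samples are compared with a two-sample Kolmogorov-Smirnov test. The
#' reported direction is the sign of the mean movement-minus-baseline
#' difference (positive for gamma synchronization, negative for beta
#' desynchronization).
#'
#' @param specs list of normalized `ecog_tfr` objects.
#' @param band Hz interval.
#' @param movement_window,baseline_window two-element windows, seconds
#'   relative to onset (half-open).
#' @return List with `p_value`, `statistic`, `direction` (+1/-1/0),
#'   `movement` and `baseline` per-trial samples.
#' @export
band_change_ks_test <- function(specs, band, movement_window = c(0, 1),
                                baseline_window = c(-2, -1)) {
  if (length(specs) < 2L) stop("need at least 2 trials for the KS test")
  window_mean <- function(spec, win) {
    keep <- spec$times >= win[1] & spec$times < win[2]
    if (!any(keep)) stop("window [", win[1], ", ", win[2],
                         ") s contains no spectrogram frames")
    mean(band_power(spec, band)[keep])
  }
  mv <- vapply(specs, window_mean, numeric(1L), win = movement_window)
  bl <- vapply(specs, window_mean, numeric(1L), win = baseline_window)
  ks <- suppressWarnings(ks.test(mv, bl))
  list(p_value = unname(ks$p.value), statistic = unname(ks$statistic),
       direction = sign(mean(mv) - mean(bl)), movement = mv, baseline = bl)
}

#' RMS difference between two spectrograms
#'
#' Root-mean-square difference over all time-frequency cells (normalized
#' by cell count so values are comparable across grid sizes).
#'
#' @param a,b `ecog_tfr` objects on identical grids.
#' @return Non-negative scalar.
#' @export
rms_error <- function(a, b) {
  check_same_grid(a, b)
  sqrt(mean((a$power - b$power)^2))
}

#' Permutation evaluation of warping efficacy
#'
#' The reference trial is permuted across all trials: for every ordered
#' pair (reference `r`, query `q != r`) the RMS error between the
#' reference spectrogram and the query spectrogram is computed twice —
#' after warping the query onto the reference via the kinematic
#' registration path, and unwarped at plain onset alignment (the null
#' set). Both error samples are log-transformed (they are approximately
#' log-normal) and compared with a one-sided Welch t-test of warped <
#' unwarped; a small p-value means warping genuinely reduced cross-trial
#' spectrogram variability.
#'
#' @param specs list of normalized `ecog_tfr` objects (>= 3 trials).
#' @param velocities list of frame-grid velocity series.
#' @param identity_paths force identity (no-op) paths; the calibration
#'   control in which no improvement should be found.
#' @param paired use a paired t-test over the common pair set instead of
#'   the two-distribution unpaired form.
#' @return An object of class `warp_eval`: `warped_errors`,
#'   `unwarped_errors`, `log_warped`, `log_unwarped`, `t_statistic`,
#'   `p_value`, `excluded_pairs` (pairs with zero error, unusable in the
#'   log domain), `n_trials`.
#' @export
permutation_evaluation <- function(specs, velocities, identity_paths = FALSE,
                                   paired = FALSE) {
  n <- length(specs)
  if (n < 3L) stop("need at least 3 trials for the permutation evaluation")
  for (s in specs[-1L]) check_same_grid(specs[[1L]], s)
  warped <- numeric(0); unwarped <- numeric(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (r in seq_len(n)) {
    for (q in seq_len(n)[-r]) {
      path <- if (identity_paths) identity_path(nrow(specs[[q]]$power)) else
        dtw_path(velocities[[r]], velocities[[q]])
      w <- rms_error(specs[[r]],
                     warp_spectrogram(specs[[q]], path,
                                      ref_times = specs[[r]]$times))
      u <- rms_error(specs[[r]], specs[[q]])
      warped <- c(warped, w); unwarped <- c(unwarped, u)
      pairs <- rbind(pairs, c(r, q))
    }
  }
  zero <- warped <= 0 | unwarped <= 0
  if (all(zero))
    stop("degenerate error distributions: all pairwise errors are zero ",
         "(identical trials?)")
  excluded <- pairs[zero, , drop = FALSE]
  lw <- log(warped[!zero]); lu <- log(unwarped[!zero])
  tt <- t.test(lw, lu, alternative = "less", paired = paired,
               var.equal = FALSE)
  structure(list(warped_errors = warped, unwarped_errors = unwarped,
                 log_warped = lw, log_unwarped = lu,
                 t_statistic = unname(tt$statistic),
                 p_value = unname(tt$p.value),
                 excluded_pairs = excluded, n_trials = n),
            class = "warp_eval")
}

#' @export
print.warp_eval <- function(x, ...) {
  cat(sprintf("Permutation evaluation over %d trials (%d ordered pairs)\n",
              x$n_trials, length(x$warped_errors)))
  cat(sprintf("  median RMS error: warped %.4g, unwarped %.4g\n",
              median(x$warped_errors), median(x$unwarped_errors)))
  cat(sprintf("  one-sided log-domain t-test (warped < unwarped): t = %.3f, p = %.3g\n",
              x$t_statistic, x$p_value))
  if (nrow(x$excluded_pairs) > 0L)
    cat(sprintf("  %d zero-error pair(s) excluded from the log domain\n",
                nrow(x$excluded_pairs)))
  invisible(x)
}

#' Kinematic warp-error report
#'
#' RMS error from warping the kinematic trajectories alone: for every
#' ordered pair, the query velocity is warped onto the reference velocity
#' and the residual RMS is recorded. Sessions whose kinematic warp error
#' is large (e.g., frequent target overshoots introducing extra velocity
#' reversals) are sessions where kinematics-guided spectrogram warping is
#' unreliable, so this summary serves as a per-session quality flag.
#'
#' @param velocities list of frame-grid velocity series (>= 2 trials).
#' @return List with `pair_errors` (data.frame `reference`, `query`,
#'   `rms`), `median_error`, `mean_error`.
#' @export
kinematic_warp_error_report <- function(velocities) {
  n <- length(velocities)
  if (n < 2L) stop("need at least 2 trials")
  ref <- integer(0); qry <- integer(0); err <- numeric(0)
  for (r in seq_len(n)) {
    for (q in seq_len(n)[-r]) {
      path <- dtw_path(velocities[[r]], velocities[[q]])
      w <- warp_series(velocities[[q]], path)
      ref <- c(ref, r); qry <- c(qry, q)
      err <- c(err, sqrt(mean((velocities[[r]] - w)^2)))
    }
  }
  list(pair_errors = data.frame(reference = ref, query = qry, rms = err),
       median_error = median(err), mean_error = mean(err))
}
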