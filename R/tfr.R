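# internal constructor shared by the STFT, the warping code and the
# synthetic ground-truth template
new_tfr <- function(power, times, freqs, normalized = FALSE, baseline = NULL,
                    baseline_window = NULL) {
  stopifnot(is.matrix(power), nrow(power) == length(times),
            ncol(power) == length(freqs))
  structure(list(power = power, times = as.numeric(times),
                 freqs = as.numeric(freqs), normalized = normalized,
                 baseline = baseline, baseline_window = baseline_window),
            class = "ecog_tfr")
}

#' @export
print.ecog_tfr <- function(x, ...) {
  cat(sprintf("%s: %d frames x %d bins, t = [%.3f, %.3f] s, f = [%g, %g] Hz\n",
              if (x$normalized) "Normalized spectrogram (% change)" else "Spectrogram (power)",
              nrow(x$power), ncol(x$power),
              x$times[1L], x$times[length(x$times)],
              x$freqs[1L], x$freqs[length(x$freqs)]))
  invisible(x)
}

#' Plot a spectrogram
#'
#' Image panel of power (or percent change) over time and frequency, the
#' usual rendering of averaged movement-locked spectrograms.
#'
#' @param x an `ecog_tfr`.
#' @param fmax upper frequency limit of the panel, Hz.
#' @param ... passed to [graphics::image()].
#' @export
plot.ecog_tfr <- function(x, fmax = 200, ...) {
  keep <- x$freqs <= fmax
  z <- x$power[, keep, drop = FALSE]
  graphics::image(x$times, x$freqs[keep], z, xlab = "time from onset (s)",
                  ylab = "frequency (Hz)",
                  main = if (x$normalized) "% change from baseline" else "power",
                  ...)
  invisible(x)
}

#' Short-time Fourier spectrogram
#'
#' Hamming-windowed short-time Fourier transform: the signal is windowed in
#' 100 ms segments, each segment zero-padded to one second of samples so
#' the bin spacing is exactly 1 Hz, and the window is advanced by 10 ms.
#' Power is the squared magnitude of the transform; each frame is stamped
#' at its window center. Edge positions where a full window does not fit
#' are dropped, not padded.
#'
#' @param signal a `signal_trace`.
#' @param window_ms analysis window length, ms (default 100).
#' @param hop_ms hop between successive frames, ms (default 10).
#' @param freq_resolution_hz frequency-bin spacing obtained by zero
#'   padding, Hz (default 1).
#' @param fmax optional upper frequency cut applied after the transform
#'   (keeps bins `<= fmax`); `NULL` keeps 0..Nyquist.
#' @return An `ecog_tfr` with `power[frame, freq]`.
#' @export
compute_spectrogram <- function(signal, window_ms = 100, hop_ms = 10,
                                freq_resolution_hz = 1, fmax = NULL) {
  stopifnot(inherits(signal, "signal_trace"))
  fs <- signal$rate
  win <- round(window_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  if (win < 2L || hop < 1L) stop("window/hop too short for the sampling rate")
  n <- length(signal$x)
  if (n < win) stop("signal shorter than one analysis window")
  nfft <- round(fs / freq_resolution_hz)
  if (nfft < win) stop("freq_resolution_hz too coarse for the window length")
  n_frames <- (n - win) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))
  seg <- matrix(0, nrow = nfft, ncol = n_frames)
  idx <- outer(seq_len(win), starts, `+`)          # 1-based sample indices
  seg[seq_len(win), ] <- signal$x[idx] * ham
  spec <- stats::mvfft(seg)
  nbin <- nfft %/% 2L + 1L
  power <- t(Mod(spec[seq_len(nbin), , drop = FALSE])^2)
  freqs <- (seq_len(nbin) - 1L) * freq_resolution_hz
  times <- signal$t0 + (starts + (win - 1) / 2) / fs
  out <- new_tfr(power, times, freqs)
  if (!is.null(fmax)) out <- crop_spectrogram(out, fmax)
  out
}

#' Restrict a spectrogram to frequencies below a limit
#'
#' @param spec an `ecog_tfr`.
#' @param fmax keep bins with center frequency `<= fmax` Hz.
#' @return The cropped `ecog_tfr`.
#' @export
crop_spectrogram <- function(spec, fmax) {
  keep <- spec$freqs <= fmax + 1e-9
  if (!any(keep)) stop("no frequency bins at or below ", fmax, " Hz")
  new_tfr(spec$power[, keep, drop = FALSE], spec$times, spec$freqs[keep],
          normalized = spec$normalized,
          baseline = if (!is.null(spec$baseline)) spec$baseline[keep] else NULL,
          baseline_window = spec$baseline_window)
}

#' Baseline-normalize a spectrogram to percent change (ERD/ERS)
#'
#' For each frequency the baseline power `B(f)` is the mean power over the
#' frames whose centers fall in `baseline_window` (by convention 1-2 s
#' before movement onset); values become
#' `100 * (P(f,t) - B(f)) / B(f)`, i.e., percent change from rest, the
#' conventional event-related (de)synchronization measure.
#'
#' @param spec an `ecog_tfr` of raw power.
#' @param baseline_window two-element window, seconds relative to onset
#'   (default `c(-2, -1)`, half-open).
#' @return A normalized `ecog_tfr` carrying `baseline` (the per-frequency
#'   `B(f)`) so normalization can be inverted.
#' @export
baseline_normalize <- function(spec, baseline_window = c(-2, -1)) {
  stopifnot(inherits(spec, "ecog_tfr"))
  if (spec$normalized) stop("spectrogram is already normalized")
  inb <- spec$times >= baseline_window[1] & spec$times < baseline_window[2]
  if (!any(inb)) stop("baseline window contains no spectrogram frames")
  B <- colMeans(spec$power[inb, , drop = FALSE])
  if (any(B <= 0)) {
    bad <- spec$freqs[which(B <= 0)]
    stop("degenerate baseline: zero power at frequency ",
         paste(bad[seq_len(min(5, length(bad)))], collapse = ", "), " Hz")
  }
  vals <- 100 * sweep(sweep(spec$power, 2L, B, `-`), 2L, B, `/`)
  new_tfr(vals, spec$times, spec$freqs, normalized = TRUE, baseline = B,
          baseline_window = baseline_window)
}

#' Invert a percent-change normalization
#'
#' Reconstructs raw power from a normalized spectrogram and its stored
#' per-frequency baseline.
#'
#' @param spec a normalized `ecog_tfr` with a `baseline` component.
#' @return An `ecog_tfr` of raw power.
#' @export
baseline_restore <- function(spec) {
  if (!spec$normalized || is.null(spec$baseline))
    stop("spectrogram is not normalized or carries no baseline")
  P <- sweep(sweep(spec$power / 100, 2L, spec$baseline, `*`), 2L,
             spec$baseline, `+`)
  new_tfr(P, spec$times, spec$freqs)
}

#' Band-power time series
#'
#' Per-frame mean over the frequency bins whose centers lie inside the
#' band (inclusive). Works on raw or normalized spectrograms; the beta
#' (12-30 Hz) and gamma (65-140 Hz) bands are the conventional choices for
#' movement-related activity.
#'
#' @param spec an `ecog_tfr`.
#' @param band two-element Hz interval.
#' @return Numeric vector, one value per frame (named attribute-free).
#' @export
band_power <- function(spec, band) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  keep <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(keep)) stop("band [", band[1], ", ", band[2],
                       "] Hz contains no frequency bins")
  rowMeans(spec$power[, keep, drop = FALSE])
}

# grids must agree for cell-wise operations across trials
check_same_grid <- function(a, b, what = "spectrograms") {
  if (nrow(a$power) != nrow(b$power) || ncol(a$power) != ncol(b$power))
    stop(what, " have mismatched grids (",
         nrow(a$power), "x", ncol(a$power), " vs ",
         nrow(b$power), "x", ncol(b$power), ")")
  if (max(abs(a$freqs - b$freqs)) > 1e-6)
    stop(what, " have mismatched frequency axes")
  dt <- median(diff(a$times))
  if (max(abs(a$times - b$times)) > dt / 2)
    stop(what, " have mismatched frame-time axes")
  invisible(TRUE)
}
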