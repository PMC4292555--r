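#' Time-registration path between two series by dynamic time warping
#'
#' Aligns a query series onto a reference series with the symmetric step
#' pattern (step weights 1, 2, 1 for reference-advance, diagonal,
#' query-advance) and no slope constraint, using the absolute difference
#' (1-D Euclidean distance) as the local cost. The recursion is
#' `g(i,j) = min(g(i-1,j) + d, g(i-1,j-1) + 2d, g(i,j-1) + d)` with
#' `g(1,1) = 2 d(1,1)`; the optimal path is recovered by backtracking with
#' ties broken deterministically in favour of the diagonal step, then the
#' reference-advance step (this matters on near-zero velocity pauses where
#' many cells tie). Both series must live on a common grid spacing
#' (typically signed X-velocity resampled to the 10 ms spectrogram frame
#' grid).
#'
#' @param reference,query numeric series (no `NA`/`Inf`).
#' @return A `registration_path`: list with integer vectors `ref_idx`,
#'   `query_idx` (1-based, first pair (1,1), last (N,M), steps in
#'   \{(1,0),(0,1),(1,1)\}), `total_cost`, and
#'   `normalized_cost = total_cost / (N + M)`.
#' @export
#' @examples
#' p <- dtw_path(c(0, 1, 2), c(0, 2))
#' p$total_cost           # 1
#' cbind(p$ref_idx, p$query_idx)
dtw_path <- function(reference, query) {
  if (length(reference) == 0L || length(query) == 0L)
    stop("empty input series")
  if (!all(is.finite(reference)) || !all(is.finite(query)))
    stop("non-finite values in input series")
  res <- .dtw_core(as.numeric(reference), as.numeric(query))
  res$n_ref <- length(reference)
  res$n_query <- length(query)
  class(res) <- "registration_path"
  res
}

#' Identity registration path
#'
#' The diagonal path that maps every frame to itself; useful as the
#' no-warping control in calibration experiments.
#'
#' @param n series length.
#' @return A `registration_path` with zero cost.
#' @export
identity_path <- function(n) {
  structure(list(ref_idx = seq_len(n), query_idx = seq_len(n),
                 total_cost = 0, normalized_cost = 0,
                 n_ref = n, n_query = n),
            class = "registration_path")
}

#' @export
print.registration_path <- function(x, ...) {
  cat(sprintf("registration_path: %d pairs, %d ref x %d query frames, cost %.4g (normalized %.4g)\n",
              length(x$ref_idx), x$n_ref, x$n_query,
              x$total_cost, x$normalized_cost))
  invisible(x)
}

check_path <- function(path) {
  stopifnot(inherits(path, "registration_path"))
  r <- path$ref_idx; q <- path$query_idx
  if (r[1L] != 1L || q[1L] != 1L ||
      r[length(r)] != path$n_ref || q[length(q)] != path$n_query)
    stop("registration path does not span both series end-to-end")
  dr <- diff(r); dq <- diff(q)
  if (any(dr < 0) || any(dq < 0) || any(dr > 1) || any(dq > 1) ||
      any(dr + dq == 0))
    stop("registration path steps must be (1,0), (0,1) or (1,1)")
  invisible(TRUE)
}

#' Apply a registration path to a series
#'
#' Re-expresses a query series on the reference time base: output frame
#' `i` is the arithmetic mean of the query values matched to reference
#' frame `i` by the path.
#'
#' @param query numeric series of length `path$n_query`.
#' @param path a `registration_path`.
#' @return Numeric series of length `path$n_ref`.
#' @export
warp_series <- function(query, path) {
  check_path(path)
  if (length(query) != path$n_query)
    stop("query length does not match the path (", length(query),
         " vs ", path$n_query, ")")
  sums <- rowsum(query[path$query_idx], path$ref_idx)
  counts <- rowsum(rep(1, length(path$ref_idx)), path$ref_idx)
  as.numeric(sums / counts)
}

#' Apply a registration path to a spectrogram
#'
#' Warps every frequency column of a spectrogram independently onto the
#' reference frame grid (each output frame averages the matched query
#' frames); the frequency axis is untouched, which is why warping in
#' time-frequency space, unlike warping the raw signal, cannot distort
#' spectral content.
#'
#' @param spec an `ecog_tfr` with `path$n_query` frames.
#' @param path a `registration_path` built on the same frame grid.
#' @param ref_times optional frame times of the reference grid to stamp on
#'   the output (defaults to the query's own times when the frame counts
#'   agree, which is the usual equal-length epoch case).
#' @return An `ecog_tfr` on the reference frame grid.
#' @export
warp_spectrogram <- function(spec, path, ref_times = NULL) {
  check_path(path)
  if (nrow(spec$power) != path$n_query)
    stop("spectrogram frame count (", nrow(spec$power),
         ") does not match the path (", path$n_query, " query frames)")
  counts <- as.numeric(rowsum(rep(1, length(path$ref_idx)), path$ref_idx))
  warped <- rowsum(spec$power[path$query_idx, , drop = FALSE],
                   path$ref_idx) / counts
  dimnames(warped) <- NULL
  if (is.null(ref_times)) {
    ref_times <- if (path$n_ref == path$n_query) spec$times else
      stop("ref_times must be supplied when reference and query grids differ")
  }
  new_tfr(warped, ref_times, spec$freqs, normalized = spec$normalized,
          baseline = spec$baseline, baseline_window = spec$baseline_window)
}

#' Warp a raw signal in the time domain (anti-pattern demonstration)
#'
#' Re-indexes raw samples along a frame-level registration path expanded to
#' sample resolution by linear interpolation. Warping the time-domain
#' signal stretches and compresses its oscillations, so it distorts the
#' spectral content (e.g., it smears a mains line across neighbouring
#' bins); it is provided only to demonstrate why paths should be applied
#' to spectrograms instead.
#'
#' @param signal a `signal_trace` covering the same epoch the path's
#'   reference/query frame grids were built on.
#' @param path a `registration_path` over spectrogram frames.
#' @return A `signal_trace` on the reference time base (same length as the
#'   input for equal-length grids).
#' @export
warp_signal_time_domain <- function(signal, path) {
  check_path(path)
  n_s <- length(signal$x)
  # mean query frame matched to each reference frame; non-decreasing
  qbar <- as.numeric(rowsum(as.numeric(path$query_idx), path$ref_idx) /
                       rowsum(rep(1, length(path$ref_idx)), path$ref_idx))
  # map sample positions -> ref frame coord -> query frame coord -> sample
  p <- seq_len(n_s)
  u <- 1 + (p - 1) * (path$n_ref - 1) / (n_s - 1)
  v <- approx(seq_len(path$n_ref), qbar, u, rule = 2)$y
  qpos <- 1 + (v - 1) * (n_s - 1) / (path$n_query - 1)
  out <- approx(seq_len(n_s), signal$x, pmin(pmax(qpos, 1), n_s))$y
  signal_trace(out, signal$rate, signal$t0)
}

#' Registration path from gamma-band activity
#'
#' Obtains a time-registration path directly from the neural signal rather
#' than the kinematics: the per-frame gamma band power (65-90 Hz by
#' default, where movement-related gamma is cleanest) of two normalized
#' spectrograms is extracted and aligned by [dtw_path()]. Useful when no
#' kinematic recording exists, at the cost of noisier paths.
#'
#' @param ref_spec,query_spec `ecog_tfr` objects on a shared grid.
#' @param band Hz interval of the gamma activity used for alignment.
#' @return A `registration_path`.
#' @export
path_from_gamma <- function(ref_spec, query_spec, band = c(65, 90)) {
  check_same_grid(ref_spec, query_spec)
  dtw_path(band_power(ref_spec, band), band_power(query_spec, band))
}
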