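test_that("identical series give the zero-cost diagonal path", {
  p <- dtw_path(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p$total_cost, 0)
  expect_equal(p$ref_idx, 1:3)
  expect_equal(p$query_idx, 1:3)
})

test_that("the worked micro-example is reproduced exactly", {
  p <- dtw_path(c(0, 1, 2), c(0, 2))
  expect_equal(p$total_cost, 1)
  expect_equal(p$normalized_cost, 0.2)
  expect_equal(p$ref_idx, c(1L, 2L, 3L))
  expect_equal(p$query_idx, c(1L, 1L, 2L))
  expect_equal(dtw_brute_force(c(0, 1, 2), c(0, 2)), 1)
  expect_equal(warp_series(c(0, 2), p), c(0, 0, 2))
})

test_that("DTW cost equals the brute-force minimum and the path re-accumulates to it", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    r <- rnorm(n); q <- rnorm(m)
    p <- dtw_path(r, q)
    expect_equal(p$total_cost, dtw_brute_force(r, q), tolerance = 1e-12)
    expect_equal(path_cost(r, q, p), p$total_cost, tolerance = 1e-12)
  }
})

test_that("cost is symmetric and bounded by the pure-diagonal cost", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    r <- rnorm(n); q <- rnorm(n)
    expect_equal(dtw_path(r, q)$total_cost, dtw_path(q, r)$total_cost,
                 tolerance = 1e-12)
    expect_lte(dtw_path(r, q)$total_cost, 2 * sum(abs(r - q)) + 1e-12)
  }
})

test_that("paths satisfy the monotone continuity invariants", {
  set.seed(12)
  for (i in 1:50) {
    r <- rnorm(sample(2:40, 1)); q <- rnorm(sample(2:40, 1))
    p <- dtw_path(r, q)
    expect_equal(c(p$ref_idx[1], p$query_idx[1]), c(1, 1))
    expect_equal(c(p$ref_idx[length(p$ref_idx)], p$query_idx[length(p$query_idx)]),
                 c(length(r), length(q)))
    dr <- diff(p$ref_idx); dq <- diff(p$query_idx)
    expect_true(all(dr %in% 0:1) && all(dq %in% 0:1) && all(dr + dq >= 1))
    expect_true(all(seq_along(r) %in% p$ref_idx))
    expect_true(all(seq_along(q) %in% p$query_idx))
  }
  expect_error(dtw_path(numeric(0), 1:3), "empty")
  expect_error(dtw_path(c(1, NA), 1:2), "non-finite")
})

test_that("warping smooth time-distorted velocity bumps reduces the residual", {
  # the scientifically relevant improvement claim: for smooth profiles that
  # differ by a time distortion, registration reduces the L1 residual
  tau <- seq(0, 1, length.out = 120)
  bump <- function(a) ecogwarp:::mj_vel(pmin(pmax(tau * a, 0), 1))
  set.seed(3)
  for (i in 1:20) {
    r <- bump(1); q <- bump(runif(1, 0.6, 1.6))
    p <- dtw_path(r, q)
    expect_lte(sum(abs(r - warp_series(q, p))), sum(abs(r - q)) + 1e-9)
  }
})

test_that("warp_series aggregates by mean on the reference grid", {
  p <- identity_path(5)
  expect_equal(warp_series(c(5, 4, 3, 2, 1), p), c(5, 4, 3, 2, 1))
  # full collapse onto a length-1 reference
  q <- c(1, 2, 3, 4)
  p1 <- dtw_path(0, q)
  expect_equal(warp_series(q, p1), mean(q))
  expect_error(warp_series(1:3, identity_path(5)), "length")
})

test_that("warping a spectrogram re-maps frames but never frequencies", {
  set.seed(2)
  sp <- random_tfr(40, 6)
  expect_equal(warp_spectrogram(sp, identity_path(40))$power, sp$power)
  # frame-constant spectrograms are invariant under any admissible path
  const <- ecogwarp:::new_tfr(matrix(rep(rnorm(6), each = 40), 40, 6),
                              sp$times, sp$freqs, normalized = TRUE)
  path <- dtw_path(rnorm(40), rnorm(40))
  expect_equal(warp_spectrogram(const, path)$power, const$power,
               tolerance = 1e-12)
  expect_error(warp_spectrogram(random_tfr(30, 6), identity_path(40)),
               "frame count")
})

test_that("kinematic paths undo a known affine time distortion of the gamma burst", {
  for (s in 1:5) {
    sa <- simulate_session(affine_trial_params(1.0, s))
    sb <- simulate_session(affine_trial_params(1.6, s + 100))
    ta <- prepare_trials(sa)[[1]]; tb <- prepare_trials(sb)[[1]]
    tpl_a <- ground_truth_template(sa$trials[[1]], sa$params, ta$spec$times,
                                   ta$spec$freqs, onset = ta$onset)
    tpl_b <- ground_truth_template(sb$trials[[1]], sb$params, tb$spec$times,
                                   tb$spec$freqs, onset = tb$onset)
    path <- dtw_path(ta$vel_frames, tb$vel_frames)
    wb <- warp_spectrogram(tpl_b, path, ref_times = tpl_a$times)
    reach <- which(tpl_a$times > -0.5 & tpl_a$times < 1.5)
    pk_ref <- reach[which.max(band_power(tpl_a, c(65, 140))[reach])]
    pk_wrp <- reach[which.max(band_power(wb, c(65, 140))[reach])]
    expect_lte(abs(pk_ref - pk_wrp), 2)
  }
})

test_that("time-domain warping distorts a pure tone; spectrogram warping does not", {
  tt <- (0:14399) / 1200
  tone <- signal_trace(sin(2 * pi * 60 * tt), 1200, t0 = -4)
  # non-uniform path from two velocity profiles with different durations
  sa <- simulate_session(affine_trial_params(1.0, 1))
  sb <- simulate_session(affine_trial_params(1.6, 2))
  path <- dtw_path(prepare_trials(sa)[[1]]$vel_frames,
                   prepare_trials(sb)[[1]]$vel_frames)
  frac60 <- function(sp) sum(sp$power[, sp$freqs == 60]) / sum(sp$power)
  f_orig <- frac60(compute_spectrogram(tone, fmax = 200))
  f_td <- frac60(compute_spectrogram(warp_signal_time_domain(tone, path),
                                     fmax = 200))
  expect_lt(f_td, f_orig)
  sp_w <- warp_spectrogram(compute_spectrogram(tone, fmax = 200), path,
                           ref_times = prepare_trials(sa)[[1]]$spec$times)
  # per-frame tone power varies at Hamming side-lobe level with tone phase,
  # so frame averaging preserves the bin fraction to ~0.1%, not bit-exactly
  expect_equal(frac60(sp_w), f_orig, tolerance = 1e-3)
})

test_that("gamma-derived paths also register trials, if less reliably than kinematics", {
  # identical spectrograms -> zero-cost path
  set.seed(4)
  sp <- random_tfr(30, 30, freqs = 61:90)
  p0 <- path_from_gamma(sp, sp, band = c(65, 90))
  expect_equal(p0$total_cost, 0)
  # warping kinematics along gamma paths beats onset-only alignment in the
  # majority of seeded trial pairs
  wins <- 0; np <- 14
  for (s in seq_len(np)) {
    ss <- simulate_session(session_params(n_trials = 2, seed = 300 + s))
    tr <- prepare_trials(ss)
    path <- path_from_gamma(tr[[1]]$spec, tr[[2]]$spec, c(65, 90))
    wv <- warp_series(tr[[2]]$vel_frames, path)
    rw <- sqrt(mean((tr[[1]]$vel_frames - wv)^2))
    ru <- sqrt(mean((tr[[1]]$vel_frames - tr[[2]]$vel_frames)^2))
    if (rw < ru) wins <- wins + 1
  }
  expect_gt(wins, np / 2)
})
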