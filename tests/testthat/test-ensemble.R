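test_that("the medoid reference is central and deterministic", {
  v <- lapply(1:2, function(i) c(0, 1, 2, 1, 0))
  expect_equal(select_reference(v, "medoid"), 1L)      # tie -> first
  # one outlier among near-duplicates is never the medoid
  set.seed(6)
  base <- ecogwarp:::mj_vel(seq(0, 1, length.out = 50))
  vs <- c(lapply(1:4, function(i) base + rnorm(50, 0, 0.01)),
          list(rev(base) * 3 + 1))
  expect_lt(select_reference(vs, "medoid"), 5L)
  expect_identical(select_reference(vs, "medoid"), select_reference(vs, "medoid"))
  expect_equal(select_reference(vs, "index", index = 3), 3L)
  expect_equal(select_reference(vs, "permute_all"), 1:5)
  expect_error(select_reference(vs[1], "medoid"), "at least 2")
})

test_that("conventional averaging is the cell-wise mean", {
  set.seed(9)
  a <- random_tfr(10, 4)
  expect_equal(conventional_average(list(a, a, a))$power, a$power)
  b <- a; b$power <- a$power + 1
  c_ <- a; c_$power <- a$power - 1
  expect_equal(conventional_average(list(b, c_))$power, a$power)
  bad <- random_tfr(9, 4)
  expect_error(conventional_average(list(a, bad)), "mismatched grids")
})

test_that("warped averaging equals conventional averaging when kinematics are identical", {
  s <- simulate_session(zero_variance_params(n_trials = 4, seed = 31))
  tr <- prepare_trials(s)
  specs <- lapply(tr, `[[`, "spec")
  vels <- lapply(tr, `[[`, "vel_frames")
  conv <- conventional_average(specs)
  wavg <- warped_average(specs, vels, reference = 1)
  expect_equal(wavg$power, conv$power, tolerance = 1e-12)
  expect_error(warped_average(specs, vels[1:3], 1), "missing kinematics")
})

test_that("onset jitter smears the conventional average (peak attenuation)", {
  s <- simulate_session(session_params(n_trials = 12, seed = 21))
  specs <- lapply(prepare_trials(s), `[[`, "spec")
  conv <- conventional_average(specs)
  smooth <- function(x) as.numeric(stats::filter(x, rep(1 / 21, 21), sides = 2))
  peak <- function(sp) max(smooth(band_power(sp, c(65, 140))), na.rm = TRUE)
  expect_lt(peak(conv), mean(vapply(specs, peak, numeric(1))))
})

test_that("rms_error matches its closed form on hand examples", {
  t2 <- c(0, 0.01); f2 <- c(1, 2)
  m <- function(v) ecogwarp:::new_tfr(matrix(v, 2, 2), t2, f2)
  a <- m(c(0, 0, 0, 0)); b <- m(c(1, 1, 1, 1))
  expect_equal(rms_error(a, a), 0)
  expect_equal(rms_error(a, b), 1)
  set.seed(1)
  x <- random_tfr(5, 3); y <- x; y$power <- x$power + 3
  expect_equal(rms_error(x, y), 3)
})

test_that("rms_error is a metric: symmetry, identity, triangle inequality", {
  set.seed(15)
  for (i in 1:30) {
    a <- random_tfr(6, 5)
    b <- a; b$power <- matrix(rnorm(30), 6, 5)
    c_ <- a; c_$power <- matrix(rnorm(30), 6, 5)
    expect_equal(rms_error(a, b), rms_error(b, a))
    expect_equal(rms_error(a, a), 0)
    expect_lte(rms_error(a, c_), rms_error(a, b) + rms_error(b, c_) + 1e-12)
  }
})

test_that("band changes are directional and significant on a default session", {
  s <- simulate_session(session_params(n_trials = 10, seed = 55))
  specs <- lapply(prepare_trials(s), `[[`, "spec")
  ks_b <- band_change_ks_test(specs, c(12, 30))
  ks_g <- band_change_ks_test(specs, c(65, 140))
  expect_equal(ks_b$direction, -1)
  expect_equal(ks_g$direction, 1)
  expect_lt(ks_b$p_value, 0.05)
  expect_lt(ks_g$p_value, 0.05)
  expect_error(band_change_ks_test(specs[1], c(12, 30)), "at least 2")
})

test_that("permutation evaluation rejects fully degenerate sessions", {
  set.seed(2)
  a <- random_tfr(20, 4)
  expect_error(permutation_evaluation(list(a, a, a),
                                      replicate(3, rnorm(20), simplify = FALSE),
                                      identity_paths = TRUE),
               "degenerate")
})

test_that("permutation evaluation finds real warping gains but none under identity paths", {
  s <- simulate_session(session_params(n_trials = 8, seed = 61))
  tr <- prepare_trials(s)
  specs <- lapply(tr, `[[`, "spec")
  vels <- lapply(tr, `[[`, "vel_frames")
  ev <- permutation_evaluation(specs, vels)
  expect_lt(ev$p_value, 0.05)
  expect_lt(median(ev$warped_errors), median(ev$unwarped_errors))
  expect_length(ev$warped_errors, 8 * 7)
  ev0 <- permutation_evaluation(specs, vels, identity_paths = TRUE)
  expect_gt(ev0$p_value, 0.05)
  expect_equal(ev0$warped_errors, ev0$unwarped_errors)
})

test_that("distribution separation grows with cross-trial variability", {
  sep <- vapply(c(0.05, 0.15, 0.3), function(sdr) {
    s <- simulate_session(session_params(
      n_trials = 6, reach_duration_sd = sdr, pause_duration_sd = sdr,
      retrieve_duration_sd = sdr, onset_jitter_sd = sdr, seed = 71))
    tr <- prepare_trials(s)
    ev <- permutation_evaluation(lapply(tr, `[[`, "spec"),
                                 lapply(tr, `[[`, "vel_frames"))
    mean(ev$log_unwarped) - mean(ev$log_warped)
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("kinematic warp error flags overshooting sessions", {
  med <- function(ov) {
    s <- simulate_session(session_params(n_trials = 10, overshoot_prob = ov,
                                         seed = 31))
    kinematic_warp_error_report(lapply(prepare_trials(s), `[[`,
                                       "vel_frames"))$median_error
  }
  e_over <- med(0.4); e_none <- med(0)
  expect_gt(e_over, e_none)
  expect_error(kinematic_warp_error_report(list(rnorm(5))), "at least 2")
  # identical kinematics -> all-zero errors
  rep0 <- kinematic_warp_error_report(replicate(3, c(0, 1, 0), simplify = FALSE))
  expect_true(all(rep0$pair_errors$rms == 0))
})

test_that("path-aligned rectified EMG retains the retrieval burst that onset alignment loses", {
  s <- simulate_session(session_params(n_trials = 12, seed = 21))
  tr <- prepare_trials(s)
  vels <- lapply(tr, `[[`, "vel_frames")
  emg <- lapply(tr, `[[`, "emg")
  # reference: typical (median retrieval duration) trial, so amplitude
  # differences across trials scatter symmetrically around it
  durs <- vapply(s$trials, function(t) t$durations[["retrieve"]], numeric(1))
  ref <- which.min(abs(durs - median(durs)))
  a_on <- average_rectified_emg(emg, "onset")
  a_wp <- average_rectified_emg(emg, "paths", velocities = vels, reference = ref)
  single <- average_rectified_emg(emg[ref], "onset")
  on <- tr[[ref]]$onset
  win <- a_on$times > (s$trials[[ref]]$phases[["retrieve_start"]] - on) &
    a_on$times < (s$trials[[ref]]$phases[["retrieve_end"]] - on)
  floor_ <- mean(single$mean[single$times < -1])
  retention <- function(avg) (mean(avg$mean[win]) - floor_) /
    (mean(single$mean[win]) - floor_)
  expect_gte(retention(a_wp), 0.8)
  expect_lt(retention(a_on), retention(a_wp))
  # zero signals average to zero
  z <- lapply(1:3, function(i) signal_trace(rep(0, 2400), 1200, t0 = 0))
  expect_true(all(average_rectified_emg(z, "onset")$mean == 0))
})
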