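# Shared fixture builders (all sessions are generated in code, seeded).

# a session with zero cross-trial variability: every trial identical
zero_variance_params <- function(n_trials = 4, seed = 1) {
  session_params(n_trials = n_trials,
                 reach_duration_sd = 0, pause_duration_sd = 0,
                 retrieve_duration_sd = 0, onset_jitter_sd = 0,
                 seed = seed)
}

# a single deterministic-kinematics trial with a chosen reach duration;
# reach amplitude scales with duration so the velocity profile is an
# amplitude-preserving (affine) time distortion of the 1 s reference
affine_trial_params <- function(reach, seed) {
  session_params(n_trials = 1, reach_duration_mean = reach,
                 reach_duration_sd = 1e-9, pause_duration_sd = 1e-9,
                 retrieve_duration_sd = 1e-9, onset_jitter_sd = 0,
                 reach_amplitude = 40 * reach, seed = seed)
}

# small synthetic spectrogram on an arbitrary grid
random_tfr <- function(n_frames = 6, n_freqs = 4, times = NULL, freqs = NULL) {
  ecogwarp:::new_tfr(matrix(rnorm(n_frames * n_freqs), n_frames, n_freqs),
                     times %||% seq(0, by = 0.01, length.out = n_frames),
                     freqs %||% seq_len(n_freqs), normalized = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
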