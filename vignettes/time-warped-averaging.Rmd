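---
title: "Kinematics-guided time-warped averaging of ECoG spectrograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematics-guided time-warped averaging of ECoG spectrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogwarp)
```

## The problem

Movement-related cortical activity is usually made visible by averaging
time-frequency representations of many repeated trials, aligned at a motor
event such as movement onset. Averaging assumes the neural components occur
at the same post-onset latencies on every trial. For unconstrained reaching
that assumption fails: initiation latency, movement speed and duration all
vary from trial to trial, so components that are sharp on single trials —
beta-band (12–30 Hz) desynchronization (ERD) and gamma-band (65–140 Hz)
synchronization (ERS) — smear or split apart in the onset-aligned average.

`ecogwarp` removes the temporal mismatch before averaging. Because beta and
gamma activity co-vary with arm velocity, aligning the velocity profiles of
two trials also aligns their movement-related neural activity. For each
trial, dynamic time warping (DTW) of its velocity profile onto a reference
trial's profile yields a monotone *time-registration path*; the path is
applied to the trial's baseline-normalized spectrogram (never to the raw
signal), and the registered spectrograms are averaged cell-wise.

## Pipeline and model

1. **Kinematics.** 3-D hand position sampled at 40 Hz is differentiated by
   central differences and smoothed with a 5-sample moving average (the
   differentiation scheme is our choice; it is robust to tracker noise at
   this rate). Movement onset is the first sample whose speed exceeds
   0.5 cm/s, searched from the auditory cue so pre-cue twitches cannot
   trigger; that instant becomes *t* = 0. Epochs run from 4 s before to 8 s
   after onset (half-open interval, so a 1200 Hz channel gives exactly
   14,400 samples).
2. **Spectrograms.** 100 ms Hamming windows advanced by 10 ms. A 1 Hz bin
   spacing is obtained by zero-padding each 120-sample window to one second
   of samples; this interpolates the spectrum (the true resolution of a
   100 ms window remains ~10 Hz). Frames are stamped at window centers and
   partial edge windows are dropped rather than padded. Power is |FFT|²
   without window-gain compensation — all downstream quantities are ratios
   to baseline, so the gain cancels. ERD/ERS values are
   100·(P − B)/B per frequency, with B(f) the mean power 1–2 s before
   onset, computed per trial.
3. **Warping.** DTW uses the symmetric step pattern with weights (1, 2, 1),
   no slope constraint, absolute difference as the local cost, and
   `g(1,1) = 2 d(1,1)`. Ties are broken deterministically (diagonal, then
   reference-advance); this matters on near-zero-velocity pauses where many
   cells tie, and makes identical inputs map to the exact diagonal. Paths
   are computed on the signed X-velocity (the reach axis, orthogonal to the
   chest) resampled to the 10 ms frame grid over the full epoch; a
   speed-based variant is available (`warp_on = "speed"`). When a path maps
   several query frames to one reference frame they are aggregated by
   arithmetic mean; the application mechanics are our choice, made for
   linearity and shape preservation.
4. **Averaging and statistics.** The conventional average is the plain
   cell-wise mean at onset alignment; the time-warped average warps each
   trial onto a reference trial first. The reference can be a fixed index
   or the *medoid* (minimum summed normalized DTW cost). Warping efficacy
   is evaluated by permuting the reference across all trials: for every
   ordered (reference, query) pair the RMS difference across all
   time-frequency cells is computed warped and unwarped; the log-transformed
   error samples (approximately normal) are compared with a one-sided Welch
   t-test of warped < unwarped. The unpaired form mirrors the two-distribution
   description of the evaluation; a paired variant is available by flag.
   RMS is normalized by cell count (a true root-*mean*-square) so values
   are comparable across grid sizes.

Warping is applied in the time-frequency domain on purpose: re-indexing the
*raw signal* along a path stretches its oscillations and distorts the
spectrum (a mains line, for instance, smears into neighbouring bins).
`warp_signal_time_domain()` exists only to demonstrate that failure mode.

## The synthetic-session generator

No patient recordings ship with the package; the generator produces
sessions with the statistical structure the method assumes, and every
simulation study below states the conditions it uses.

* **Kinematics.** Each trial holds a rest period, a cue at 4.5 s, a
  cue-to-onset latency of 0.5 s with sd `onset_jitter_sd` (default 0.3 s),
  a minimum-jerk reach of 40 cm along X (duration 1.2 ± 0.3 s), a
  stationary pause (1.3 ± 0.4 s), and a minimum-jerk return (1.0 ± 0.3 s);
  trial recordings last 15 s so the −4/+8 s epoch always fits. The
  minimum-jerk profile is our modelling choice — the standard description
  of point-to-point reaching, smooth and exactly integrable. Durations are
  drawn from normals truncated at mean ± 3 sd; parameter sets whose
  mean − 3 sd is not positive are rejected. With probability
  `overshoot_prob` a trial overshoots the target by 15% and adds a 0.4 s
  corrective reversal, emulating subjects who overshoot.
* **ECoG.** A sum of independent Gaussian processes shaped in the frequency
  domain: 1/f background (amplitude capped below 1 Hz), flat-in-band beta
  whose amplitude is multiplied by `erd_depth` (default 0.6, i.e. a ~64%
  power drop) while speed is non-zero, and flat-in-band gamma whose power
  scales as 1 + `ers_gain`·speed (default 0.05 per cm/s, roughly a
  four-fold increase at peak reach speed). Envelopes are built on the 40 Hz
  kinematic grid and linearly resampled to 1200 Hz. An optional mains
  sinusoid (off by default; 60 Hz when enabled) supports the line-noise
  demonstrations. The 1/f floor, the modulation depths and the mains
  convention are generator choices; real recordings fix only the
  *directions* of the band changes.
* **EMG.** Zero-mean broadband noise with amplitude
  `emg_noise_sd + emg_gain·speed`: silent at rest, bursting with movement.
* **Ground truth.** Each trial records its onset ground truth — the
  operational definition (velocity estimation, then the 0.5 cm/s
  threshold) applied to the noiseless trace, so that detection accuracy on
  noisy kinematics is measured against the clean-data answer rather than
  an unobservable continuous crossing; the 5-sample velocity smoothing
  advances the apparent crossing by one to two tracker samples relative to
  the analytic crossing, identically for ground truth and detection — and
  its phase boundaries, and
  `ground_truth_template()` returns the *expected* normalized spectrogram
  implied by the model for a trial's kinematics. The template ignores the
  window smearing of the short-time Fourier estimator; that bias is shared
  by the conventional and warped averages it is compared against, so their
  ranking is unaffected.

What the generator does **not** emulate: artifacts (eye movement, cable
noise), non-stationary background power, cross-frequency coupling,
trial-to-trial changes in modulation depth, and imperfect synchronization
between kinematic and neural clocks. Tests passing on synthetic sessions
therefore demonstrate the correctness and calibration of the *method*, not
its robustness to every pathology of clinical recordings.

## Numerical and design notes

* Frame grids across trials agree in size and spacing by construction;
  cell-wise operations verify grid compatibility and tolerate sub-sample
  offsets in absolute frame times (onsets do not fall exactly on sample
  boundaries).
* Normalization is exactly invertible given the stored baseline
  (`baseline_restore()`), round-tripping to < 1e−9 relative error.
* Cross-trial statistics run on spectrograms cropped at 200 Hz — well
  above the 140 Hz gamma edge — which keeps the quadratic-cost permutation
  evaluation light without touching any analysis band.
* Degenerate inputs fail loudly: zero baselines name the frequency, epochs
  that do not fit name the trial, all-identical trials make the
  permutation evaluation refuse to log-transform zero errors, and
  zero-error pairs are reported as excluded rather than dropped silently.
* In simulation studies the reference trial is the session's first trial —
  an arbitrary draw under the generator's randomization — rather than the
  medoid, so reference selection does not interact with the effect under
  study; the pipeline default for real use remains the medoid.
* One open ambiguity is whether paths should be computed on signed
  velocity or speed; both are available, signed X-velocity being the
  default because the reach is essentially one-dimensional along X and the
  sign distinguishes reach from retrieval.
* The no-slope-constraint choice follows the symmetric Sakoe–Chiba form;
  windowed or slope-limited DTW variants are deliberately out of scope.

## Problem sizes used in the shipped studies

The test suite and `scripts/acceptance.R` run entirely on generated data:
20 sessions of 50 trials for the template-recovery study, one 50-trial
session (2,450 ordered pairs) for the permutation evaluation, 20 eight-trial
sessions for its null calibration, 1,000 short random pairs for the
exhaustive DTW optimality check, and 10-trial sessions for the overshoot
comparison. These sizes give stable Monte-Carlo outcomes at desk scale and
are stated here as the package's own study conditions.

## Worked example

```{r example, eval = FALSE}
params <- session_params(n_trials = 20, seed = 1)
session <- simulate_session(params)
report <- run_pipeline(session, run_config(reference = 1))
report
plot(report$conventional, fmax = 150)
plot(report$warped, fmax = 150)
```

The report prints the direction and significance of the beta/gamma band
changes, the permutation-evaluation t and p, and the median kinematic warp
error that flags sessions (e.g., frequent overshoots) where
kinematics-guided warping is unreliable.

## Known limitations

* DTW cost is quadratic in epoch length; full-session medoid selection and
  the permutation evaluation are the expensive steps (minutes for 50
  trials).
* Amplitude differences between trials are not corrected: warping aligns
  *when* things happen, not *how strongly*; a slower-but-weaker movement
  still averages to an attenuated component.
* The permutation evaluation's ordered pairs share trials and are therefore
  not independent; the t-test is used as a descriptive separation measure,
  as is conventional for this design.
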