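# ecogwarp

Kinematics-guided time-warped averaging of trial-based electrocorticographic
(ECoG) spectrograms.

## The problem

Averaging movement-locked trials is the standard way to expose
movement-related spectral components — beta-band (12–30 Hz) event-related
desynchronization (ERD) and gamma-band (65–140 Hz) synchronization (ERS) —
in low-SNR electrophysiology. Unconstrained reaching movements, however,
vary in initiation time, speed and duration from trial to trial, so
onset-aligned ("conventional") averages smear these components. Because
beta and gamma activity track arm velocity, registering the *velocity
profiles* of trials onto a common time base also registers the neural
activity. `ecogwarp` computes, per trial, a dynamic-time-warping (DTW)
alignment of its velocity profile onto a reference trial,

```
g(i,j) = min( g(i-1,j) + d(i,j),  g(i-1,j-1) + 2 d(i,j),  g(i,j-1) + d(i,j) ),
d(i,j) = | v_ref(i) - v_query(j) |,   g(1,1) = 2 d(1,1),
```

(the symmetric step pattern, no slope constraint), applies the resulting
time-registration path to the trial's baseline-normalized spectrogram
`100·(P(f,t) − B(f))/B(f)` (baseline B: mean power 1–2 s before onset), and
averages the registered spectrograms cell-wise. Warping acts on the
time-frequency representation, never on the raw signal — time-domain
warping provably distorts spectral content (`warp_signal_time_domain()`
demonstrates it). A permutation evaluation quantifies the gain: with every
trial taking a turn as reference, the RMS difference across all
time-frequency cells between reference and query spectrograms is compared
warped vs unwarped via a one-sided Welch t-test on the log-transformed
error samples.

A seeded synthetic-session generator (minimum-jerk reach/pause/retrieve
kinematics at 40 Hz; 1200 Hz ECoG with 1/f background, movement-gated beta
suppression and velocity-scaled gamma power; movement-gated EMG) makes the
entire pipeline testable without patient data.

For whom: anyone averaging trial-locked time-frequency responses of
movements with variable kinematics — ECoG/EEG/LFP motor studies,
brain-machine-interface template building — or needing a clean, tested DTW
with exact symmetric-step semantics.

## Worked example

```r
library(ecogwarp)

params  <- session_params(n_trials = 20, seed = 1)   # reach 1.2 +/- 0.3 s, 40 cm
session <- simulate_session(params)
report  <- run_pipeline(session, run_config(reference = 1))
report
```

```
Time-warped averaging report: 20 trials, reference trial 1
  beta band change:  direction -1, KS p = 5.8e-10
  gamma band change: direction +1, KS p = 1.45e-11
  warping evaluation: t = -9.019, p = 7.7e-19
  median kinematic warp error: 1.586 cm/s
```

Reading the output: beta power drops and gamma power rises during movement
relative to the pre-movement baseline (directions −1/+1, two-sample
Kolmogorov–Smirnov p-values across trials); the permutation evaluation's
negative t and small p say that warping the spectrograms onto the reference
trial's time base reduced cross-trial RMS variability relative to plain
onset alignment; the kinematic warp error summarizes the residual velocity
mismatch after warping (large values — e.g., from frequent target
overshoots — flag sessions where kinematic warping is unreliable).
`report$conventional` and `report$warped` hold the two averaged
spectrograms (`plot()` renders them); `report$emg_onset` / `$emg_warped`
are the average rectified EMG traces under the two alignments.

A thin CLI wraps the same functions:

```sh
exec/ecogwarp simulate --out session_dir --trials 20 --seed 1
exec/ecogwarp run --session session_dir --out report.json
```

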