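---
title: "Methods: quantifying PKA biosensor responses to optogenetic stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying PKA biosensor responses to optogenetic stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(pkadyn)
```

## Scope and signal model

`pkadyn` analyzes fluorescence time series from PKA activity reporters
imaged while noradrenergic (locus coeruleus) axons are stimulated
optogenetically. Two acquisition regimes are supported and carry separate
defaults throughout the package:

* **slice / FRET**: a two-channel ratiometric reporter (AKAR3EV-like) in
  acute cortical slices; slow frames (15-s interval by default), five
  stimulation trials ~10 min apart, bath pharmacology;
* **in vivo / single channel**: a single-chromophore green reporter
  (GAkdYmut-like) imaged at 6.2 Hz; three trials 5 min apart,
  intraperitoneal pharmacology, dendritic and somatic ROI populations.

The measured quantity is always the fractional change of a per-ROI
brightness signal relative to a pre-stimulus baseline — ΔR/R0 for the
FRET ratio R = F535/F480, ΔF/F0 for a single channel — expressed in percent.
A stimulus-locked transient is modeled by a parametric kernel with
amplitude `A` (%), a rise phase and a single-exponential decay
(`response_kernel()`):

* the **piecewise** form rises as `A (1 − e^(−u/τ_rise))` for
  `u ∈ [0, rise_duration]` and then decays with constant `τ_decay` from the
  value reached at the end of the rise. Its peak is
  `A (1 − e^(−rise_duration/τ_rise))`, i.e. equals `A` up to the saturation
  factor; default rise durations are ≥ 4 rise constants so the shortfall is
  1–2%. This form is the analysis model itself (saturating-exponential
  onset, exponential decay), so estimator and generator match exactly and
  fits can be validated for exact recovery.
* the **difference-of-exponentials** form
  `A c (e^(−u/τ_decay) − e^(−u/τ_rise))` is smooth at the peak; `c`
  normalizes the peak to `A`, and the peak time has the closed form
  `τ_r τ_d/(τ_d − τ_r) ln(τ_d/τ_r)` used as a test oracle.

Reference kinetics are `slice_kernel()` (rise 15 s over 75 s, decay
178.4 s, peaking inside the 60–90 s bin) and `invivo_kernel()` (rise
14.7 s over 60 s, decay 154.1 s).

## The synthetic generator

`simulate_traceset()` draws, per ROI, a responder flag
(Bernoulli `responder_fraction`) and a base amplitude, log-normal with mean
`A` and CV `amplitude_cv` (default 0.3). Log-normality encodes that
responses to a Gs-coupled agonist are non-negative and right-skewed;
signed drug effects enter through per-trial multiplicative factors instead.
The realized amplitude of ROI *i* in trial *k* is exactly
`A_i × rundown_k × δ_k` — run-down profiles (`rundown_layer5()`,
`rundown_layer23()`) and the drug schedule δ act multiplicatively, and the
paired ground truth stores these products so recovery is testable without
re-deriving them.

In FRET mode a gain split γ ∈ [0, 1] sends `1 + γ s` to the acceptor and
`(1 + γ s)/(1 + s)` to the donor, so the noiseless, bleach-free ratio
change equals the injected signal *exactly* for any γ; γ = 1 is an
acceptor-only sensor. Channels are then multiplied by per-channel
mono-exponential bleaching and receive additive Gaussian noise (SD in % of
the channel baseline; a variance-matched Poisson option exists but is off —
no shot-noise model is asserted for the emulated data).

Noise defaults were fixed once, on plausibility grounds: 0.2% per channel
per frame in the slice regime (a bright FRET sensor, 15-s integration,
soma-sized ROIs averaging many pixels) and 1.0% in vivo (6.2-Hz frames,
small dendritic ROIs). `simulate_fsk_plateau()` adds the
forskolin-saturation recording — a saturating rise to a plateau (default
25.7%, τ 120 s) with no decay — used to express responses as a fraction of
the sensor's maximum (`fsk_fraction()`).

What the generator does **not** emulate: motion and vascular artifacts,
neuropil contamination, time-varying drug pharmacokinetics within a trial
(i.p. time courses are represented as per-trial factors), receptor or
release kinetics, and spatial structure beyond disk-ROI movie rendering for
extraction tests. Green tests on this generator therefore validate the
*estimators* under the stated statistical structure, not robustness to
those artifacts.

## Preprocessing

`compute_ratio()` (FRET only) excludes ROIs with non-positive donor
samples, then `normalize_to_baseline()` converts to % change using the 60 s
preceding the first trial onset (≥ 3 frames required; ROIs with non-finite
or non-positive raw samples are dropped, never imputed). ΔR/R0 is computed
on the raw ratio, not a log-ratio, so inverted transients (β-blockade)
keep their sign.

`segment_by_stimulus()` cuts one epoch per ROI × trial on a shared
relative-time grid built from frame indices (so all epochs align exactly),
and re-baselines each epoch to its own pre-window mean: drug effects are
assessed against a local baseline, as a per-stimulation design implies.
Pre-windows are 60 s (slice; four frames — the shortest window compatible
with the ≥ 3-frame requirement of the statistical test) and 10 s (in vivo).
Overlapping windows are rejected up front with the maximum feasible post
window in the message.

**Tail subtraction.** With inter-trial intervals of 2–3 decay constants,
every epoch after the first sits on the residual exponential tail of the
preceding response. Re-baselining removes the tail's *level* but not its
continued *decay*, which subtracts a small constant from all later-trial
amplitudes — immaterial for full-sized responses, but a large relative
error when a drug nearly abolishes the response, and a strong bias on decay
fits of pooled multi-trial traces. `subtract_trial_tails()` therefore fits
each ROI's trial-(k−1) decay, extrapolates it into trial k's window and
subtracts it, sequentially, so the subtracted fit is itself tail-free. Both
regime presets enable this step.

`bleach_correct()` fits `I0 e^(−k t)` per ROI and channel on quiet frames
only (pre-stimulus, plus the last 60 s of each inter-trial gap and of the
recording), initialized by log-linear regression and refined with
`minpack.lm::nlsLM` under `k ≥ 0`; non-convergence skips the correction
with a warning. Equal bleaching in both FRET channels cancels in the ratio,
so the correction mainly matters for single-channel data and for absolute
intensities.

## Detection

`test_responsiveness()` compares response-window samples (onset → +120 s
slice, +60 s in vivo) against the pre-window with a two-sided rank-sum
test, per ROI and trial, at α = 0.05 uncorrected — the per-ROI usage the
analysis emulates; Welch's t and Benjamini–Hochberg adjustment are options,
off by default. Frames within a window are treated as exchangeable, which
overstates the effective sample size for autocorrelated high-rate data; a
`subsample` step is provided as a mitigation. The companion criterion
`threshold_classify()` flags epochs whose peak strictly exceeds 2% of
baseline; `concordance()` reports both conditional fractions between the
two verdicts, and `repeated_responders()` the ROIs responsive in every
trial. All-tied (noise-free, non-responding) epochs are reported degenerate
with p = 1 rather than erroring.

The test's type-I calibration is asserted on 10,000 simulated null epochs
(positive rate inside the 99% binomial interval around α), and power is
checked to be monotone over a four-point amplitude ladder.

## Kinetics

`measure_amplitude()` takes the signed extremum of the epoch within the
response window (earliest frame on ties; an all-zero epoch reports 0 at the
first frame). Because the maximum of a noisy trace is positively biased,
the presets smooth the peak search with a centred moving average — 45 s
(three frames) in the slice regime, 5 s (~31 frames) in vivo — spans short
relative to the kernel curvature (attenuation well under 5%) but long
enough to suppress most of the max-statistic bias. The raw search remains
the function default.

`measure_amplitude_at_cohort_peak()` is the estimator used for condition
contrasts: the pooled mean trace of each trial locates one peak latency,
and every ROI is read out at that fixed latency. A fixed-time read-out has
zero-mean noise, so it stays unbiased when a drug abolishes the response
and a window maximum would measure pure noise.

Time-to-peak is binned into half-open 30-s intervals `[k·30, (k+1)·30)` —
boundary peaks go up — matching the resolution imposed by slow frames;
time zero is the stimulation-train onset.

`fit_decay()` fits `y0 e^(−(t − t_peak)/τ)` from the empirical peak to the
epoch end (peak-anchored, since time-to-peak and decay are reported
separately); `fit_onset()` fits `P (1 − e^(−t/τ))` from onset to the peak.
Both use `nlsLM` with analytic initialization (log-linear regression for
the decay, the last rise sample for `P`), bounds τ ∈ [1, 10⁴] s, ≥ 5
frames, and a free-offset option. The offset makes the model exact when
epochs carry superposed tails of earlier trials (tails share τ), and the
in vivo preset — where pooled multi-trial traces are fitted — enables it;
for short per-ROI slice segments the three-parameter model is weakly
identifiable and noticeably inflates τ under noise, so the slice preset
fits the pure two-parameter model. Fits report R² and the τ standard
error; R² < 0.5 is flagged `poor`, non-convergence, a boundary τ, or a
wrong-sign plateau `failed` (τ absent). Negative transients are fitted
after sign inversion. Cohort time constants can be computed per ROI and
averaged, or on the pooled mean trace via `pooled_epoch()` — both paths are
exposed since either convention is defensible; the package's own summaries
use the pooled trace for in vivo cohorts (higher SNR at 6.2 Hz) and
per-ROI fits for slice cohorts.

## Pharmacology

`normalize_amplitudes()` expresses each ROI's per-trial amplitude as % of
its own first response (ROIs with non-positive first responses are excluded
and logged); `summarize_condition()` adds per-trial mean ± SEM across ROIs
and paired two-sided Wilcoxon signed-rank tests against trials 1 and 2
(flags `*` and `+`, p < 0.05; Welch's paired t optional; tests are
suppressed below three ROIs). Statistics pool ROIs across slices or mice,
matching designs whose n counts ROIs; a hierarchical per-slice analysis is
out of scope. `kinetics_shift_report()` applies the same paired flags to
peak times and summarizes decay constants over `ok` fits, reporting the
modal time-to-peak bin per trial.

## Numerical and design choices, in brief

* Windows: baseline 60 s before the first onset; epoch pre/post 60/480 s
  (slice) and 10/240 s (in vivo); peak search 120 s / 60 s. Post windows
  stop one pre-window short of the next trial.
* Slice frame interval 15 s: a plausible slow-scan setting consistent with
  30-s time-to-peak bins; the in vivo rate 6.2 Hz is the regime's
  defining constant.
* Ties in the peak search break to the earliest frame; bin boundaries round
  up; threshold comparisons are strict (`>`).
* All randomness flows through one integer seed per simulation
  (`withr::local_seed`), making trace sets bit-reproducible; the pipeline
  stamps outputs with a hash of the scientific configuration.
* Cohort sizes used by the validation suite mirror the emulated designs:
  18 slice somatic ROIs, 21–27 ROIs per drug design, 200–320 in vivo
  dendritic ROIs (960 ROI × trial epochs), 10,000 null epochs for test
  calibration, 50 simulation replicates for the false-flag rate.

## Limitations

Estimator validation on this generator shows correctness under the assumed
statistical structure; real recordings add motion, neuropil and vessel
artifacts, non-Gaussian noise, drifting baselines beyond mono-exponential
bleaching, and within-trial drug kinetics, none of which are modeled. The
rank-sum test treats frames as exchangeable; at high frame rates its
nominal α is optimistic unless subsampling is used. Single-exponential
kinetics are a reporting convention, not a biophysical decomposition —
sensor relaxation and phosphatase kinetics are not separated.
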