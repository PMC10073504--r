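---
title: "Transition-based physiological feature selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-based physiological feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transfeat)
```

## The problem

Psychological stress expresses itself in the autonomic nervous system:
heart rate rises, beat-to-beat variability and peripheral pulse-wave
amplitude fall, sweat glands fire more often. A stress-assessment system
built on wearable signals — electrocardiogram (ECG), blood volume pulse
(BVP/PPG) and galvanic skin response (GSR) — therefore needs to know *which*
of the many physiological features it can compute actually track emotional
state. Conventional selection compares feature distributions between
discrete emotional states. The method at the core of this package instead
tests each feature across *emotional state transitions*: for every subject
it pairs the feature's mean over the segment before a transition with its
mean over the segment after, and keeps features whose paired differences are
significant across all protocol transitions. Pairing removes the large
stable between-subject differences that drown unpaired comparisons, which is
the statistical content of the method's advantage.

`transfeat` implements the full pipeline: a synthetic cohort generator with
planted ground truth, signal preprocessing, 39-feature extraction over
sliding windows, three competing selection methods, and a cross-validated
classifier harness for the 3-class emotion task and the binary stress task.

## The session protocol and the synthetic cohort

The emulated session alternates 3 minutes of relaxing music with 4-minute
picture blocks eliciting neutral, negative and positive affect:
relax (180 s), neutral (240 s), relax, negative, relax, positive — 1260 s in
total. ECG is sampled at 400 Hz, BVP and GSR at 201 Hz. The default cohort
size is 85 subjects. Because no public recording of such a session exists,
every downstream stage is tested against synthetic recordings whose
generating parameters are retained as planted truth.

Each labelled segment carries a `state_effect` holding the parameters a
field scientist would recognise:

* `mean_rr_s` — mean R-R interval (s); heart rate is `60 / mean_rr_s`.
* `rr_sd_s` — total SD of the stochastic beat-to-beat variation (s).
* `rr_lf_amp_s`, `rr_hf_amp_s` — amplitudes (s) of deterministic sinusoidal
  R-R modulation at 0.1 Hz (baroreflex band) and 0.25 Hz (respiratory band).
* `pulse_amp_mean`, `pulse_amp_sd` — per-beat pulse-wave amplitude (a.u.).
* `scr_rate_per_min`, `scr_amp_mean` — Poisson rate and exponential mean
  amplitude (µS) of skin-conductance responses.
* `tonic_level`, `tonic_drift_per_min` — skin conductance level (µS) and
  drift (µS/min).

The defaults encode the expected stress physiology: the negative (stress)
state shortens the R-R interval (0.72 s vs 0.80 s neutral), reduces
beat-to-beat variability, lowers pulse amplitude (0.55 vs 0.72), and raises
SCR rate (6/min vs 2/min), SCR amplitude and tonic level. The positive state
is a milder arousal response. Relax defaults to the neutral effect, but the
two are exposed independently because whether relax periods are
physiologically "neutral" is not knowable from published protocols.

### Why the R-R noise is coloured

A naive generator adds white Gaussian noise to each beat. That choice breaks
multiscale entropy on 60-s windows: a window holds only ~75 beats, so the
scale-5 coarse-grained series has ~15 points, and for white noise the
tolerance `r = 0.2 × SD(scale-1)` leaves so few template matches that
SampEn is undefined (no (m+1)-matches) on 40–80% of windows — real
recordings do not behave this way. Real tachograms concentrate their fast
variability in a quasi-periodic respiratory band; block-averaging cancels an
oscillation far faster than it cancels white noise, so coarse-grained real
tachograms are flat relative to `r` and matches are abundant. The generator
therefore colours the beat noise: a dominant narrowband respiratory
component (an AR(2) process with poles at 0.35 Hz), a small white component
and a small very slow AR(1) trend, mixed to the requested total SD
(fractions 0.96/0.22/0.14 of the SD). With this model fewer than ~3% of
windows have an undefined entropy at any scale, which the median-imputation
policy absorbs.

Two consequences are worth knowing. First, the slow trend inflates the
standard error of a window's mean R-R relative to the iid formula by about
1.33× (the package's tests use Monte-Carlo-derived bounds accordingly).
Second, within-window variance is mildly nonstationary, which is why the
spectral estimator detrends each Welch segment (below).

### Signal synthesis

* **ECG** — one template QRS complex (dominant 10-ms Gaussian R wave with
  small Q/S dips) centred at each cumulative beat time. Morphology beyond
  the R wave (P/T waves), motion artifacts and electrode noise are *not*
  modelled; detector tests on this ECG show that the event-time logic is
  right, not that the detector is robust to clinical-grade noise.
* **BVP** — one pulse per beat: a smooth time-warped sine-squared lobe
  (fast rise, slower decay) that returns exactly to baseline before the
  next onset. The smooth quadratic peak lets the detector recover the
  planted amplitude to ~1e-6 by parabolic interpolation; the flat
  pre-onset gap makes the onset minimum exact on the sampling grid.
* **GSR** — tonic level (relaxing exponentially toward each segment's
  target with a 20-s time constant, so conductance is continuous across
  boundaries) plus a Poisson train of Bateman-shaped SCRs
  (`exp(-t/τ2) − exp(-t/τ1)`, τ1 = 0.75 s, τ2 = 2.0 s, the conventional
  EDA modelling values) plus small Gaussian measurement noise
  (SD 0.005 µS).

## Preprocessing

* **Conditioning filters.** 4th-order Butterworth high-pass (1 Hz) and
  low-pass (40 Hz) sections in cascade for ECG and BVP, and a 2nd-order IIR
  notch (default 50 Hz, quality factor 30, unit DC gain) for powerline
  interference. All filters run forward–backward (zero phase) over
  reflection-padded input, so event times are not shifted and edges carry no
  transient. Note the 1-Hz high-pass sits close to the pulse fundamental
  (~1.2 Hz), so absolute BVP amplitudes after filtering are attenuated;
  amplitude *orderings* between states survive, and recovery studies bypass
  the filters (there is nothing to filter in noise-free data).
* **R-peak detection.** A derivative-energy detector in the Pan–Tompkins
  tradition: squared first difference, 150-ms moving integration, adaptive
  quantile threshold, 250-ms refractory period, then refinement to the
  largest absolute excursion within ±80 ms. Polarity is resolved by majority
  vote over the beat candidates, making detection invariant to amplitude
  scaling and electrode inversion.
* **Pulse detection.** Peaks above an adaptive threshold with a 300-ms
  refractory period; the onset is the preceding trough; amplitude is the
  parabolic-refined peak level minus the onset level; per-pulse width is the
  inter-onset interval.
* **GSR.** Downsampled to 4 Hz (anti-alias low-pass then interpolation onto
  the exact 4-Hz grid), then decomposed into tonic and phasic components.
  The tonic is a 31-s running median smoothed by an 8-s moving average; the
  phasic is the residual, so the two reconstruct the input exactly. SCRs are
  scored by sparse deconvolution: the lightly smoothed phasic trace is
  inverse-filtered by the discrete Bateman kernel, which concentrates each
  SCR into a localised impulse cluster; clusters whose calibrated amplitude
  reaches 0.02 µS become events. Deconvolution was chosen over peak-picking
  because overlapping SCRs at realistic stress rates (4–6/min) merge under
  peak-picking, capping count recovery near 85%; the deconvolving detector
  recovers ~95% of planted events at or above its amplitude floor. A
  convex-optimisation decomposition in the cvxEDA style was considered and
  rejected: no suitable sparse QP solver is available in the package's
  dependency budget, and the filter-based decomposition meets every
  recovery requirement placed on it.
* **Windows.** 60-s windows sliding in 1-s steps, half-open, fully inside
  their segment (windows never straddle a boundary, so every window has an
  unambiguous state label). A 240-s picture block yields 181 windows; the
  grid slides inside each segment separately, which is the only reading
  consistent with that count.

## The 39 features

Per window: 15 ECG features (MEANRR, SDNN, RMSSD, NN50, PNN50, HR; VLF, LF,
HF, LF/HF band powers; multiscale sample entropy at scales 1–5), 12 BVP
features (pulse rate, SDNN/RMSSD/MEANRR of the peak-interval series, LF and
HF power, mean inter-onset width, mean amplitude/width ratio, max/SD/mean of
pulse amplitude, mean absolute peak level) and 12 GSR features (tonic
mean/SD/area, phasic SD/area, SCR count, max/mean/SD of SCR amplitude,
mean/SD of rise time, total spectral power).

Conventions, chosen once and used everywhere:

* SDs are sample SDs (n−1), standard HRV practice; the SD of a single SCR
  amplitude or rise time is 0 by convention.
* NN50 counts successive differences strictly greater than 50 ms;
  PNN50 = NN50/(n−1).
* Spectral features: the R-R (or pulse-interval) tachogram is cubic-spline
  interpolated to 4 Hz and analysed by Welch averaging (32-s Hann segments,
  50% overlap, end-anchored final segment, *per-segment linear detrending*).
  Per-segment detrending matters: with a wandering baseline an undetrended
  tapered estimate measures local variance and can exceed the global
  variance bound. VLF on a 60-s window is below the resolvable band; it is
  computed anyway for completeness and should not be interpreted.
  The BVP "LF" band is 0–0.15 Hz (DC excluded), following the source
  convention for pulse-interval spectra; ECG uses 0.04–0.15 Hz.
* Sample entropy: `SampEn(m = 2, r = 0.2 × SD)`, Chebyshev distance,
  self-matches excluded, both template lengths counted over the first
  `n − m` templates; a constant series scores 0; the value is missing when
  no (m+1)-match exists. Multiscale entropy fixes `r` from the scale-1
  series. The implementation agrees with an exhaustive brute-force oracle to
  1e-10.
* GSR features are computed after per-subject z-standardisation of the
  tonic and phasic components (session-level), with SCR amplitudes rescaled
  by the phasic SD. Standardisation makes tonic means comparable across
  subjects (and negative values meaningful); `gsr_normalize = FALSE`
  restores raw microsiemens.
* `HIGH_BVP` is the mean absolute signal level at pulse peaks — related to,
  but distinct from, `MEANPA_BVP` (mean peak-minus-onset amplitude), so the
  two are not trivially collinear. `PR_BVP` is the pulse rate in beats/min,
  the rate analogue of `HR_ECG`. `AUCR_GSR` is the phasic area (also known
  as AUCP).
* Missing window values (too few beats, undefined entropy or spectral
  ratio) are imputed by the per-subject-per-segment median; a column more
  than 20% missing aborts extraction with a diagnostic.

## The three selection methods

**M3 — transition-based (the package's reason to exist).** For each feature
and each transition of the design (defaults: neutral→negative,
negative→neutral, neutral→positive), per-subject *before* and *after*
values are the feature's means over the full flanking segments; relax blocks
count as the neutral flank, which is how negative→neutral exists in a
protocol where every picture block is preceded by music. The paired
differences pass a Shapiro–Wilk normality gate (α = 0.05, applied to the
differences because that is what the t-test assumes); normal differences get
a paired t-test, others a Wilcoxon signed-rank test (zeros discarded, exact
distribution below n = 25, normal approximation with continuity correction
above). A feature is significant only if p < α in **all** transitions — a
conjunction that makes the method conservative (measured type-I rate well
below α). Zero-variance differences score p = 1.

**M1 — discrete-state baseline.** A Kruskal–Wallis test on the two groups
of per-subject segment means for each pairwise state comparison (the
two-group KW statistic is the standard resolution of "KW for paired
samples", which is a contradiction — KW is unpaired), significant only if
p < α in all three comparisons.

**M2 — PCA baseline.** Per-signal-group z-scoring followed by PCA, keeping
6 ECG, 5 BVP and 6 GSR components (17 total); component counts are inputs,
as no selection criterion for them is defined.

**Redundancy filter (M1 and M3).** Significant features are walked in the
canonical registry order; a feature is kept only if its absolute Pearson
correlation with every kept feature (over pooled window-level values) is
≤ 0.9. The rule is greedy and order-dependent by construction — reversing
the candidate order changes which of a correlated pair survives — so the
order is fixed once (registry order) and documented. Constant features have
undefined correlation and are kept with a flag.

The package also ships the published worked example
(`inst/extdata/table1.csv`): the printed significance/redundancy markers of
both methods over all 39 features. The bookkeeping reproduces the printed
counts — M1: 33 preliminary, 11 discarded, 22 final; M3: 17 preliminary,
4 discarded, 13 final (5 ECG + 4 BVP + 4 GSR). The printed table and the
surrounding text disagree on two GSR rows (the text names STDPR as
discarded where the table marks MEANPA/STDPA); the transcription follows
the table, whose totals match the published per-signal split.

## Classifier harness

Four classifiers (kNN with k = 5, CART decision tree, random forest with
100 trees, RBF-SVM with C = 1 and γ = 1/d — none of these hyperparameters
is prescribed by the source, so common defaults are exposed in
configuration), 10-fold cross-validation, features standardised with
training-fold statistics only, metrics (accuracy, macro recall, precision,
F1) computed per fold and averaged. Two fold modes exist for a reason:
`pooled_window` stratifies over windows, which is the protocol shape implied
by window-level matrices but lets one subject's windows appear on both sides
of a fold — every such report carries a leakage note; `grouped_by_subject`
keeps each subject in one fold and is the honest default for generalisation
claims. The binary stress task maps negative → stress and
neutral/positive → non-stress.

## What the tests do and do not show

The suite verifies, against planted truth and brute-force oracles: beat and
pulse recovery (≥ 99% sensitivity/precision at ±10 ms), noise-free parameter
recovery (HR to 0.5 bpm and MEANRR/MEANPA/tonic mean to 1e-6 on
uniform-state sessions — a pulse straddling a state boundary legitimately
mixes two amplitudes), SCR count recovery within 10% for planted events at
or above the detector's 0.02 µS floor, sample-entropy equality with an
exhaustive oracle, M3 type-I control (≤ 0.05; measured ≪ 0.05 because of
the all-transitions conjunction) and > 0.99 power at a planted 1-SD
transition effect with n = 85, chance-level accuracy on null features and
near-perfect accuracy on separable ones, redundancy-filter idempotence and
α-monotonicity of the significance sets.

Problem sizes are deliberately desk-scale: power/type-I studies run 200–500
replicates at the paired-sample level (signal synthesis is not needed
there); end-to-end runs use 1–12 subjects with 70–240 s segments. None of
this shows robustness to real-world artifacts — motion, electrode drift,
ectopic beats, nonstationary respiration — which the generator deliberately
does not model. Published classification accuracies from the original
85-subject study depend on recordings that were never released and are not
reproduction targets; the harness is validated on constructed cases with
known answers instead.

## Worked example

```{r example, eval = FALSE}
library(transfeat)

# simulate a small cohort on a shortened protocol and extract features
tl <- session_timeline(data.frame(
  label = c("relax", "neutral", "relax", "negative", "relax", "positive"),
  start_s = (0:5) * 70, end_s = (1:6) * 70))
cohort <- simulate_cohort(cohort_sim_config(n_subjects = 8, seed = 42,
                                            timeline = tl))
fm <- extract_feature_matrix(cohort)

# transition-based selection and the discrete baseline
transition_select(fm)
discrete_select(fm)

# the published worked example
tbl <- read_annotation_table(system.file("extdata", "table1.csv",
                                         package = "transfeat"))
selection_from_annotations(tbl, "M3")
```
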