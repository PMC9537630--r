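---
title: "P-wave morphology and POAF risk modelling: methods and design notes"
author: "PWaveAF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{P-wave morphology and POAF risk modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PWaveAF)
```

## The problem

New-onset atrial fibrillation after cardiac surgery (POAF) is common,
dangerous, and often transient enough to slip past routine postoperative
monitoring. Before fibrillation ever appears on the surface ECG, atrial
remodelling leaves subtle fingerprints on the P wave — the deflection
produced by atrial depolarisation. Longer and more *variable* P-wave
durations, and especially a large spread between the widest and narrowest
P wave of a recording (P-wave dispersion, PWd), mark atria with
heterogeneous conduction and a raised propensity to fibrillate.

PWaveAF implements a complete, testable version of this analysis for
long-term single-lead recordings: it synthesises ECG with known per-beat
ground truth and a matched two-group surgical cohort, conditions the
signal, delineates P waves at their isoelectric-line intersections,
computes seven per-patient P-wave parameters, reproduces the cohort
group-comparison statistics, and fits the clinical and clinical+ECG risk
models (logistic with ROC/AUC, and an RBF-SVM protocol with class-balanced
splits).

## The seven P-wave parameters

For each patient, every valid beat yields a duration $d_i$ (onset to
offset) and a peak time $q_i$ (onset to first peak), both in
milliseconds. The parameters are

$$\mathrm{Pmax} = \max_i d_i,\quad \mathrm{Pmin} = \min_i d_i,\quad
\mathrm{Pmean} = \bar d,\quad \mathrm{Pstd} = s_d,$$
$$\mathrm{PWd} = \mathrm{Pmax} - \mathrm{Pmin},\quad
\mathrm{Pptmean} = \bar q,\quad \mathrm{Pptstd} = s_q,$$

with $s$ the sample (n−1) standard deviation. The choice of the sample
rather than population SD is a documented decision (the source tables
print "SD" without qualification); it is what `stats::sd` computes and
what a statistician would do with per-beat samples. `PWd = Pmax − Pmin`
holds *exactly* by construction and is asserted, not assumed; its group
mean therefore equals the difference of the group Pmax and Pmin means
(linearity of the mean), which is the identity the acceptance checks
evaluate on the bundled group-summary table (167 − 105 = 62 ms no-POAF,
184 − 104 = 80 ms POAF).

## The synthetic data generator

No public recording accompanies the study conditions this package
emulates, so the generator is a first-class, tested module rather than a
fixture.

**Beat model.** Each beat is a sum of smooth lobes on an isoelectric
baseline: an asymmetric P wave built from two half raised-cosine lobes
(rise over a fraction `p_peak_fraction` of the width, fall over the
remainder), and symmetric raised-cosine QRS and T lobes. Raised cosines
were chosen over piecewise-linear shapes deliberately: they leave and
rejoin the baseline *tangentially*, which is exactly the geometry that
makes the "intersection with the iso-potential line" measurement rule
non-trivial, so the delineator is exercised on the hard version of the
problem. Defaults: 0.2 mV P amplitude, 1.0 mV QRS over 90 ms, 0.3 mV T
over 160 ms, RR 1000 ± 40 ms truncated at 300 ms.

**P-duration distribution.** Per beat, $d_i \sim
\mathcal N(\mu, \sigma)$ truncated at 40 ms (the floor prevents
degenerate zero-width waves). Per patient, $\mu$ and $\sigma$ are drawn
from the published between-patient structure: $\mu \sim \mathcal N(133,
23)$ ms (no-POAF) or $\mathcal N(141, 25)$ ms (POAF), and $\sigma$ from
the group Pstd summaries (15 ± 7 vs 19 ± 11 ms, truncated at 2 ms). This
reproduces the published group differences to first order: with ~60
beats measured, the expected extreme deviations $\mathbb E[\max_i d_i -
\bar d] \approx 2.3\sigma$ give Pmax ≈ 167/184 ms for the two groups,
matching the printed rows without any additional tuning. The first-peak
position is the group ratio Pptmean/Pmean (≈ 0.54), fixed per patient;
consequently peak-time spread is tied to duration spread
($\mathrm{Pptstd} \approx f\,\mathrm{Pstd}$), which understates the
printed Pptstd slightly — a documented simplification.

**Placement.** The P offset sits at a fixed PR segment before QRS onset
(pipeline default 70 ms), so duration variability moves the onset — the
physiologic direction for atrial conduction delay. The PR interval of a
template is `p_duration_mean` plus that segment. Colliding beats (long
durations at short RR) are truncated at the preceding T offset with a
warning, per the generator's overlap contract.

**Noise.** Three independent knobs: a sinusoidal baseline wander
(default 0.05 mV at 0.3 Hz), a powerline sinusoid (0.02 mV at 50 Hz) and
white Gaussian noise (0.01 mV). The source study never characterised its
noise environment beyond noting the long-term data "were not very
clean", so these amplitudes are free parameters chosen as a plausible
quiet ambulatory patch recording; tests that need exact ground truth use
all-zero noise, and the signal-to-noise-targeted helper
`whiteSdForSnr()` calibrates white noise to a stated SNR.

**Cohort.** The clinical table is drawn from the bundled per-variable
group summaries: normal continuous variables as Normal(mean, SD), binary
flags as Bernoulli(count/group n), and skewed operative times as
log-normal with the group median matched exactly and the IQR matched
through the log-scale quartile spread. Variables are drawn independently
within group because only marginal summaries are published; no joint
structure (e.g. age–GFR correlation) is emulated. This is the main
respect in which passing tests do *not* certify behaviour on real data:
real covariates are correlated, real P-wave variability is
autocorrelated in time, and real noise is neither stationary nor
Gaussian. What the synthetic cohort does certify is the *machinery*:
measurement accuracy against known truth, the statistical dispatch, and
the model protocols.

**Sampling rate.** 500 Hz by default (one sample = 2 ms), configurable
with a floor of 250 Hz; the recording device's true rate is not public,
and 500 Hz keeps millisecond-scale duration errors honest.

## Signal conditioning

The chain is low-pass, then high-pass, then smoothing — in that order.
Both filters are 4th-order Butterworth applied forward and backward
(zero phase), with reflect padding to suppress boundary transients;
defaults 40 Hz and 0.5 Hz bracket the ambulatory P-wave band. Zero-phase
application is what makes "correct filter delay" exact rather than
approximate: a passband tone emerges with its cross-correlation peak at
lag 0 (a tested invariant). Smoothing is a centred moving average,
default 20 ms (rounded to an odd sample count); `window = 0` is the
identity. The applied window is recorded in the signal's provenance
slot, which matters below.

## Delineation

**QRS anchors.** A derivative-energy detector (band-pass 5–22 Hz,
differentiate, square, 120 ms integration window) with an adaptive
threshold and a 200 ms refractory period finds R peaks; the QRS onset is
the isoelectric junction found by walking left from the R peak. A flat
record returns an empty annotation with a warning rather than an error.

**P-wave search.** Within a 350 ms window ending 40 ms before each QRS
onset (clipped to 420 ms after the previous R peak, so a previous beat's
T wave cannot masquerade as a P wave at short RR), the isoelectric level
is the median of the PR-segment samples, polarity is the record-level
median of each beat's dominant deflection sign, and the first peak is
the earliest local extremum reaching at least 60% of the window's
maximum deviation — "first", because a biphasic P wave's initial
component is the measured one.

**Edges.** A smooth wave approaches the baseline tangentially, so the
first crossing of a tolerance band (default 10% of the P amplitude)
necessarily lies *inside* the true wave; reading it off directly would
bias every duration short by 5–10 ms. The band crossing therefore only
initialises the edge. The refinement models the flank between the edge
and the peak as a half raised-cosine, passes each candidate template
through the same moving-average window the signal received (read from
the provenance slot), and minimises the least-squares misfit over the
flank samples up to 80% of the peak height, scanning candidate edges on
a quarter-sample grid. Under smoothing, first-differencing both flank
and template approximately whitens the correlated noise, keeping the
fit close to maximum likelihood. Beats with no crossing inside the
window, deviations under the 0.05 mV amplitude floor, or inverted
fiducial order are marked invalid, never guessed.

Measured performance on the package's own synthetic truth (fixed seeds,
320 s records, ~319 beats): on clean records ≥ 95% of durations fall
within ±2 samples of truth (the acceptance contract; the observed rate
is ~100%), and at 20 dB SNR the mean absolute duration error stays
under 4 ms. Error grows monotonically with white-noise amplitude — a
tested property, not an assumption.

**Quality control.** In place of the manual verification a human reader
would perform, rule-based QC drops beats with durations outside
[40, 400] ms or amplitudes below the floor, and flags the whole patient
as excluded when fewer than half the beats survive (threshold
configurable). Excluded patients are reported alongside the feature
matrix, mirroring how a handful of difficult recordings were dropped
before the published 94-patient machine-learning matrix.

## Group statistics

`compareGroups()` dispatches by declared variable kind — pooled-variance
two-sample t-test for normal continuous variables, Mann–Whitney U for
skewed ones, Pearson chi-square *without* continuity correction for
categorical variables, switching to Fisher's exact test when any
expected cell is below 5. Normality is declared per variable in the
spec table, not tested automatically, because the source analysis does
not state its normality test. Two decisions were validated against the
printed values rather than guessed: the *pooled* (Student) rather than
Welch t-test, and the *uncorrected* chi-square — the summary-statistic
battery reproduces every checkable printed p-value within ±0.005 (age
0.012, GFR 0.001, urea 0.012, Pmax 0.018, Pstd 0.031, PWd 0.008, sex
0.314), which a Welch test or Yates correction would not. No
multiple-testing correction is applied, matching the source analysis.
`ttestFromSummary()` is the oracle here: a pooled t computed from
(n, mean, SD) triplets that agrees with `t.test(var.equal = TRUE)` on
raw data to 1e-9 whenever the raw data have those summaries.

## Risk models

**Logistic.** The clinical model uses sex, age, left-atrial diameter,
GFR and mechanical ventilation time; the clinical+ECG model adds Pmax,
Pstd and PWd. Fits are maximum-likelihood `glm`, coefficients carry Wald
95% CIs, and (quasi-)separation is flagged while probabilities are still
returned. Mechanical ventilation time is a *postoperative* quantity used
as a predictor; the package keeps it, because the models being
reproduced do, but attaches a temporal-leakage note to every result that
includes it. AUC is the Mann–Whitney rank statistic with ties counted
one half (oracle-checked against the brute-force pairwise count), and
the 95% CI is DeLong's, the standard choice when none is stated.
On cohorts simulated with the published group differences, the
clinical+ECG model attains an AUC at least as high as the clinical model
in well over 80% of seeded replicates — a directional, not numeric,
reproduction of the published 0.86 vs 0.89, since the real patient data
are not available.

**SVM.** The protocol is: 7:3 split of the POAF class
(floor(0.7·28) = 19 train, 9 test), an equally sized class-0 training
draw (19), then either the full remainder as test (scheme A: 47+9) or a
class-balanced subsample (scheme B: 9+9). How 28 × 0.7 became 19 is
inferred from the printed counts (floor on the training side).
Features are z-scored with parameters fitted on the training set only —
not stated in the source but required for an RBF kernel to be
meaningful, and documented as a deviation. Hyperparameters (C, γ) are
tuned by stratified fivefold cross-validated grid search; grids default
to 6 log-spaced points per decade over C ∈ 10^[−2, 3] and γ ∈ 10^[−3, 2]
(the printed tuned values fall inside these ranges), with ties broken
toward smaller C then smaller γ. The whole protocol is deterministic
given data, grids and seed. Published test accuracies are not
reproduction targets: they depend on one realisation of a 94-patient
split of unavailable data; the package instead verifies the protocol's
behaviour on constructed cases (separable clouds reach ≥ 0.95 CV
accuracy; permuted labels sit at chance).

## Numerical and interface decisions

* Sample indices are 0-based and windows half-open; all exported times
  are milliseconds from record start.
* `Pmax` is taken over all valid beats of the analysis record; whether
  the original analysis averaged over discrete segments is unknown, so
  the record (or any window the caller passes) is the segment.
* Pstd/Pptstd are reported in ms even where the source prints them
  unitless.
* Seeds: every stochastic entry point takes an integer seed and restores
  the caller's RNG state; derived child seeds stay below 2^31.
* Degenerate inputs fail loudly and specifically: constant predictors,
  collinear designs, single-class outcomes, sub-Nyquist cutoffs,
  windows longer than the record, fewer than two valid beats.
* I/O: two-column CSV (`time_s,amplitude_mV`) and minimal single-signal
  WFDB format-16 records; annotations, cohorts, features and stats as
  CSV; model reports as JSON.

## Problem sizes used by the test-suite and scripts

Test records default to 1–2 minutes at 500 Hz and the accuracy contracts
run on ~320 s (~319-beat) records; the end-to-end recovery study uses 30
patients per group with 60 s clean records; the model-comparison
property uses 200 replicates of a 94-patient cohort at the feature
level. Record length is a free parameter everywhere — nothing in the
feature mathematics depends on it — so these sizes are a deliberate
choice of desk-scale defaults, with longer records available by
configuration.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- readPipelineConfig(system.file("extdata", "demo-config.yaml",
                                      package = "PWaveAF"))
res <- runPipeline(cfg)
res$stats[res$stats$variable %in% c("age_y", "pmax", "pwd"), ]
res$models$clinical_ecg$auc
```

## Known limitations

* The generator's beats are smooth unimodal lobes; notched, biphasic or
  low-amplitude pathological P morphologies are not emulated, and the
  flank-fit refinement assumes the unimodal shape it was designed for.
* Clinical covariates are drawn independently within group; odds ratios
  from multivariable fits on synthetic cohorts therefore reflect the
  marginal, not joint, structure.
* The published SVM test metrics and tuned (C, γ) values, and the
  published AUCs with their CIs, are properties of the original private
  cohort and are not desk-reproducible; the package reproduces the
  protocols and their directional behaviour instead.
* Powerline handling relies on the band-pass alone; no adaptive notch
  filtering is provided.
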