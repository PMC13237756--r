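---
title: "Methods: resting-state alpha power and Bayesian mixed-model topography"
author: "restalpha"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state alpha power and Bayesian mixed-model topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model, the statistical model, the synthetic-data generator that stands in
for human recordings, and the numerical and design decisions a maintainer
would want written down.

## The measurement chain

### Montage geometry

The default montage places the 64 recorded channels of a standard
64-channel cap plus the recovered online reference FCz on an idealized unit
sphere, constructed from the extended 10-20 scheme: midline electrodes at
18° steps along the nasion–inion great circle, an outer ring at 72° polar
angle, a lower ring at 90° for the 9/10-suffixed electrodes, and
intermediate rows by great-circle interpolation between the midline anchor
and the ring electrode of the same row. Spherical angles use theta measured
from the vertex and phi from the right-lateral axis toward the nasion, so
the Cartesian axes come out as ML = +right, AP = +anterior, IS = +superior,
each in [−1, 1] (unit radius; head-shape realism is out of scope). These
three coordinates are the continuous spatial covariates of the models: they
preserve the full topographic geometry instead of collapsing electrodes into
regional clusters. The montage ships as a plain-text fixture
(`inst/extdata/montage65.tsv`) and is rebuilt identically in code; which
spherical convention a given acquisition system uses is not standardized, so
the convention above is stated rather than inferred, and `readMontage()`
accepts any (label, theta, phi) table.

### Preprocessing

The stage order is fixed: average re-reference → 2-s segmentation →
artifact detection → channel rule → segment rule.

* **Reference recovery.** A cap referenced online to FCz records 64
  channels; FCz is recovered as an explicit zero channel *before*
  re-referencing — the only reading under which 65 electrodes enter the
  analysis. After re-referencing, the cross-channel mean is zero at every
  sample, and the operation is idempotent.
* **Artifact criterion.** Publications rarely state the inspection rule;
  the package uses conventional resting-EEG screening defaults — any sample
  above 100 µV absolute or any sample-to-sample step above 50 µV flags that
  (channel, epoch) cell — both configurable.
* **Channel rule.** A channel flagged in strictly more than 40% of epochs
  is replaced in *every* epoch by Hjorth Laplacian interpolation: the
  inverse-angular-distance weighted mean of its k = 4 nearest neighbors
  (weights normalized to sum 1), excluding neighbors themselves flagged in
  that epoch. Its flags are then cleared before the segment rule — clearing
  first maximizes retained data, consistent with retaining most of each 90-s
  recording. If every neighbor is flagged in some epoch, the unweighted
  neighbor mean is used there and the flag is kept, so the segment rule
  still sees the problem.
* **Segment rule.** An epoch with strictly more than 10% of sensors flagged
  is dropped. Both rules use strict inequalities because the thresholds are
  worded as "more than".

### Spectral estimation

2-s epochs give an exact 0.5 Hz grid, so the inclusive 8–13 Hz band holds
exactly 11 bins. Each channel-epoch is demeaned, tapered with a
split-cosine-bell covering 10% of the epoch (5% raised-cosine ramp per
edge; a "10% Hanning window" in acquisition-software parlance, and
configurable because that phrase is ambiguous — fraction 1 is a full Hanning
window), and Fourier transformed. One-sided periodograms are normalized so
their sum equals the population variance of the demeaned epoch under a
rectangular taper; taper power loss is compensated by dividing by the
taper's mean square, preserving the absolute-power (µV²) interpretation.

Averaging order: periodograms are averaged across epochs first, then each
bin is log10-transformed, then the band mean is taken ("log before the
band average"). The alternative — averaging log spectra across epochs, i.e.
a geometric mean — is exposed as `epochAverage = "log-power"`. Log base 10
is used throughout; units are log10(µV²). A zero-power bin inside the band
raises an error advising a configurable floor (default suggestion 1e-20
µV²) rather than silently producing −Inf.

### Split-half reliability

Retained epochs are partitioned by original temporal order into the first
⌈m/2⌉ and last ⌊m/2⌋ (the halves of the recording, not an odd/even
interleave), band power is computed per half, and Pearson r is taken
*across participants* for each electrode × condition — the only reading
under which a per-electrode correlation exists. Electrodes below r = 0.7
are flagged.

## The statistical model

All models are Gaussian linear mixed models on the long table (one row per
participant × electrode × eye condition; 130 rows per participant):

y = X b + u[participant] + e, with u_j ~ N(0, σ_u²) and e ~ N(0, σ²).

Coding: Group 0 = abstinent (reference), 1 = non-abstinent; Eyes 0 =
closed, 1 = open; Sleep on its raw 0–10 scale (uncentered — the
difference-over-observed-range summaries are raw-scale arithmetic);
ML/AP/IS as above. Interactions always include their non-redundant
lower-order constituents; the standard suite is Models 1–7 (main effects,
sleep × group, and its moderation by eyes or each spatial axis), and
exploratory four-way models are expressed through the same term builder
(e.g. `"Sleep x Group x Eyes x AP + ML * AP * IS"`).

Priors: fixed effects (including the intercept, since one prior family is
stated for b) get N(0, 10²) — weakly informative on the log10 scale, where
coefficients of magnitude above ~2 are already implausible; both variances
get inverse-gamma(0.001, 0.001). Half-t variance priors are a common
alternative; the conjugate choice keeps every full conditional exact.

### Sampler

A collapsed conjugate Gibbs sampler: (b, u) are drawn as one block — b from
its multivariate-normal conditional *marginalized over u* (the marginal
covariance σ²I + σ_u²ZZ' is block-diagonal per participant, so Woodbury
gives X'Σ⁻¹X from precomputed per-participant column sums), then u | b from
independent normals — followed by inverse-gamma draws of σ² and σ_u².
Sampling b jointly with u matters: participant-level covariates (Group,
Sleep) are nearly collinear with the random intercepts, and updating them
in separate blocks mixes an order of magnitude worse (effective sample
sizes of ~10 instead of ~4000 at 4 × 1000 kept draws). All per-iteration
work is O(p²J), independent of the row count.

Defaults: 4 chains × 2000 iterations with 1000 warmup, one master seed
(chain c derives its own seed from it). Chains initialize overdispersed:
b ~ N(0, 0.5²), σ and σ_u scaled by uniform multiples of sd(y). A design
with zero rows samples the prior, which the tests use to verify the prior
is what it claims to be. With the residual SD fixed and random effects
disabled the posterior is available in closed form, and the sampler is
checked against it.

### Summaries

Per coefficient: posterior median, equal-tailed 95% credible interval
(2.5th–97.5th percentiles), and PP = max(P(b > 0), P(b < 0)) as a
percentage, mapped to verbal strata — none (50), anecdotal (51–74),
moderate (75–90), strong (91–96), very strong (97–99), extreme (> 99) —
with boundaries resolved by rounding PP to the nearest integer percent.
Convergence is assessed by split-chain R-hat (pass threshold 1.01) and
effective sample size with Geyer initial-monotone truncation of the
chain-averaged autocorrelations (warning below 400), plus posterior
predictive checks on the response mean and SD.

Marginalized sleep slopes are the posterior of ∂E[alpha]/∂Sleep — for a
model linear in Sleep, the sum over Sleep-involved columns of the
coefficient times the remaining factors — evaluated per group and per
moderator stratum. Eye strata are closed/open (0/1). The spatial axes are
continuous, so "Left/Midline/Right"-style strata need a convention: the
15th, 50th and 85th percentiles of the corresponding coordinate in the
design, chosen to represent the flanks and center of the electrode
distribution without falling outside it. The difference over the observed
sleep range is slope × (max − min observed sleep), per draw.

## The synthetic-data generator

The generator emulates the study conditions: 32 participants (15 abstinent,
17 non-abstinent), sleep quality on integers 0–10 drawn from a discretized
normal centered at 6 with SD 2 *identically in both groups* (the analysis
regime of interest is groups that differ in alpha, not in sleep); abstinent
participants report 30–104 days since use, non-abstinent 1–13 days.
Log10 alpha power follows the linear predictor

beta0 + betaGroup·Group + (betaSleep + betaSleepGroup·Group)·Sleep +
betaEyes·Eyes + gammaML·ML + gammaAP·AP + gammaIS·IS + u + ε,

with defaults beta0 = 1.35, betaGroup = −0.36, betaSleep = −0.19,
betaSleepGroup = +0.14 (so the non-abstinent slope is −0.05), betaEyes =
−0.30, spatial gradients (+0.05, −0.15, +0.10) placing more alpha at right,
posterior and superior sites, σ_participant = 0.5 and σ_noise = 0.4 log10
units. The sleep-slope magnitudes are the regime the analysis is designed to
detect; the eyes-open reduction and the noise scales are stated assumptions
at values typical of resting EEG. Optional named coefficients add
higher-order terms (e.g. `c("Sleep:Group:AP" = -0.05)`).

**Tabular mode** emits the long table directly — the fast path for
inference testing. **Waveform mode** synthesizes raw 500 Hz, 90-s
recordings whose *measured* log alpha power (through the full preprocessing
and spectral chain) matches the same linear predictor. Alpha content is a
comb of equal-amplitude sinusoids at the 11 alpha bin centers with
independent random phase per channel per 2-s block, not a single 10 Hz
carrier: the band statistic is a mean of log bin powers, and a lone carrier
leaves 10 of 11 bins empty, making that mean undefined (or forcing absurd
amplitudes against a floor). Two exact calibrations make the round trip
close to within 0.02 log10 units: the phase-averaged own-bin power loss of
the analysis taper is cancelled analytically, and the expected power
shrinkage of the average reference (a channel loses ~1/n of its power to
the subtracted mean under independent phases) is inverted as a linear
system over channels. Scalp potentials are synthesized for all 65
electrodes and emitted referenced to FCz, matching the acquisition
convention. The 1/f background is spectrally shaped Gaussian noise
(power exponent 1, default 10 µV RMS); artifacts are square 250 µV
transients injected at random (channel, 2-s block) sites at rate 0.02 with
ground truth returned. The acquisition band limit (0.1–100 Hz online
filter) is emulated only as a limit on generated content — the alpha band
is far from both edges.

What the generator does *not* emulate: realistic ocular or muscle artifact
morphology, ICA-separable blink sources, non-sinusoidal or individually
varying alpha peaks, non-stationarity across the recording, or circadian
structure. Passing tests therefore show that the pipeline recovers what it
assumes, on data satisfying those assumptions — not that the assumptions
hold for human EEG.

## Numerical and robustness decisions

* Thresholds on the artifact rules are strict inequalities; boundary cases
  (exactly 40%, exactly 10%) are kept.
* Parseval checks are stated against the population variance (denominator
  n) of the demeaned epoch — the quantity the one-sided periodogram sums to
  exactly.
* `evidenceStratum()` rounds to the nearest integer percent before lookup,
  so 99.5% is "extreme" and 96.4% is "strong".
* Ocular correction: the stand-in is least-squares regression on an EOG
  reference (`eogRegress()`), not ICA; it is optional and off the default
  path.
* In cohort-level waveform runs, a participant whose recording is
  unrecoverable (all epochs rejected — possible when a genuinely
  high-amplitude subject exceeds the screening thresholds) is excluded with
  a logged message and a manifest entry rather than aborting the whole run;
  the single-recording functions still raise labeled errors.
* All randomness flows from one master seed through tagged derivations
  (stage + participant + condition), so stages are reproducible in
  isolation and whole runs are bit-identical on disk.

## Problem sizes used in the tests

The packaged tests run the full study geometry where it is cheap (65
electrodes, 32 participants, 4160 rows) and scale down only Monte-Carlo
settings: parameter recovery uses 20 replicate cohorts at 4 × 1500
iterations; null calibration uses 50 replicate cohorts at 2 × 1000; the
waveform reliability check runs the full 32-participant cohort once;
sampler-versus-closed-form checks use 500-row subsets. These sizes were
chosen so the whole suite completes in a few minutes while keeping each
check's Monte-Carlo error well inside its tolerance.

## Known limitations

* The montage is an idealized sphere; no individual head geometry or
  digitized positions.
* Only a minimal BrainVision dialect (multiplexed binary, IEEE float-32 or
  INT_16 with per-channel resolution) is read and written.
* No multitaper/Welch estimation, relative power, or individual alpha
  frequency detection; no HMC, model comparison (LOO/WAIC), random slopes,
  or non-Gaussian responses.
* Split-half reliability has no Spearman-Brown correction and no
  test–retest analogue across sessions.
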