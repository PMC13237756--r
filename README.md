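# restalpha

Resting-state EEG alpha power and its modulation by sleep quality,
abstinence status, eye condition and scalp position, in one reproducible R
pipeline.

## The problem

In clinical neurophysiology, alpha band power (8–13 Hz) during quiet rest is
a marker of cortical deactivation: it rises with relaxed wakefulness and eye
closure, and tracks sleep pressure. In people with cocaine use disorder,
both sleep and resting EEG rhythms are disrupted, and the relationship
between *subjective sleep quality* and alpha power may depend on whether a
person is currently using or recently abstinent. Testing that hypothesis
requires a chain of steps — artifact-managed spectral estimation per
electrode, then mixed models over thousands of electrode-level observations
— that is usually scattered across lab scripts. `restalpha` packages the
whole chain for a 64-channel cap (65 electrodes after recovery of the online
reference FCz), two 90-s eye conditions at 500 Hz, and a cohort of abstinent
and non-abstinent participants, together with a synthetic-data generator
that emulates the study conditions so every stage is testable end to end.

## What it computes

**Preprocessing.** Average re-reference (recovering FCz as a zero channel),
2-s segmentation, threshold artifact detection (absolute 100 µV,
sample-to-sample step 50 µV, both configurable), Hjorth Laplacian
interpolation of channels bad in strictly more than 40% of segments, and
rejection of segments with strictly more than 10% bad sensors.

**Spectral estimation.** Tapered-FFT periodograms on the clean 2-s epochs
(split-cosine-bell tapering 10% of each epoch, power-loss compensated),
averaged across epochs; alpha power is the mean of log10 bin power over the
11 bins with 8 ≤ f ≤ 13 Hz, in log10(µV²). Split-half (first vs second half
of the recording) Pearson correlations per electrode and condition report
internal consistency.

**Modelling.** Each electrode is encoded by continuous Cartesian axes
derived from its spherical montage angles — ML (left→right), AP
(back→front), IS (bottom→top) — and the long table (130 rows per
participant: 65 electrodes × 2 eye conditions) is fit with Bayesian Gaussian
linear mixed models with a participant random intercept:

```
Model 1:  alpha ~ Group + Eyes + ML * AP * IS
Model 2:  alpha ~ Sleep + Eyes + ML * AP * IS
Model 3:  alpha ~ Sleep * Group + Eyes + ML * AP * IS
Model 4:  alpha ~ Sleep * Group * Eyes + ML * AP * IS
Model 5-7: alpha ~ Sleep * Group * {ML, AP, IS} + Eyes + ML * AP * IS
```

with weakly informative priors b ~ N(0, 10²) on fixed effects and
inverse-gamma(0.001, 0.001) on both variances. A from-scratch collapsed
conjugate Gibbs sampler (fixed effects drawn marginally over the random
intercepts) yields posterior medians, 95% credible intervals, the posterior
probability PP = max(P(b>0), P(b<0)) mapped to evidence strata (none /
anecdotal / moderate / strong / very strong / extreme), marginalized sleep
slopes within group and moderator strata (eyes at closed/open; electrode
axes at their 15th/50th/85th percentiles), differences over the observed
sleep range, split-chain R-hat, Geyer-truncated effective sample sizes, and
posterior predictive checks.

## Worked example

```r
library(restalpha)

layout <- buildDefaultLayout()          # 65-electrode extended 10-20 montage
params <- genParams(seed = 42)          # study-condition generative defaults
cohort <- generateCohort(15, 17, params)
tab    <- generateAlphaTable(cohort, layout, params)
nrow(tab)                               # 4160 rows = 32 participants x 130

fit <- fitModel(tab, model = 3, chains = 4, iterations = 2000,
                warmup = 1000, seed = 42)
summarizePosterior(fit$draws, c("Sleep", "Sleep:Group", "Eyes"))
#>     parameter      median       lower       upper      pp     stratum  rhat  ess
#> 1       Sleep -0.16775998 -0.31392802 -0.02658774  98.975 very strong 1.000  3912
#> 2 Sleep:Group  0.09835979 -0.08746226  0.28989277  84.650    moderate 1.000  3995
#> 3        Eyes -0.29275275 -0.31772700 -0.26810992 100.000     extreme 1.000  4000

marginalSlopes(fit$draws, fit$design, model = 3)[, c("group", "slope",
                                                     "lower", "upper", "pp")]
#>           group      slope      lower       upper     pp
#> 1     Abstinent -0.1677600 -0.3139280 -0.02658774 98.975
#> 2 Non-Abstinent -0.0709915 -0.1989798  0.05590214 87.475
```

The `Sleep` coefficient is the sleep-quality slope of log10 alpha power in
the abstinent (reference) group — here recovered near its generative value
of −0.19 with "very strong" evidence of a negative sign — while the
marginal-slope table shows the flat non-abstinent relationship (generative
−0.05). `Eyes` is the eyes-open alpha reduction. For raw-EEG simulation, use
`mode = "waveform"`:

```r
res <- runPipeline(pipelineConfig(mode = "waveform", models = 3, seed = 1),
                   "out/")
median(res$reliability$r)   # split-half consistency across electrodes
```

which writes `alpha_power.tsv`, `reliability.tsv`, `model_*.json`,
`marginal_slopes.tsv` and `manifest.json`. A thin CLI wrapper is installed
at `inst/scripts/alpha-pipeline.R` (verbs `simulate`, `run-all`).

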