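Package: restalpha
Title: Resting-State EEG Alpha Power and Bayesian Mixed-Model Topography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for resting-state EEG alpha band power
    analysis: synthetic cohort and multichannel waveform generation, average
    re-referencing with recovery of the online reference channel, 2-s epoch
    segmentation, threshold artifact detection with Hjorth Laplacian channel
    interpolation and segment rejection, tapered-FFT spectral estimation of
    log10 alpha (8-13 Hz) band power per electrode, split-half reliability,
    and Bayesian Gaussian linear mixed models with participant random
    intercepts fit by a conjugate Gibbs sampler. Posteriors are summarized as
    medians, 95% credible intervals, sign posterior probabilities with verbal
    evidence strata, marginalized sleep slopes within group and moderator
    strata, and effect differences over the observed covariate range, with
    split-chain R-hat, effective sample size, and posterior predictive
    checks. Includes a minimal BrainVision-dialect reader and writer and a
    config-driven pipeline orchestrator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), coda, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'geometry.R'
    'montage.R'
    'synthetic.R'
    'preprocess.R'
    'spectral.R'
    'reliability.R'
    'design.R'
    'gibbs.R'
    'diagnostics.R'
    'summaries.R'
    'brainvision.R'
    'pipeline.R'
    'utils.R'
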