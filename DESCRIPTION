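Package: rippletools
Title: Multi-Scale Ripple Detection and Spike-Field Synchrony Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and statistical characterization of transient 80-120 Hz
    ripple oscillations recorded simultaneously at the macro-scale (intracranial
    EEG) and micro-scale (microelectrode-array local field potentials), together
    with the single-unit spiking activity that accompanies them. Provides
    regression-based line-noise removal, local detrending, quartile-based trial
    rejection and transient-artifact masking; Morlet time-frequency power and
    high-frequency-activity measures; Hilbert-envelope ripple detection with
    strict and relaxed threshold presets and a 1/f-referenced narrowband episode
    detector; pairwise phase consistency (PPC) spectra with Rayleigh tests,
    trial-shuffle z-scoring and cluster-based sign-flip permutation statistics;
    event cross-correlograms with shift predictors and circular-shift nulls;
    a Hartigan dip test on binned densities; restricted maximum-likelihood
    random-effects meta-analysis of correlation effect sizes; and a synthetic
    multi-scale session generator with full ground truth for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    MASS,
    metafor,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite
Config/testthat/edition: 3
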