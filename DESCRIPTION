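Package: somatomap
Title: Efficiency-Optimized Event-Related Designs and Fingertip pRF Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping fingertip tactile tuning in sensorimotor cortex
    with functional MRI. Implements generation and efficiency optimization of
    fast and slow event-related (ER) stimulation sequences, contrast-efficiency
    computation on canonical and FIR design matrices, simulation of somatotopic
    BOLD timeseries with ground-truth Gaussian fingertip population receptive
    fields (pRFs), phase-encoded (traveling-wave) Fourier analysis with
    coherence-based inference, a two-step GLM (FIR deconvolution, participant
    HRF estimation, fingertip amplitude estimation), Gaussian pRF fitting with
    recentered ROI tuning curves, and cortical magnification distances on a
    voxel grid. The full pipeline runs on simulated data, so every stage is
    testable without any imaging-data download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
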