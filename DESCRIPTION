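Package: drgt2map
Title: Simulation and Analysis of Dorsal Root Ganglion T2 Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative T2 relaxometry of the lumbosacral dorsal
    root ganglia (DRG): extended-phase-graph (EPG) simulation of multi-echo
    spin-echo (CPMG) acquisitions, B1-inhomogeneity-corrected voxelwise T2
    estimation by dictionary matching alongside log-linear and nonlinear
    mono-exponential baselines, digital DRG phantoms with known ground truth,
    volume-of-interest extraction of DRG T2 and volume, synthetic patient
    cohorts emulating a Fabry-disease study design, intraclass-correlation
    reliability analysis, and the nonparametric statistical battery used for
    cohort comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    minpack.lm,
    nortest,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
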