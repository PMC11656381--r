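Package: specdecon
Title: Baseline Correction, Peak Detection and Profile Decomposition for
    Spectroscopic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless engine for one-dimensional spectroscopic signal
    analysis (Raman, IR, UV-vis, powder XRD). Provides interpolation onto
    uniform grids, moving-window denoising, baseline estimation by a
    straight line or by penalized least squares with adaptive (airPLS) or
    asymmetric (arPLS) reweighting, peak detection by window propagation
    over second-derivative candidates, decomposition of detrended signals
    into sums of Gaussian, Lorentzian or Voigt profiles under robust
    least-squares losses, and Miller-index assignment for tetragonal
    diffraction patterns via Bragg's law. Includes a synthetic-spectrum
    generator with ground truth for validation and a command-line pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'faddeeva.R'
    'spectrum-io.R'
    'preprocess.R'
    'baseline.R'
    'peakfind.R'
    'profiles.R'
    'decompose.R'
    'xrd.R'
    'synthgen.R'
    'pipeline.R'
    'show-methods.R'
    'specdecon-package.R'
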