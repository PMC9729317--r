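Package: PupilKit
Title: Photoreceptor-Targeted Light Stimulation and Pupillometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated, hardware-free toolkit for pupillometry with
    spectrally tuneable multiprimary light stimulation. Provides spectral
    data types with alpha-opic irradiance, photopic illuminance,
    chromaticity and blue-light-hazard weighted radiance computations; a
    simulated ten-primary, 12-bit light engine with JSON stimulus
    ("video") files and a simulated spectrometer; calibration of the
    engine by per-channel intensity sampling, interpolation lookup tables
    and beta-CDF linearisation; alpha-opic irradiance matching of target
    spectra by bounded least squares and local optimisation; light-onset
    timestamping from camera frame streams by two-frame differencing;
    preprocessing of pupil recordings (eye selection, blink and
    confidence masking, interpolation, zero-phase Butterworth smoothing,
    trial extraction and baseline normalisation); pupillometer-style
    parametrisation of the pupillary light reflex (PLR) and summaries of
    the post-illumination pupil response (PIPR); and synthetic
    ground-truth generators for pupil traces, camera streams and full
    recording sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    signal
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PupilKit-package.R'
    'spectrum.R'
    'weighting.R'
    'photometry.R'
    'engine.R'
    'calibration.R'
    'hazard.R'
    'matching.R'
    'preprocess.R'
    'metrics.R'
    'stamper.R'
    'synthetic.R'
    'session.R'
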