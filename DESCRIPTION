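Package: ventsfc
Title: Ventricle Volume and fNIRS Functional Connectivity in Preterm Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bedside-monitoring analysis pipeline linking lateral-ventricle
    volumes from 3D cranial ultrasound to spontaneous functional connectivity
    (sFC) measured with multichannel fNIRS in preterm neonates with
    germinal matrix-intraventricular hemorrhage. Implements windowed signal
    quality metrics (scalp coupling index, peak spectral power), contiguous
    best-subsample selection, spline motion-artifact correction, modified
    Beer-Lambert conversion to hemoglobin concentrations, nuisance
    regression with Fourier and polynomial drift terms plus global signal,
    robust-correlation connectivity, and three incremental |sFC|/VV slope
    estimators (per-patient OLS, linear mixed effects, LME with gestational
    age). A synthetic-cohort generator emulates the statistical structure of
    the study data for parameter-recovery and calibration experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
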