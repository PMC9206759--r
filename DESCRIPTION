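Package: cmsaw
Title: Covariance-Matrix Statistical Adaptive Weighting for Minimum-Variance Ultrasound Beamforming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Synthetic transmit aperture (STA) ultrasound beamforming toolbox.
    Implements delay-and-sum (DAS), minimum-variance (Capon) beamforming with
    spatial/temporal smoothing and diagonal loading, eigenspace-based MV,
    coherence-factor and generalized-coherence-factor pixel weighting, and the
    covariance-matrix mean-to-standard-deviation-ratio weights CMSF and CMSAW
    built from adaptive spatial smoothing, rotary averaging, and (adaptive)
    diagonal reducing.  Ships a Field-II-style point-scatterer simulator for
    speckle/cyst/point phantoms and image-quality metrics: lateral -6 dB FWHM,
    contrast ratio, generalized contrast-to-noise ratio (gCNR), and speckle SNR.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
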