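Package: musclemech
Title: Muscle Fiber Mechanics, Cross-Bridge Kinetics and Cardiac Physiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis toolkit for small-amplitude sinusoidal
    analysis of striated muscle fibers (complex modulus extraction, work and
    power spectra, three-process Nyquist-model fitting with apparent rate
    constants 2*pi*b and 2*pi*c), large-amplitude work-loop energetics,
    Michaelis-Menten and linear dose-response fits (actin-activated ATPase,
    f_max versus ATP and phosphate), M-mode cardiac metrics for the
    Drosophila heart tube (diastolic/systolic diameter, fractional
    shortening, heart period, systolic interval), flight behavior indices,
    and salt-bridge classification on atomic coordinates.  A stochastic
    two-state cross-bridge ensemble simulator and a set of parametric
    generators produce every input the pipeline consumes, so the full
    analysis chain is testable without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    minpack.lm,
    bio3d,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
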