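Package: genpol
Title: General Compact-Polarimetric SAR Simulation and Delta-Alpha/Alpha
    Target Decomposition for Crop Monitoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for general compact-polarimetric (CP) synthetic aperture
    radar analysis. Synthesizes CP observations for an arbitrary transmit
    polarization ellipse (orientation and ellipticity angles) from quad-pol
    scattering matrices, including the classic pi/4 and circular-transmit
    linear-receive (CTLR) modes; computes the delta-alpha/alpha target
    decomposition for full-pol and CP data; provides boxcar and Lee speckle
    filtering, a fully developed speckle scene simulator with per-class
    scattering-mixture covariances and a six-date rice phenology schedule,
    difference-degree feature ranking, RBF-SVM classification with
    producer's/user's accuracy and kappa reporting, and transmit-ellipse
    separability sweeps and phenological trajectory analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'utils.R'
    'general-cp.R'
    'decomposition.R'
    'classify-phenology.R'
    'genpol-package.R'
    'polsar-io.R'
    'show-methods.R'
    'speckle.R'
    'synthetic-scenes.R'
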