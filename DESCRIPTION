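Package: keelmetry
Title: Radiographic Keel Bone Morphometry and Damage Association Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for longitudinal radiographic bone morphometry in laying
    hens: line-profile optical density proxies (tibiotarsal mid-shaft and
    cranial keel), keel spline geometry (length, mid-depth, cranial depth and
    the length to mid-depth ratio), dissected-keel ordinal damage scoring with
    localization-to-extent recoding, maximum-likelihood polychoric and
    polyserial correlations, per-age damage regressions (linear, logistic and
    right-censored Poisson) and pelvic-dimension interaction models. A
    synthetic layer generates bone phantom radiographs with analytic ground
    truth and simulated flocks with latent-normal ordinal scores, censored
    fracture counts and body-weight-correlated pelvic dimensions, so the whole
    pipeline is verifiable without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    mvtnorm,
    png,
    tiff
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
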