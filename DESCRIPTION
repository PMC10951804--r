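Package: kammetrics
Title: Moment-Based Rotationally Invariant Similarity Metrics for Cryo-EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Alignment-free similarity metrics for molecular structures based
    on the rotation-invariant low-order moments used in Kam's method of
    moments for single-particle cryogenic electron microscopy (cryo-EM). The
    package computes Fourier-space spherical harmonic expansions of 3D
    density maps or atomic models, the analytic first and second moments of
    their projection images under uniform or bandlimited nonuniform
    viewing-angle distributions, and empirical moments from noisy,
    CTF-affected particle image stacks. Two metrics are provided: a
    volume-to-volume distance between uniform-density moments, and an
    image-stack-to-volume distance that eliminates the unknown viewing-angle
    distribution by linear least squares. A synthetic cryo-EM simulator
    (nonuniform von Mises-Fisher poses, radial CTF bank, white noise at
    fixed SNR) and a database-search layer with NDCG ranking evaluation
    support nearest-neighbor structure matching experiments end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
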