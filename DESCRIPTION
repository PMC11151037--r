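Package: rheoCT
Title: Quantitative Analysis of In Situ Loaded Cartilage and Meniscus Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for quantitative analysis of time-resolved
    synchrotron phase-contrast micro-CT of articular cartilage and meniscus
    under in situ unconfined compression. Provides image-quality metrics
    (Fourier-criterion spatial resolution, SNR, CNR), depth-resolved
    chondrocyte density profiles, 3D collagen fiber orientation by the
    structure gradient tensor, stress-relaxation mechanics (instantaneous
    and quasi-equilibrium moduli, relaxation ratios, Poisson's ratio,
    aggregate modulus), radiation-dose estimation for rotating soft-tissue
    cylinders, and scan-to-scan repeatability analysis. Includes a synthetic
    phantom generator (fiber phantoms, cellular cartilage phantoms,
    standard-linear-solid loading curves, repeated-scan pairs) with known
    ground truth so every analysis stage is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
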