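Package: pactherm
Title: Photoacoustic Tomography Thermometry and Photothermal Therapy Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale computational pipeline for ring-array photoacoustic
    computed tomography (PACT) thermal monitoring of photothermal therapy
    (PTT). Provides synthetic ring-array radio-frequency data generation from
    digital absorption phantoms, half-time delay-and-sum image reconstruction
    via precomputed sparse projectors, RF conditioning (impulse-response
    deconvolution, low-pass filtering), motion-mitigating frame selection and
    rigid image registration, Grueneisen-relation photoacoustic thermometry
    with CEM43T50 thermal dosimetry, exponential-rise heating-kinetics
    analysis, and a voxel Monte Carlo photon transport plus Pennes bioheat
    finite-difference simulator for comparing submerged and open-air
    photothermal treatment configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
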