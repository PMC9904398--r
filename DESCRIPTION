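Package: activesed
Title: Sedimentation of Run-and-Tumble Squirmer Suspensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sedimentation in suspensions of active
    microswimmers. Provides a resolved-particle D3Q19 lattice-Boltzmann
    simulator of squirmers with run-and-tumble reorientation between no-slip
    walls, a hydrodynamics-free run-and-tumble reference simulator, and a
    steady-state drift-diffusion (Smoluchowski) solver with a height-dependent
    effective temperature driven by fluid velocity fluctuations. Includes the
    measurement toolkit for sedimentation studies: density profiles and
    exponential sedimentation-length fits, steady-state detection from the
    mean-height series, near-wall crystalline layering, supernatant metrics,
    and joint elevation-orientation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
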