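Package: frickeirt
Title: Monte Carlo Track Chemistry of the Fricke Dosimeter Under Carbon-Ion Irradiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of the radiolysis of aerated Fricke and
    Fricke-cystamine solutions by high-energy carbon ions (6-500 MeV per
    nucleon, LET ~9.3-248 keV/um). A parametric track-segment generator
    emulates the 1-ps nonhomogeneous species distribution along an ion
    track; an independent-reaction-times (IRT) engine samples pairwise
    first-passage reaction times and pseudo-first-order scavenging to
    propagate the intratrack chemistry to microsecond handoff; an analytic
    pseudo-first-order cascade continues the homogeneous chemistry to 200 s.
    Computes time-dependent and 200-s ferric-ion yields G(Fe3+) as functions
    of LET, cystamine concentration and the multiple-ionization channel,
    with per-reaction yield decompositions, concentration scans and
    provenance-complete replication.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    tidyr,
    rlang,
    Matrix,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
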