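Package: frickesim
Title: Monte Carlo Track Chemistry of Fricke and Fricke Gel Dosimeters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of the radiation chemistry of the ferrous
    sulfate (Fricke) dosimeter and its gel analogues. Generates nonhomogeneous
    spur and cylindrical-track distributions of water radiolysis species at
    1 ps, evolves them through the nonhomogeneous stage with the independent
    reaction times (IRT) method, hands off to deterministic pseudo-first-order
    bulk kinetics, and follows the ferric ion yield G(Fe3+) from 1 ps to 200 s.
    Supports linear energy transfer (LET) effects via track geometry and
    uniform Stokes-Einstein viscosity scaling of diffusion coefficients, with
    rate constants repartitioned into activation and diffusion components.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
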