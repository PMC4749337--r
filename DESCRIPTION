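Package: indivobs
Title: Individual Colorimetric Observer Modelling and Observer-Population
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physiologically parameterised cone fundamentals for individual
    human observers, extending the CIE 2006 physiological observer with eight
    inter-observer deviation parameters (lens and macular pigment densities,
    peak optical densities and lambda-max shifts of the L, M and S cone
    photopigments).  Provides Monte Carlo simulation of observer populations,
    metameric colour-match and Rayleigh-match simulation, variance pooling of
    literature standard deviations, a two-scalar fit of the parameter standard
    deviations to colour-matching data, and population standard-deviation
    prediction with two-sample F tests.  Reference basis tables are shipped as
    clearly labelled synthetic stand-ins built from published analytic
    templates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
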