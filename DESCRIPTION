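Package: drykin
Title: Distributed Reactivity Modelling of Isothermal Dehydration Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for isothermal mass-loss (dehydration) experiments
    recorded at several fixed operating temperatures, built around the distributed
    activation energy model (DAEM) of parallel first-order reactions. Provides
    model-free (integral and Friedman differential) isoconversional estimation of
    the effective activation energy as a function of conversion, derivation of the
    experimental density distribution of activation-energy counterparts, fitting of
    Extreme (Gumbel), Lorentz (Cauchy) and Log-normal peak families as well as a
    discrete binomial reactivity model, forward simulation of conversion curves
    from a fitted distribution, kinetic compensation-effect analysis, and a
    synthetic-data generator emulating multi-temperature oven drying of plant
    specimens with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
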