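Package: anisogamy
Title: Disruptive-Selection Models for the Evolution of Gamete Dimorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Game-theoretic and population-genetic models of the evolution of
    anisogamy by disruptive selection (gamete competition). Provides the
    Levitan-type and threshold gamete/zygote survival functions, closed-form
    and numerical evolutionarily stable strategy (ESS) analysis of gamete
    sizes with a brute-force invasion oracle, a haploid two-mating-type
    simulator of gamete-size evolution under selection, stepwise mutation and
    multinomial drift, an extension with a gamete-motility locus that yields
    anisogamy, pseudooogamy or oogamy depending on the cost of motility, a
    volvocine-algae species table with volume-adjustment rules and the
    anisogamy-ratio test against the predicted threshold of three, cost-of-sex
    calculations, and synthetic species-table generators with
    parameter-recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
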