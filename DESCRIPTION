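Package: rovesim
Title: Monte Carlo Simulation of Roving Versus Mate-Guarding Tactics in
    Socially Monogamous Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based Monte Carlo model of the reproductive payoff of a
    paired male that leaves his territory to seek extra-pair copulations
    (a "rover") in a tile-based population of mate-guarding residents,
    roving residents, unpaired wandering males and, optionally, unpaired
    females. Each simulated male scores reproductive success as
    R = E + I - C (extra-pair copulations gained, intra-pair copulations
    retained, cuckoldries suffered) over four forays of three sequential
    encounter attempts each. The package sweeps the payoff over the
    prevalence of roving, the prevalence of wandering, and population
    size, and post-processes replicate outcomes with one-sample t-tests
    against the mate-guarding baseline, Benjamini-Hochberg false
    discovery rate correction, histogram summaries, and detection of the
    roving level at which extra-pair success overtakes intra-pair
    success. An exhaustive enumeration oracle provides exact expectations
    on miniature populations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
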