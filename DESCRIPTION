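Package: moswo
Title: Multiobjective Spider-Wasp Optimization for Benchmarks and Drug Regimen Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiobjective variant of the spider-wasp optimizer: bio-inspired
    variation operators (searching, following/escaping, nesting, mating), an
    external non-dominated archive truncated by crowding distance, and a linear
    population-reduction schedule.  Ships the ZDT and DTLZ benchmark families
    with analytic Pareto-front samplers, the IGD, hypervolume and spread quality
    indicators, a seeded multi-run benchmark campaign driver, and a drug-therapy
    design layer that scores dose-regimen decision vectors (dose, dosing
    interval, co-drug dose, duration) against efficacy, safety and cost
    objectives fitted to a pharmacokinetic/pharmacodynamic patient cohort,
    including a synthetic cohort generator with a dose-exposure-response
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
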