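Package: gutsim
Title: Agent-Based Simulation of Bacterial Population Dynamics on the
    Ileal Wall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-time stochastic agent-based simulator of four bacterial
    genera (Bifidobacterium, Bacteroides, Clostridium, Desulfovibrio)
    competing for carbohydrate metabolites along a 1x100-element
    discretization of the ileal wall under unidirectional luminal flow.
    Colonies adhere to and escape the mucus layer, consume discrete
    metabolite units, reproduce on fixed doubling times, and wash out at the
    distal boundary. Includes scripted perturbation scenarios (probiotic
    dosing, altered glucose diet, constipation, diarrhea), replicate
    ensembles with 95% confidence intervals, percent-difference-from-control
    summaries, steady-state and extinction detection, and YAML/CSV
    input-output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
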