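Package: invivomca
Title: In Vivo Metabolic Control Analysis of Microbial Production Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in vivo metabolic control analysis (MCA) of microbial
    fed-batch production processes. Provides a reduced stoichiometric model of
    Escherichia coli central carbon metabolism and L-cysteine biosynthesis,
    constraint-based flux estimation (flux balance analysis, loopless flux
    variability analysis, and thermodynamics-based flux analysis),
    thermodynamic classification of reactions, elasticity estimation by the
    thermokinetic affinity model and lin-log regression from short-term
    perturbation experiments, control-coefficient algebra with Monte Carlo
    uncertainty propagation, bioprocess rate/selectivity/carbon-balance
    calculations, and a synthetic perturbation-experiment generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
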