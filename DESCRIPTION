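Package: optcoupleR
Title: Growth-Coupled Strain Design by Joint Knockout, Insertion and
    Medium Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based prediction of growth-coupled production strains
    for genome-scale metabolic models. Implements the OptCouple approach: the
    growth-coupling potential (the drop in maximal growth rate when the target
    production reaction is blocked) is maximized over combinations of native
    reaction knockouts, heterologous reaction insertions and growth-medium
    supplements by a single-level mixed-integer linear program obtained from
    the natural bi-level formulation via LP duality and big-M linearization.
    Includes flux balance analysis, LP dualization, heterologous-pool
    reachability pruning, solution-pool harvesting with no-good cuts, design
    minimization, merging and verification, and production-envelope analysis.
    Models are read from COBRA JSON or SBML (fbc); linear and mixed-integer
    programs are solved with the HiGHS solver through SciPy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: python3 with scipy (HiGHS backend)
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
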