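Package: cytotwin
Title: Digital-Twin Simulation of Cytarabine Consolidation Scheduling in AML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation study of white-blood-cell (WBC) dynamics
    during acute myeloid leukemia (AML) consolidation therapy. Couples a
    Friberg-type transit-compartment model of granulopoiesis with cytarabine
    (Ara-C) pharmacokinetics/pharmacodynamics, a two-compartment leukemic
    blast submodel, and lenograstim (G-CSF) kinetics. Provides virtual
    cohorts of digital twins, enumeration of the 334-setting treatment grid
    comparing Ara-C given on days 1,2,3 (AC-123) versus days 1,3,5 (AC-135),
    extraction of recovery-time (kpiL) and blast-ratio (kpiB) indicators,
    per-twin parameter fitting, and a Wei-Lin-Weissfeld marginal Cox
    comparison with cluster-robust variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    survival,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
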