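Package: contamscreen
Title: Contaminant Screening for Low-Biomass Subseafloor Amplicon Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies likely contaminant reads in 16S rRNA amplicon surveys of
    low-biomass subseafloor samples, such as scientific ocean drilling cores.
    Builds an order-level contaminant database from negative-control samples
    (drilling-associated and laboratory controls versus seawater and drilling
    fluids), screens query ASV tables against it, and reports per-sample read
    fractions labelled as potential contaminant, seawater influenced, endemic,
    below threshold, or unassigned. Ships a reference database of common
    drilling and laboratory contaminant orders, plus a Dirichlet-multinomial
    community simulator with ground truth so the whole pipeline can be
    exercised and validated without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
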