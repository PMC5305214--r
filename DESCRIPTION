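Package: replicount
Title: Replisome Stoichiometry and Lifetime Analysis by Single-Molecule
    Photobleaching
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Counts fluorescently tagged replisome subunits in living
    bacteria by photobleaching-step analysis and measures replisome complex
    lifetimes by rule-based focus tracking. Intensity traces are idealized
    with a Monte-Carlo calibrated, parameter-free change-point filter; the
    unitary fluorophore step is inferred from the power spectrum of the
    pairwise difference distribution of idealized levels; copy numbers are
    the ratio of the fitted initial intensity to the unitary step. Complex
    lifetimes are right-censored at the observation window and the
    disassembly rate is estimated by closed-form censored-exponential
    maximum likelihood. A synthetic-data generator provides ground truth
    for every stage (bleaching traces, focus image stacks, censored
    lifetimes, stoichiometry mixtures).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    survival,
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
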