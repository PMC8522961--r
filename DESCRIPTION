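Package: dntmix
Title: Dose-Response, Benchmark-Dose and Mixture Synergy Analysis for In
    Vitro Developmental Neurotoxicity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in vitro developmental neurotoxicity (DNT)
    screens of single chemicals and defined chemical mixtures. Implements
    solvent-control normalisation and variable-slope four-parameter logistic
    fitting with inhibitory-concentration (ICx) inversion, a continuous
    benchmark-dose (BMD) framework with bootstrap BMDL/BMDU bounds, LOAEC
    determination by one-way ANOVA with Dunnett many-to-one comparisons,
    endpoint-anchored mixture design tables with two-fold serial dilutions,
    Toxic-Unit scoring under concentration addition with a two-criterion
    synergistic/interactive classification, Pearson-correlation attribution
    of mixture effects to single chemicals, and multi-electrode array (MEA)
    spike, burst and network-burst analytics. A synthetic-data module
    generates dose-response tables, concentration-addition mixtures with
    optional injected interaction, and Poisson spike trains with known
    ground truth, so the whole pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    multcomp,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
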