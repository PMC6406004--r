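Package: ergkit
Title: Simulation and Analysis of Electroretinogram Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale electroretinography (ERG) studies: a
    parametric generator for synthetic ERG traces (a-wave, b-wave,
    oscillatory potentials, Naka-Rushton intensity scaling), a cohort
    simulator for genotype-by-treatment designs with streptozotocin-style
    hyperglycemia, extraction of a/b-wave amplitudes and implicit times
    from averaged traces, isolation of oscillatory potentials by 25 Hz
    high-pass filtering with b-wave-normalized RMS scoring, a split-plot
    (two-way mixed) ANOVA with Bonferroni post-hoc comparisons, and Monte
    Carlo evaluation of type-I error and power for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
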