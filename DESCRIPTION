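Package: delink
Title: Differentially Expressed Links in Backbone Functional-Coupling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects condition-specific rewiring of a backbone
    functional-coupling interactome from replicated two-condition
    time-course expression data. Classifies backbone edges as
    condition-enabled, condition-sensitive, condition-resistant or
    developmental links from split-condition Pearson correlations combined
    with three-way (gene by day by treatment) analysis of variance,
    estimates a permutation false discovery rate, discovers network modules
    enriched in differentially expressed links, computes day-1 seed linkage
    statistics, and builds a temporal GO-to-GO "meta-flow" enrichment
    network that traces day-by-day propagation of a perturbation signal
    across biological processes. Includes a synthetic-data generator that
    emulates the replicated 5-day two-condition design, scale-free
    backbones, planted condition-specific links and planted temporal
    propagation for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    car,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
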