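Package: betasort
Title: Gating Simulation and Sort-Timing Analysis for Stem Cell-Derived
    Islet Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and simulating marker-based cell sorting of
    stem cell-derived islet preparations. Provides a log-normal mixture
    simulator of event-level cytometry data emulating end-of-stage-6
    SC-islet composition, quantile summaries of labeled populations, the
    relative position index quantifying alpha/beta overlap on a sorting
    channel, sort-window selection across the stage-6 time course,
    deterministic gate simulation (top-fraction, fixed-threshold and
    positive/negative split gates, composable sequentially) with purity,
    yield and enrichment accounting, exact nonparametric replicate
    statistics (Wilcoxon signed-rank, Mann-Whitney), and readers/writers
    for CSV event tables, a subset of FCS 3.0/3.1, and JSON/TSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
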