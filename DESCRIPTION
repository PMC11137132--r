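Package: baitform
Title: Differential Bait Peptidoform Analysis for IP-MS Open-Search Data
Version: 0.1.0
Authors@R:
    person("Baitform", "Developers", email = "baitform@example.org",
           role = c("aut", "cre"))
Description: Detects differentially present bait peptidoforms from
    immunoprecipitation mass-spectrometry (IP-MS) experiments searched with an
    open (wide precursor tolerance) database search. Peptide-spectrum matches
    are aggregated into peptidoforms keyed by peptide sequence and delta mass
    rounded to one decimal, bait spectral counts are normalized to the
    smallest sample within each comparison, singleton peptidoforms are
    filtered, and differential presence is scored with a SAINTexpress-style
    AvgP/BFDR model (external binary or a built-in Poisson surrogate).
    Additional tooling covers protein coverage on the longest isoform,
    peptide position maps, delta-mass annotation against known modifications
    and amino-acid substitutions (including fixed-modification displacement),
    hierarchical clustering of peptidoform profiles, and a seeded synthetic
    open-search PSM generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
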