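Package: tidegem
Title: Sex-Biased Metabolic Task Scoring and Context-Specific Models for
    Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sex-dimorphic metabolism with genome-scale
    metabolic models (GEMs). Implements gene-protein-reaction (GPR) rule
    parsing and evaluation, flux balance analysis and weighted flux-sum
    minimization on a built-in linear-programming solver, permutation-based
    metabolic task scoring from differential expression (TIDEs),
    transcript-guided context-specific model extraction with flux sampling
    in the style of RIPTiDe, and downstream between-sex comparison
    statistics (reaction presence and uniqueness, exchange-flux tests, and
    adverse-event report rate analyses). Includes generators for toy GEMs,
    sex-labeled expression matrices with planted subsystem effects, and
    synthetic adverse-event report tables so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
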