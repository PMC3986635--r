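Package: metaconsim
Title: Diversity-Driven Metagenome Read Simulation and Multi-Method
    Taxonomic Assignment Consistency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates shotgun metagenome read sets from a target Shannon
    diversity (H') with a dominance cap, a rarefaction-curve design step and
    a 454-style error model (point substitutions plus homopolymer-run
    edits), and evaluates the consistency of taxonomic read assignments
    across multiple classification methods.  Includes an NCBI-dialect
    taxonomy loader with canonical-rank projection and lowest-common-
    ancestor computation, a BLAST-tabular LCA assigner, a naive Bayes k-mer
    classifier, epsilon-cutoff and BLAST-combination post-processing,
    per-rank agreement classification and consensus calling, truth-based
    sensitivity/precision tables, read-length versus consistency curves
    with threshold-length estimation, and epsilon-sweep summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
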