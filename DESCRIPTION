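Package: gmci
Title: Gut Microbiome Cancer Index and Case-Control Microbiome-Metabolome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control profiling of the gut microbiome and fecal
    metabolome in cancer cohorts. Reads species-level taxonomic count tables
    (merged Bracken reports or plain count matrices), computes alpha diversity
    (Shannon) and compositional beta diversity (centered log-ratio PCA with
    PERMANOVA), selects directed marker species by Mann-Whitney tests with
    Benjamini-Hochberg correction, and summarises each sample by a gut
    microbiome cancer index: the log2 ratio of the detected fraction of
    control-associated marker species to the detected fraction of
    case-associated marker species. Also compares short-chain fatty acid and
    amino acid panels between case groups and healthy controls in
    concentration and proportion-of-total modes, correlates taxa with
    metabolites (Spearman, Ward clustering into modules), and simulates
    seeded case-control cohorts with planted effects for power and error
    control studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    withr,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
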