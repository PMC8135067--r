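Package: ovatome
Title: Comparative Ovary Transcriptomics and Follicle Morphometry for
    Two-Condition Ascidian Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for comparing ovary transcriptomes and
    histology between two conditions (e.g. a neuropeptide-gene mutant versus
    wildtype) in the ascidian Ciona intestinalis. Implements PCR-duplicate
    removal from single-end reads by a prefix-identity plus whole-read
    similarity rule, FPKM quantification with strict expression (FPKM > 5)
    and fold-ratio (> 2 / < 0.5) differential calls, a pseudo-count
    regularized signed enrichment score for Gene Ontology terms compared
    between condition-specific gene sets and rendered on the 'is_a' graph,
    ovarian follicle stage classification and per-mm2 section morphometry,
    and delta-delta-Ct relative quantification of qPCR data. A synthetic-data
    module generates every pipeline input with known ground truth so all
    stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
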