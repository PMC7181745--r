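Package: tribekit
Title: Target Identification for HyperTRIBE RNA-Editing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies RNA-binding-protein targets from HyperTRIBE (RBP-ADAR
    fusion) RNA-seq experiments. Converts variant calls into strand-consistent
    A-to-I edit-site candidates, models per-site edit frequencies with a
    beta-binomial distribution, tests fusion-versus-control and one-cell-type
    -versus-rest differential editing with likelihood-ratio tests under
    FDR control, aggregates significant sites into gene-level targets,
    selects an edit-site clustering window by motif enrichment, and measures
    distances from edit sites to position-weight-matrix motif occurrences.
    Includes a synthetic-experiment generator so the full pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
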