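Package: sangermab
Title: Full-Length Monoclonal Antibody Sequencing from Sanger Clone Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational layer of a two-step Sanger workflow for
    full-length monoclonal antibody sequencing from hybridoma cells:
    clustering and consensus calling of clone reads, detection of aberrant
    (non-productive) immunoglobulin chains, CDR3 junction localisation and
    lightweight V-(D-)J germline assignment, DNA-level mouse IgG subclass
    calling from CH1 sequence motifs, CDR3-anchored primer design with
    in-silico 3' RACE amplicon prediction, strain-level constant-region
    comparison, and MALDI-TOF peptide-mass-fingerprint verification of CDRs
    at the protein level. Ships a deterministic synthetic-fixture generator
    that emulates clone read sets, full antibody mRNA architectures, and
    MALDI peak lists with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
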