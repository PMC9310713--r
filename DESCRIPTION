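Package: srnaphase
Title: Processing Accuracy and Phasing Analysis of Artificial Small RNA
    Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for small RNA sequencing experiments with
    artificial small RNAs (amiRNAs and syn-tasiRNAs): collapsing of
    identical reads, exact (mismatch- and gap-free) mapping of unique
    reads to both strands of precursor and target references,
    per-position count and RPM profiles, quantification of precursor
    processing accuracy around the expected mature 5' end, guide and
    star strand accumulation, and 21-register phasing analysis of
    target-derived secondary siRNAs downstream of the sRNA-guided
    cleavage site. Includes a generative simulator of art-sRNA
    biogenesis (accurate and imprecise precursor processing, star
    strands, degradation, background, and phased secondary siRNAs with
    configurable phase fidelity) that emits ground-truth labels and
    closed-form expectations for every pipeline statistic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
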