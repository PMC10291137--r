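Package: pdxplore
Title: Cross-Species Multi-Omics Comparison of Patient Tumors and
    Patient-Derived Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing patient tumor samples across disease
    timepoints (diagnosis, relapse) with matched patient-derived xenograft
    (PDX) models. Provides k-mer based partitioning of xenograft sequencing
    reads into graft, host, both, neither and ambiguous classes; somatic
    variant filtering on read support, allele fraction and population
    frequency with Jaccard-distance sample comparison; copy-number segment
    categorization (amplification, focal amplification, gain, loss,
    deletion) and gene-level annotation; multi-caller gene-fusion consensus
    with junction-read validation; separation of tumor-cell expression from
    microenvironment expression using the PDX human fraction, and
    construction of a cross-species microenvironment matrix via orthologs;
    principal-component selection with variance and species-separation
    rules plus loading-based preranked gene-set enrichment; proteomics
    missingness filtering with iterative-PCA imputation; and exponential
    doubling-time estimation from tumor growth curves. A synthetic-data
    generator with recorded ground truth makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
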