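Package: promevo
Title: Promoter Element Content and Evolutionary Divergence of Housekeeping
    and Tissue-Specific Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes promoters of housekeeping and tissue-specific genes
    from a transcript-by-tissue FPKM matrix and promoter FASTA sequences.
    Classifies genes as housekeeping (detected in all tissues, uniform
    expression by a Kolmogorov-Smirnov test, within a fourfold range of the
    tissue average, all isoforms concordant) or tissue-specific (expressed in
    at most three tissues); scans promoters for CpG islands (windowed
    observed/expected CpG rule), perfect short tandem repeats, potential
    G-quadruplex-forming sequences and degenerate IUPAC consensus motifs; and
    estimates evolutionary rates (Nei-Gojobori dN, dS and dN/dS with a
    codon-bootstrap Z-test of selection, and the promoter substitution rate dP
    under pairwise deletion). A seed-deterministic synthetic-data generator
    with recorded ground truth supports end-to-end validation, and a pipeline
    driver produces per-class BED annotations and Mann-Whitney
    group-comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    withr
Config/testthat/edition: 3
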