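Package: haircutr
Title: Single-Cell DNA Repair Activity Profiling from Hairpin Substrate Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of droplet-based single-cell DNA repair
    ("Haircut") experiments, in which polyadenylated DNA hairpin substrates
    carrying defined lesions are incised by repair enzymes in single-cell
    extracts and read out by sequencing. Extracts and corrects cell barcodes
    and UMIs from read 1, trims template-switch and polyA sequence from read 2,
    places reads on the hairpin references by exhaustive forward-only ungapped
    alignment, deduplicates UMIs with directional adjacency clustering, and
    assembles sparse cells-by-(substrate, position) incision count matrices.
    Downstream tools compute log-normalized repair-activity scores, per-group
    incision position profiles, pairwise rank tests, threshold-based genotype
    calls for knockout cell-mixing experiments, classification evaluation
    (confusion tables, TPR/FPR, random baseline, read-downsampling
    sensitivity), empty-droplet background profiles, and droplet-chemistry
    estimates of substrate molecules per drop. A seeded simulator generates
    paired FASTQ files with complete ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
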