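Package: kmernb
Title: Incremental Naive Bayes Taxonomic Classification of Metagenomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An incrementally updatable naive Bayes taxonomic classifier for
    shotgun metagenomic reads. Per-species models store raw k-mer counts in
    independent savefiles, so new genomes and new species can be added -- and
    reclassified species merged -- without reprocessing any previous training
    data, with results exactly identical to batch retraining. Includes Laplace
    (add-one) smoothed log-likelihood scoring of reads, NCBI taxonomy
    trace-back for accuracy at higher ranks, memory-capped batch scheduling,
    rank-level abundance profiling with Bray-Curtis drift between model
    versions, a genome-level cross-validation and yearly-snapshot evaluation
    harness, and a synthetic taxonomy/genome/read simulator for testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
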