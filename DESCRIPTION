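Package: waspcomp
Title: Comparative Genomic Computations for Parasitoid Wasp Genome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implements, as a tested pipeline, the desk-scale computations
    used in draft-genome studies of parasitoid wasps: genome-size estimation
    from 17-mer depth spectra and from propidium-iodide flow-cytometry channel
    ratios, windowed GC content and CpG observed/expected ratios, assembly
    contiguity statistics (N50), best-reciprocal-hit orthology with an
    aligning-ratio times identity similarity score, microsynteny block
    detection under an anchor-count and gene-gap rule with consensus
    gene-order summaries, and the all-tools consensus intersection of miRNA
    target predictions.  A synthetic-data module generates inputs with planted
    ground truth (Markov-chain genomes with controlled CpG depletion, Poisson
    k-mer spectra with an error-k-mer noise component, Gaussian flow-cytometry
    peaks, paired gene orders with planted ortholog blocks, reciprocal hit
    tables, and overlapping target-prediction sets) for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    withr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
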