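Package: tfregnet
Title: Multi-Evidence Inference of Transcription Factor Target Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers transcription factor (TF) to target gene (TG) regulatory
    networks by integrating four evidence layers: co-expression of TFs and
    candidate targets across perturbation experiments, promoter binding-site
    (TFBS) content in conserved regions, chance-corrected annotation
    similarity (Cohen's kappa), and curated interaction evidence. Candidate
    genes are selected by differential-expression filters across two-group
    perturbation experiments, grouped by fuzzy clustering via local
    approximation of membership (FLAME), and each TF-TG pair is scored with
    an integrated Score, cluster-pair Support and a ranked Confidence.
    Includes a seeded synthetic-data generator with planted regulatory
    modules for end-to-end benchmarking, network export to SIF/GraphML, and
    validation utilities (binomial overlap tests, known-pair rank reports,
    edge-recovery metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
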