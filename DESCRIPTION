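Package: consensr
Title: Consensus-Query Ligand-Based Virtual Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based virtual screening with consensus queries built
    from several known active molecules. Implements five consensus
    policies (single, opportunist max-of-scores fusion, pessimist AND
    fusion, optimist OR fusion, realist bit-frequency fusion and the
    potency-weighted knowledgeable fusion), Tanimoto similarity for
    binary and real-valued fingerprints, three 2D fingerprints (MACCS
    166 bits, ECFP4 2048 bits and an unfolded MOLPRINT2D variant built
    on SYBYL atom types), early-enrichment and global performance
    metrics (ROC AUC, power metric, accumulated-actives curves), and
    retrospective, CPU-bounded and potency delta-rank screening
    experiments, plus a synthetic fingerprint data generator for
    self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
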