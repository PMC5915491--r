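Package: gstrw
Title: Two-Tier Global-Similarity Random Walks for miRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate microRNA-disease associations on a pair of
    similarity networks. miRNA functional similarity is fused with miRNA family
    membership, global network similarity is obtained from a graph-Laplacian
    smoothing closed form, restart random walks propagate optimized disease
    seeds over the miRNA network and optimized miRNA seeds over the disease
    network, candidate pairs are scored by Pearson correlation between the
    stationary walk distributions and global-similarity profiles, and the two
    tiers are fused by a mixing weight. Includes leave-one-out, orphan-disease
    and new-miRNA evaluation protocols with in-house ROC/AUC and
    precision-recall, a block-structured synthetic data generator, labeled-TSV
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
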