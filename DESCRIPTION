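Package: linaprs
Title: Multi-Task Linearizing Neural Networks for Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Parallel estimation of polygenic risk scores for many binary
    disease traits with a multi-task linearizing neural network (MTL LINA):
    an attention subnetwork makes the model exactly linear in the genotypes
    given the attention vector, so per-SNP importance scores and per-pair
    interaction scores are model-wise exact rather than sampled
    approximations. Includes a single-task feedforward baseline, decoy-SNP
    false-discovery-rate estimation for importance thresholds, Spearman
    genetic correlation between traits over FDR-selected SNP sets, PLINK1
    binary genotype input/output, and a liability-threshold cohort simulator
    with tunable pleiotropy for end-to-end evaluation without biobank access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
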