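Package: claudinlow
Title: Multi-Omic Stratification of Claudin-Low Breast Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stratifies claudin-low breast tumors into three copy-number
    related subgroups (CL1/CL2/CL3) from multi-omic inputs. Implements
    expression normalization (TPM conversion, per-batch median Z-scores,
    probe collapsing), fraction-of-genome-altered (FGA) computation from
    segmented copy-number profiles, tumor-purity gating by rank-test
    equalization, BAF/LRR verification of focal hemizygous losses,
    univariate Gaussian finite-mixture stratification of FGA with BIC model
    selection, a nearest shrunken centroid expression classifier with
    cross-validation, Signal2Noise-preranked GSEA and single-sample GSEA
    scoring, methylation-expression correlation filtering with differential
    methylation calling, and a synthetic multi-omic cohort generator with
    truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
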