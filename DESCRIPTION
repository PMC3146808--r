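Package: pathsig
Title: Oncogenic Pathway Activity Signatures for Fresh-Frozen and FFPE
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds gene expression signatures of oncogenic pathway activity
    (RAS/MYC-style two-class designs) by Bayesian probit regression on SVD
    metagene factors fitted with a latent-variable Gibbs sampler, and predicts
    posterior pathway-activity probabilities for new samples. Includes
    microarray quality-control metrics (percent present, 3'/5' control ratios,
    MAS5-style scaling factors, scaled log2 percentile summaries), matched
    versus unmatched whole-genome correlation and clustering analyses for
    paired fresh-frozen/FFPE designs, a per-patient concordance rule for
    lesion-level predictions, and a parametric simulator of training sets,
    xenograft pairs and patient lesions with an FFPE RNA-degradation model, so
    the full pipeline can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
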