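Package: ddibalance
Title: Balance-Regularized Semi-NMF for Signed Drug-Drug Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community detection and cold-start link prediction on signed
    drug-drug interaction (DDI) networks, where edges carry an enhancive (+1)
    or degressive (-1) pharmacological polarity. Implements weak structural
    balance diagnostics (triad census, community balance index, within- and
    between-community interaction-ratio differences, sign-shuffle null
    models), a balance-regularized semi-nonnegative matrix factorization
    (BRSNMF) with multiplicative updates alongside a plain Semi-NMF baseline,
    and a cold-start pipeline that maps binary drug features (for example
    drug-binding-protein profiles) into the latent community space by partial
    least squares regression to score enhancive and degressive interactions
    for drugs with no known DDIs. Includes planted-partition generators for
    signed networks and community-linked binary features, rank-based
    evaluation (AUROC, AUPR, mean percentile ranking, top-n accuracy),
    drug-level cross-validation, readers and writers for edge-list and
    feature-table text formats, and a small command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    mclust,
    mixOmics,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
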