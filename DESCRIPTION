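Package: grnkit
Title: Gene Regulatory Network Inference, Integration and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers gene regulatory networks from steady-state expression
    matrices with six complementary algorithms: relevance (co-expression)
    networks, shrinkage graphical Gaussian models, CLR (context likelihood
    of relatedness), GENIE3 tree-ensemble regression, TIGRESS stability
    selection, and a bounded-order, order-independent constraint-based
    causal learner with Fisher-z conditional-independence tests. Ranked
    edge lists from any subset of methods are combined by Borda-count rank
    aggregation and scored against gold-standard edge lists with
    DREAM-style AUPR/AUROC and directionality metrics. Additional tools
    cover subnetwork queries, reciprocal-best-hit ortholog mapping and
    metagene construction for cross-species network comparison, chi-square
    annotation-term enrichment, and a linear-Gaussian synthetic benchmark
    generator with known ground truth. A command-line interface exposes
    the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    splines,
    parallel,
    MASS,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
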