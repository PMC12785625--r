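Package: hetmix
Title: Mixed-Cell Models of Inter-Patient Tumor Heterogeneity for Drug
    Combination Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for building transcriptomic "mixed-cell" models of
    inter-patient tumor heterogeneity and for evaluating drug combinations
    in heterogeneous cell mixtures. Bulk tumor expression profiles are
    purified by non-negative least-squares deconvolution against a
    cell-type signature matrix, integrated with cell-line profiles under
    empirical-Bayes batch correction, and clustered with Ward's method to
    assign a representative cell line to each patient cluster. Drug
    combinations are scored under the principle of independent drug action
    from monotherapy viability tables, mixed-cell co-culture growth is
    simulated with shared-capacity logistic kinetics and Hill
    dose-response, and well-level growth areas are analyzed with
    normalized growth ratios, exact Mann-Whitney U tests, Bliss
    independence synergy scores, and a mixture-versus-aggregated efficacy
    comparison. A seeded synthetic-data generator emulates patient
    cohorts, cell-line panels, monotherapy screens, and co-culture
    experiments so that every stage of the pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    fgsea,
    glmnet,
    jsonlite,
    pracma,
    stats,
    sva,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
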