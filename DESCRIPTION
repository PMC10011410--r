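Package: cptriage
Title: Cell-Painting Profiling and Cell-Health Triage of Cytotoxic and
    Nuisance Compounds
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for triaging cytotoxic and nuisance compounds
    from cell-painting morphological profiles and companion cell-health
    readouts. Implements per-plate robust z-score normalization against
    vehicle (DMSO) wells, correlation-based redundant-feature removal, a
    Mahalanobis-distance activity score computed in a truncated principal
    component space with a sample-weighted pooled covariance, vehicle-derived
    activity cutoffs (mean + 3 SD), hierarchical phenotype clustering with
    (1 - Pearson) distances and Ward linkage, cluster phenotype signatures and
    signature-correlation matching, uncentered scaled PCA embeddings,
    dendrogram entanglement, concentration-response cluster trajectories,
    trapezoid AUC summarization of live-cell imaging time courses with
    reagent-free background correction, and glutathione (GSH:GSSG)
    quantification from luminescence standard curves. A seeded synthetic
    plate-data generator with ground-truth labels supports end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
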