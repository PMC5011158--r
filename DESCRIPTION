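Package: flavoqsar
Title: Charge-Weighted 3D Descriptors and Stepwise QSAR for P-Glycoprotein
    Modulation by Flavonoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for ligand-based prediction of P-glycoprotein (P-gp)
    modulation by flavonoids. Implements partial-equalization (PEOE) sigma
    charges, Hueckel-type pi charges and lone-pair electronegativities as
    per-atom property channels; property-weighted radial distribution
    function (RDF) and 3D autocorrelation descriptors with a 1252-name
    descriptor registry; the pFAR activity transform; a three-stage
    descriptor-selection cascade (marginal correlation filter, pairwise
    redundancy filter, stepwise multiple linear regression with partial-F
    entry and removal); leave-one-out q2 validation; and the published
    six-descriptor pFAR equation with its inhibitor/inducer classification
    rule, together with the printed training and external-set fixtures.
    A seeded synthetic-data module generates planted descriptor matrices
    and random point-cloud molecules so every stage of the workflow is
    testable without external inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR
Suggests:
    ChemmineOB,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
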