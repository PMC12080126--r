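Package: ensdock
Title: Ensemble Docking and Multilabel Screening for Partially
    Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for structure-based screening of small-molecule
    binders against the weighted conformational ensembles of partially
    disordered proteins.  Provides ensemble containers with statistical
    reweighting of biased simulations, per-residue structural analytics
    (fluctuations, radius of gyration, solvent-accessible surface area,
    ligand distances), selection of AlphaFold-derived inter-residue
    distance restraints with evaluation of the metainference restraint
    energy, filtering and clustering of transient binding pockets,
    adapters around an external docking engine with a deterministic mock
    scorer, percentile-based activity labelling of docking energies, a
    multilabel feed-forward neural network surrogate for docking scores
    with Matthews-correlation model selection, fraction-of-sites
    screening of compound libraries, and multibinding hit-rate analysis.
    Synthetic-fixture generators emulate every input so the full
    pipeline runs and is tested without external data or engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
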