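Package: afmi
Title: Structural Ensembles of Disordered Proteins from AlphaFold-Derived
    Distance Restraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts AlphaFold distogram, PAE and pLDDT output into filtered
    inter-residue distance restraints and samples coarse-grained multi-replica
    Langevin dynamics under a Bayesian metainference energy combined with
    parallel-bias well-tempered metadynamics. Produces reweighted structural
    ensembles of disordered and partially disordered proteins together with
    validation statistics: pairwise distance distributions P(r), radius of
    gyration, polymer scaling exponent and Kullback-Leibler divergences.
    Includes a synthetic-fixture generator so the full pipeline runs without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    yaml,
    seqinr,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
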