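Package: admixkit
Title: Hierarchical Dissection of Admixed Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing population structure and selection in
    recently admixed cohorts. Infers locus-specific continental ancestry on
    phased haplotypes with a hidden Markov model, masks genomes into
    per-ancestry "virtual genomes", resolves within-continent substructure
    with a subspace PCA that tolerates massive individual-specific
    missingness, dates the admixture event from ancestry-block counts under
    a hybrid-isolation model, and scans each ancestral component for recent
    positive selection with an ancestry-aware integrated haplotype score
    (iHS). A synthetic-cohort simulator (Balding-Nichols differentiation,
    haplotype-copying linkage disequilibrium, Poisson ancestry switching,
    founder-copy selective sweeps, segment-level mask corruption) makes
    every stage testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
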