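Package: repairSurv
Title: Proliferation-Adjusted Survival Analysis of DNA Repair Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Candidate-gene survival analysis for DNA repair pathways in
    tumor RNA-Seq cohorts. Expression of repair genes is rank-normalized
    (van der Waerden scores) and adjusted for age at diagnosis, pathological
    stage, and the PCNA proliferation metagene by linear residualization.
    Adjusted genes are screened with median-binarized Kaplan-Meier logrank
    tests, the significant set is summarized by the best binarized
    varimax-rotated principal component, and that statistic is judged
    against a randomization null built from same-size random repair-gene
    sets. Also computes genomic event rates (pathogenic mutations, GISTIC
    -2 deletions, GISTIC +2 amplifications) per gene-tumor for driver and
    pathway gene groups and clusters cancers by UPGMA on Euclidean
    distances. A synthetic cohort generator reproduces the assumed data
    structure (latent proliferation factor, confounding, proportional
    hazards, censoring) so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    SummarizedExperiment,
    S4Vectors,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
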