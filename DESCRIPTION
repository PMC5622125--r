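Package: msapDiff
Title: Differentiation of DNA Methylation from Methylation-Sensitive
    Amplified Polymorphism (MSAP) Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale analysis of global DNA methylation
    assayed by methylation-sensitive amplified polymorphism (MSAP) with the
    HpaII/MspI isoschizomer pair, and for efficiency-corrected relative
    quantification of gene expression by RT-qPCR. Converts two-enzyme band
    presence/absence patterns into methylation types I-IV, classifies
    methylation-susceptible loci (MSL), quantifies among-group differentiation
    by AMOVA with a permutation test on Phi_ST, ordinates samples by principal
    coordinates analysis, tests single loci with Fisher exact tests under
    Benjamini-Hochberg FDR control, and orders significant loci by UPGMA
    clustering of categorical Gower distances. The qPCR side implements the
    2^-ddCq method with per-primer efficiency correction, two-reference-gene
    normalization, propagated errors, Student t tests and Storey q-values.
    Includes seeded generators of synthetic MSAP and qPCR data with known
    ground truth for power analysis and pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Genetics, GeneExpression, qPCR
RoxygenNote: 7.3.3
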