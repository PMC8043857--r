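Package: tauLT
Title: Latent-Trait Reduction of Graded Tau Neuropathology with
    Quantitative-Trait Genetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits Samejima's graded response model to semi-quantitative
    (ordinal 0-3) tau pathology scores across brain regions and lesion
    types, scores cases on the latent severity scale by expected a
    posteriori (EAP) estimation, and ranks regions by Fisher item
    information. The latent-trait phenotypes feed a quantitative-trait
    genetics workflow: call-rate/MAF/Hardy-Weinberg variant QC,
    KING-robust relatedness pruning, iterative PCA outlier removal,
    additive-model GWAS with covariates, two-stage combined analysis
    (pooled and inverse-variance meta), LD-aware stage-2 SNP selection,
    and cis-eQTL scans with Benjamini-Hochberg q-values. A synthetic
    cohort generator emulates the full data structure (latent severities
    driving ordinal items, HWE genotypes with planted additive effects,
    related pairs, cis-regulated expression) so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
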