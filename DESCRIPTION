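Package: wsnpset
Title: Weighted SNP-Set Association Tests and Case-Control Power Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint association tests for sets of single-nucleotide
    polymorphisms (SNPs) in case-control studies: logistic kernel machine
    score tests with linear, identity-by-state (IBS) and Beta-density
    weighted IBS kernels, principal-component likelihood-ratio tests, and a
    weighted principal-component test that up-weights rare variants before
    component extraction. Includes a latent-multivariate-normal genotype
    simulator with allelic linkage-disequilibrium calibration, haplotype
    panel resampling, a logistic disease model with case-control
    ascertainment, and a replicate engine for type-I error and power
    studies, together with PLINK raw / TSV genotype input-output and an
    effective-number-of-tests Bonferroni correction for single-SNP minimum
    p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
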