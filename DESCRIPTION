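Package: mldphen
Title: Genotype-Phenotype Analysis and Disease-Burden Estimation for
    Metachromatic Leukodystrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotype-phenotype analysis of arylsulfatase A (ARSA)
    variants in metachromatic leukodystrophy (MLD). Classifies variant
    severity from curated patient cohorts by an iterative ruleset and from
    percent-of-wild-type enzyme activity by fixed brackets, predicts disease
    phenotype for biallelic genotypes through a symmetric phenotype matrix,
    scores genotype-phenotype consistency by Shannon entropy, estimates
    population birth incidence of each disease subtype under Hardy-Weinberg
    assumptions with analytic (variance propagation, beta approximation) and
    bootstrap confidence intervals, and simulates the order of discovery of
    pathogenic alleles under newborn screening. Includes a synthetic-data
    generator producing variant pools, diploid patient cohorts, and noisy
    activity measurements with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
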