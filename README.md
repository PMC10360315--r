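# mldphen

Genotype–phenotype analysis for metachromatic leukodystrophy (MLD), an
autosomal recessive lysosomal storage disorder caused by loss of
arylsulfatase A (ARSA) activity. The package is aimed at researchers and
newborn-screening programs who need to turn a patient's two *ARSA* alleles
into an expected disease course, and population allele frequencies into
disease-burden estimates.

## The model

Residual ARSA activity is assumed inversely related to clinical severity
and **additive across the two alleles** of a genotype. Variants are graded
into four severity classes — severe, moderate, mild, benign (plus
"unknown") — by two independent routes:

- **Patient-based severity**: an iterative ruleset over a curated cohort.
  Loss-of-function variants and any variant carried by an
  infantile/late-infantile patient are severe; the partner of a severe
  allele in a juvenile patient is moderate (a second severe allele would
  have caused infantile disease); adult homozygotes are moderate; the
  partner of a severe allele in an adult patient is mild; the partner of a
  pathogenic allele in an asymptomatic individual is benign. Rules are
  staged to a fixpoint, variants seen in fewer than 5 patients stay
  unknown, and conflicts resolve toward the more severe class.
- **Activity-based severity**: percent-of-wild-type enzyme activity from a
  cell-based assay, bracketed at <2% severe, 2–<4% moderate, 4–13% mild,
  >13% benign.

An unordered **phenotype matrix** maps each severity pair to the expected
phenotype (severe/severe → infantile/late-infantile, severe/moderate →
juvenile, severe/mild or moderate/moderate → adult, milder pairings →
asymptomatic; genotypes containing an uncharacterized allele are
predictable only against a benign partner). Per-genotype consistency is
scored by the Shannon entropy H = −Σ pᵢ ln pᵢ of the observed phenotype
distribution.

Population burden follows Hardy–Weinberg: with pooled class frequencies
p̂[Severe], p̂[Moderate], p̂[Mild],

    E[Infantile] = p̂[Severe]²
    E[Juvenile]  = 2 p̂[Severe] p̂[Moderate]
    E[Adult]     = p̂[Moderate]² + 2 p̂[Severe] p̂[Mild]

with variances propagated analytically (including the covariance terms
that arise because the severe class feeds several phenotypes), 95%
intervals from a method-of-moments beta approximation or a parametric
bootstrap over binomial allele-count resampling, and a weighted-draw
simulation of the order in which pathogenic alleles would be discovered
among screened patients.

## Worked example

Everything below runs on synthetic data with known ground truth:

```r
library(mldphen)

cfg    <- synthetic_config(seed = 1)          # 28/5/2/2 variants, 489 patients
pool   <- generate_variant_pool(cfg)
cohort <- generate_cohort(pool, cfg)

sev <- assign_patient_based_severity(cohort, overrides = character(0))
head(sev[sev$severity != "unknown", ], 5)
#>          id severity eligible rule_trace
#> 1 c.SIM0002   severe     TRUE         R2
#> 2 c.SIM0003   severe     TRUE         R2
#> 3 c.SIM0004   severe     TRUE         R2
#> 5 c.SIM0006   severe     TRUE         R2
#> 6 c.SIM0007   severe     TRUE         R2

truth <- setNames(pool$true_severity, pool$id)
evaluate_matrix_accuracy(cohort, truth)$overall_accuracy
#> [1] 100            # noiseless cohort: every phenotype matches the matrix

inc <- phenotype_incidence(severity_class_frequencies(pool, "true_severity", "all"))
print(inc, digits = 3)
#>      phenotype expected variance one_in
#> 1    infantile 1.95e-05 3.45e-12  51256
#> 2     juvenile 4.75e-06 4.20e-13 210369
#> 3        adult 3.00e-06 2.63e-13 333067
#> 4      overall 2.73e-05 7.85e-12  36676
#> 5 asymptomatic 4.15e-06       NA 241063
#> 6      unknown 0.00e+00       NA    Inf

ov <- inc[inc$phenotype == "overall", ]
analytic_ci(ov$expected, ov$variance)
#> overall MLD incidence: 1 in 36676 (95% CI 1 in 30281 - 1 in 45347)
```

`expected` is the per-birth probability of each MLD subtype under
Hardy–Weinberg given the pool's allele frequencies; `one_in` is its
reciprocal ("1 affected birth in N"). `unknown` is the
genotype-of-unknown-significance (GUS) rate — here zero because every
synthetic variant is characterized. The discovery simulation estimates how
many affected patients must be screened before each additional distinct
pathogenic allele appears, and a monotone piecewise-cubic extrapolation
predicts the screening effort to the first allele *absent* from the pool:

```r
path  <- pool$true_severity != "benign"
curve <- simulate_discovery(setNames(pool$freq_all[path], pool$id[path]),
                            n_sims = 2000, seed = 1)
curve$mean_patients[2]
#> [1] 1.09           # the 2nd distinct allele appears by the 1st-2nd patient
extrapolate_discovery(curve, 1)
#>   rank mean_patients
#> 1   36          5113 # ~5113 screened patients before a novel allele
```

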