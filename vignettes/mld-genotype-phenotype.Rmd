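---
title: "Methods: severity classes, the phenotype matrix, and burden estimation in MLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity classes, the phenotype matrix, and burden estimation in MLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mldphen)
```

Metachromatic leukodystrophy (MLD) is an autosomal recessive
neurodegenerative disease caused by deficient sulfatide catabolism when
both copies of the arylsulfatase A gene (*ARSA*) are damaged. Onset age
stratifies patients into infantile/late-infantile (before 2.5 years),
juvenile (2.5–16 years) and adult (after 16 years) forms; earlier onset is
more severe. This vignette explains the model the package implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the test suite does and does not demonstrate.

## The additive-severity model

The central assumption is that disease severity is a function of residual
ARSA activity, and that residual activity is additive across the two
alleles of a genotype. Variants therefore get a per-allele **severity
class** — severe, moderate, mild, benign, or unknown — and a biallelic
genotype maps to an expected phenotype through a symmetric 5×5 look-up
table, the **phenotype matrix** (`default_phenotype_matrix()`): two severe
alleles give infantile disease, severe+moderate juvenile, severe+mild or
moderate+moderate adult, and pairings of mild alleles with mild, moderate
or benign alleles are expected to be asymptomatic — two pathogenic alleles
do not guarantee disease. A genotype containing an uncharacterized allele
is predictable only when the partner is benign; the four remaining
VUS-containing combinations are genotypes of unknown significance (GUS).

The matrix is data, not code: it ships as a default table, can be written
and re-read as a labelled TSV (`write_phenotype_matrix()` /
`read_phenotype_matrix()`), and every consumer takes it as an argument.

## Patient-based severity rules

`assign_patient_based_severity()` iterates the cohort ruleset to a
fixpoint, staged the way the class lists are constructed: severe variants
are pinned down first (loss-of-function consequences, R1, and any variant
carried by an infantile patient, R2), these define the moderate list
(juvenile partner of a severe allele R3, adult homozygote R4, symptomatic
partner of a moderate allele R5), which defines the mild list (adult
partner of a severe allele R6), and finally benign (asymptomatic partner
of a pathogenic allele R7); the whole cycle repeats until nothing changes.

Design choices:

* **Observation threshold.** Classification requires `min_patients = 5`
  carriers, counted as patients (a homozygote counts once); allele counts
  are tallied separately because both accountings are useful. Incomplete
  records (second allele unreported) contribute their known allele to
  tallies and to rule R2 but are excluded from genotype-level analyses.
* **Conflicts.** Evidence can genuinely conflict (the same allele in an
  infantile and an adult patient). The most severe fired class wins, and
  `rule_trace` keeps every fired rule for audit rather than raising.
* **Patients with unknown phenotype never fire rules.**
* **Overrides.** Three variants ship as benign overrides
  (`default_severity_overrides()`): the pseudo-deficiency allele p.T393S
  (common, benign in ClinVar, yet present in patients — without the
  override rule R3 would call it moderate) and the high-frequency variants
  p.P220L and c.466-7G>C. R7 cannot derive these because asymptomatic
  individuals are not curated in practice.

The ruleset has an identifiability limit worth knowing: a truly severe
variant observed *only* in juvenile patients (always in trans with a
moderate allele, never in an infantile patient) is indistinguishable from
a moderate one and will be called moderate. The recovery tests therefore
condition on the informative pairing being present, which is also the
regime the ruleset was designed for.

## Entropy of the genotype–phenotype relationship

`genotype_entropy()` computes H = −Σᵢ pᵢ ln pᵢ over the phenotype
distribution observed for a genotype (natural log; 0 for perfectly
consistent genotypes; ln k maximum over k observed categories). Two
numerical decisions:

* The defining formula is implemented with the leading minus sign so that
  H ≥ 0, which is what reproduces all worked values (0.66 for 15
  juvenile/9 adult; 0.96 for 4/4/1; ln 3 = 1.099 as the three-phenotype
  ceiling).
* Observed *unknown* phenotypes form their own entropy category. This is
  required to reproduce the worked values for genotypes containing
  unknown-phenotype patients (0.14 for 32 infantile + 1 unknown, 0.41 for
  6 + 1), even though the three symptomatic phenotypes are the nominal
  categories. In `evaluate_matrix_accuracy()`, by contrast,
  unknown-phenotype records are dropped from the denominator — an
  unknown observation can neither match nor contradict a prediction.
  `entropy_summary()` reports the population (n-denominator) standard
  deviation across eligible genotypes.

## Activity-based severity

`percent_wt_activity()` normalizes each well's blank-subtracted ARSA
product/internal-standard ion ratio by the matching beta-lactamase (BLA)
transfection-control ratio, then expresses it against the **per-plate
mean** of wild-type wells (wild-type wells are co-transfected on every
plate precisely to absorb assay drift, so the reference is per plate
rather than global). Values can be negative after blank subtraction near
zero activity; they are preserved in reporting and treated as null
activity when bracketing.

`activity_based_severity()` brackets the mean percent of wild-type:
below 2% severe, [2, 4) moderate, [4, 13] mild, above 13 benign. The mild
bracket is closed at 13 because 13% doubles as the pathogenic threshold of
the binary screen (`diagnostic_metrics()`, which reports zero-denominator
likelihood ratios and diagnostic odds ratios as infinite rather than
erroring — a screen with no false positives has infinite DOR by
construction). The anchors are the lowest-activity mild allele (p.I181S,
4.3%) and the lowest-activity benign allele (p.T393S, 14.7%).

`finalize_severity()` reconciles the patient-based call with CDS and
genomic-construct activity calls, conceding to patient evidence on
conflict. When the two constructs disagree, the call matching (or
ordinally closer to, on the severe < moderate < mild < benign scale) the
patient-based class wins; ties, and cases with no patient evidence,
resolve toward the more severe call — conservative for a screening
context. The default override pins p.P428L to moderate: its patient-based
class is moderate but its measured CDS activity is in the severe range, a
mismatch attributed to cell-type-specific proteolysis that no activity
assay parameter here can model.

## Incidence estimation

`severity_class_frequencies()` pools allele frequencies per class under
the simplifying assumption that variants never co-occur on the same *ARSA*
copy, so class frequencies are plain sums; each variant contributes the
binomial sampling variance p(1−p)/AN, with AN the population allele
number (per-population when available, default 100,000 — the scale of a
large reference database). `phenotype_incidence()` then applies the
Hardy–Weinberg composition (E[Infantile] = p̂[Severe]², etc.), with the
asymptomatic expectation including carrier pairings of benign with
pathogenic alleles (this is what makes asymptomatic rates of order 1 in 2)
and benign×unknown counted as asymptomatic, since a genotype is
predictable when one allele is benign.

Variance propagation notes:

* The variance of a product of independent frequency estimates expands as
  Var[XY] = (Var[X]+E[X]²)(Var[Y]+E[Y]²) − E[X]²E[Y]², with a factor 4 for
  heterozygote terms and the squared-term analogue
  2((Var+p²)² − p⁴) for homozygote terms. All formulas vanish when every
  per-variant variance is zero, which the test suite checks symbolically
  by evaluation.
* The juvenile variance is implemented in its published asymmetric form
  4 p̂[Severe]² Var[Moderate], which ignores the severe-class variance;
  `symmetric_juvenile_variance = TRUE` switches to the symmetric product
  form for sensitivity analysis.
* The overall variance adds the covariance terms that arise because the
  severe class feeds the infantile, juvenile and adult phenotypes;
  phenotype variances cannot simply be summed.
* Per-genotype incidence (`genotype_incidence()`) uses p² for homozygotes
  and 2pq for compound heterozygotes. The factor 2 counts both phase
  arrangements and is required to reproduce published per-genotype rates.

`analytic_ci()` fits a method-of-moments beta distribution to the
estimate's mean and variance and reads off the 2.5/97.5 percentiles; it
refuses moment pairs no beta can have (variance ≥ m(1−m)) and degenerates
gracefully as variance → 0. `bootstrap_ci()` is the numeric counterpart:
each iteration redraws every variant's allele count as Binomial(AN, p̂)/AN
and recomputes all phenotype incidences through the same closed-form
composition (the composition *is* the default matrix, so no separate
matrix argument is taken); it is the only interval offered for the
asymptomatic and GUS phenotypes, whose analytic variances are not
derived. Percentile intervals from 10⁵ iterations are the default;
intervals below 100 iterations warn.

## Newborn-screening discovery simulation

`simulate_discovery()` draws affected "patients" — two pathogenic alleles
per patient, sampled with replacement with probability proportional to
allele frequency renormalized over the pool — and records the patient
index at which each additional distinct allele first appears, averaged
over simulations. The first allele always appears with patient 1; when one
patient reveals two new alleles both ranks are credited to that patient.
Both the mean first-appearance index and its per-rank difference
(`mean_gap`) are reported, since "patients screened between the k-th and
(k+1)-th allele" is the gap view while "patients to the k-th allele" is
the index view; for two equal-frequency alleles the index view has the
closed form ½·1 + ½·(1 + 1/(3/4)) = 5/3, which the suite checks against an
independent dynamic-programming oracle. Runs exceeding a configurable
patient cap (default 10⁷) abort with a warning, guarding against
near-zero-frequency tails.

`extrapolate_discovery()` fits a monotone piecewise-cubic (Fritsch–Carlson)
interpolant to the mean curve and evaluates it beyond the pool, predicting
the screening effort before alleles absent from the reference pool are
encountered; the monotone construction is used because an unconstrained
cubic can oscillate, and linear curves extrapolate exactly linearly.
`births_per_novel_allele()` converts patients-per-novel-allele into a
population birth rate by multiplying with births-per-affected-patient.

## The synthetic-data generator

`synthetic_config()` fixes the study conditions once: 28 severe, 5
moderate, 2 mild and 2 benign variants (the composition of the curated
well-observed set), 489 patients (the curated cohort size), allele
frequencies log-uniform on 10⁻⁶–10⁻³ per population (bracketing the
observed pathogenic range, whose most common allele sits near 6×10⁻⁴),
allele number 10⁵, zero phenotype misclassification and 0.5 %WT activity
noise by default.

`generate_cohort()` samples genotypes proportional to Hardy–Weinberg
frequency *conditioned on being symptomatic* under the matrix — direct
rejection over all births would need ~10⁶ draws per patient at realistic
incidences. Recorded phenotypes equal the matrix prediction, flipped to a
random other symptomatic phenotype with the configured misclassification
probability, and onset ages are drawn uniformly inside the recorded
phenotype's window (adult capped at 50 years).
`generate_activity_table()` places class-typical activities mid-bracket
(severe 0.5, moderate 3, mild 8, benign 60 %WT) so that boundary stress
tests are explicit, and back-converts to ion-ratio wells whose round-trip
through `percent_wt_activity()` is exact.

What the generator does **not** emulate: pseudo-deficiency cis-modifiers,
splice-construct effects, plate-to-plate drift, allele-frequency
correlation between populations, duplicate patients across publications,
and ascertainment bias in the literature. Passing recovery tests
therefore demonstrate internal consistency of the pipeline — the rules
invert the matrix, brackets invert the activity generator, estimated
incidences match generating frequencies — not accuracy on real curated
data.

## Problem sizes and limitations

The default test run uses desk-scale sizes: 2×10⁴ simulations for the
two-allele discovery check, 8×10³ against the DP oracle, 400 synthetic
pools × 400 bootstrap iterations for interval coverage, cohorts of
200–800 patients. These choices keep the full suite under a minute while
leaving Monte-Carlo error well inside the asserted tolerances.

Four published cohort-level numbers (76%/52% matrix accuracy, the 1 in
310,996 / 1 in 185,365 overall incidences and GUS rates, the 1.12-patient
discovery rate with its rank-106 extrapolation, and the 90-of-251 VUS
activity tally) can only be recomputed from the original supplementary
tables, which are not redistributed with this package. The corresponding
acceptance tests contain the full computation, driven by loader paths
under `inst/extdata/curated/` with the schemas documented in the readers,
and report as explicit failures until those tables are installed there.
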