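#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the curated study conditions: 28 severe, 5 moderate, 2
#' mild and 2 benign characterized variants (plus uncharacterized ones if
#' requested), allele frequencies log-uniform between 1e-6 and 1e-3
#' (bracketing the observed pathogenic range, whose most common allele sits
#' near 6e-4), a cohort of 489 patients, gnomAD-scale allele numbers, and
#' noiseless phenotypes and activities unless noise is switched on.
#'
#' @param n_variants_per_class Named integer vector of pool sizes per
#'   severity class.
#' @param frequency_log10_range Length-2 numeric, log10 bounds for allele
#'   frequencies.
#' @param populations Character vector of population names to simulate.
#' @param n_patients Cohort size.
#' @param phenotype_misclassification_rate Probability that a patient's
#'   recorded phenotype is flipped to a random other symptomatic phenotype.
#' @param activity_noise_sd Gaussian noise on synthetic activities, in
#'   percent-of-wild-type units.
#' @param allele_number Chromosomes sampled per population (`an_` columns).
#' @param seed RNG seed recorded in the config and used by the generators.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_variants_per_class = c(severe = 28, moderate = 5,
                                                      mild = 2, benign = 2),
                             frequency_log10_range = c(-6, -3),
                             populations = "all",
                             n_patients = 489,
                             phenotype_misclassification_rate = 0,
                             activity_noise_sd = 0.5,
                             allele_number = 1e5,
                             seed = 1L) {
  stopifnot(
    all(n_variants_per_class >= 0),
    length(frequency_log10_range) == 2,
    frequency_log10_range[1] <= frequency_log10_range[2],
    n_patients >= 1,
    phenotype_misclassification_rate >= 0,
    phenotype_misclassification_rate <= 1,
    activity_noise_sd >= 0,
    allele_number >= 1
  )
  if (is.null(names(n_variants_per_class)) ||
      !all(names(n_variants_per_class) %in% severity_levels())) {
    stop("n_variants_per_class must be named by severity classes",
         call. = FALSE)
  }
  structure(list(
    n_variants_per_class = n_variants_per_class,
    frequency_log10_range = frequency_log10_range,
    populations = populations,
    n_patients = n_patients,
    phenotype_misclassification_rate = phenotype_misclassification_rate,
    activity_noise_sd = activity_noise_sd,
    allele_number = allele_number,
    seed = seed
  ), class = "synthetic_config")
}

#' Generate a synthetic variant pool with known true severities
#'
#' One variant per requested class slot, with per-population allele
#' frequencies drawn log-uniformly within the configured range and the
#' generating ("true") severity recorded both in `true_severity` and in the
#' standard severity columns, so the pool drops into any severity-selecting
#' analysis. All variants are missense except that pools may be extended by
#' the caller. Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A data.frame shaped like [parse_variant_table()] output with an
#'   extra `true_severity` column.
#' @export
generate_variant_pool <- function(config) {
  counts <- config$n_variants_per_class
  classes <- rep(names(counts), counts)
  n <- length(classes)
  with_seed(config$seed, {
    pool <- data.frame(
      id = sprintf("c.SIM%04d", seq_len(n)),
      hgvs_p = sprintf("p.SIM%04d", seq_len(n)),
      consequence = rep("missense", n),
      clinvar_label = rep(NA_character_, n),
      true_severity = classes,
      stringsAsFactors = FALSE
    )
    for (pop in config$populations) {
      lo <- config$frequency_log10_range[1]
      hi <- config$frequency_log10_range[2]
      pool[[paste0("freq_", pop)]] <- 10^stats::runif(n, lo, hi)
      pool[[paste0("an_", pop)]] <- rep(config$allele_number, n)
    }
    for (cc in c("patient_based_severity", "activity_based_severity_cds",
                 "activity_based_severity_genomic", "finalized_severity")) {
      pool[[cc]] <- classes
    }
    pool
  })
}

#' Sample a symptomatic patient cohort from a variant pool
#'
#' Enumerates all unordered biallelic genotypes in the pool, keeps those
#' whose matrix-predicted phenotype is symptomatic (infantile, juvenile or
#' adult), and samples patients with probability proportional to the
#' Hardy-Weinberg genotype frequency (`p^2` homozygous, `2pq`
#' heterozygous) — conditioning on being symptomatic rather than rejecting
#' over all births, which keeps cohorts desk-scale at realistic 1e-6
#' incidences. Each patient's recorded phenotype is the matrix prediction,
#' flipped to a random other symptomatic phenotype with the configured
#' misclassification probability; onset ages are drawn uniformly within
#' the recorded phenotype's onset window (adult ages capped at 50 years).
#'
#' @param pool Variant pool from [generate_variant_pool()].
#' @param config A [synthetic_config()].
#' @param matrix Phenotype matrix (default [default_phenotype_matrix()]).
#' @param population Which population's frequencies drive sampling.
#' @return Patient records shaped like [parse_patient_table()] output, with
#'   an extra `true_phenotype` column (the unflipped matrix prediction).
#' @export
generate_cohort <- function(pool, config,
                            matrix = default_phenotype_matrix(),
                            population = config$populations[1]) {
  freq <- stats::setNames(pool[[paste0("freq_", population)]], pool$id)
  sev <- stats::setNames(pool$true_severity, pool$id)
  idx <- which(upper.tri(diag(nrow(pool)), diag = TRUE), arr.ind = TRUE)
  a <- pool$id[idx[, "row"]]
  b <- pool$id[idx[, "col"]]
  pheno <- predict_phenotype(sev[a], sev[b], matrix)
  keep <- pheno %in% symptomatic_phenotypes()
  if (!any(keep)) {
    stop("no symptomatic genotype is possible in this pool", call. = FALSE)
  }
  a <- a[keep]; b <- b[keep]; pheno <- pheno[keep]
  gfreq <- genotype_incidence(freq[a], freq[b], homozygous = a == b)
  with_seed(config$seed + 1L, {
    pick <- sample.int(length(a), config$n_patients, replace = TRUE,
                       prob = gfreq)
    true_phen <- pheno[pick]
    recorded <- true_phen
    flip <- stats::runif(config$n_patients) <
      config$phenotype_misclassification_rate
    if (any(flip)) {
      recorded[flip] <- vapply(true_phen[flip], function(ph) {
        sample(setdiff(symptomatic_phenotypes(), ph), 1)
      }, character(1))
    }
    onset_window <- list(infantile = c(0, 2.5), juvenile = c(2.5, 16),
                         adult = c(16, 50))
    onset <- vapply(recorded, function(ph) {
      w <- onset_window[[ph]]
      stats::runif(1, w[1], w[2])
    }, numeric(1))
    data.frame(
      patient_id = sprintf("SIMPT%05d", seq_len(config$n_patients)),
      allele1 = unname(a[pick]),
      allele2 = unname(b[pick]),
      phenotype = recorded,
      age_of_onset_years = onset,
      source_ref = "synthetic",
      incomplete = FALSE,
      true_phenotype = true_phen,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  })
}

# class-typical activity levels in percent of wild-type, placed mid-bracket
# so boundary stress tests are explicit
synthetic_class_activity <- function() {
  c(severe = 0.5, moderate = 3, mild = 8, benign = 60, unknown = 60)
}

#' Generate a synthetic well-level activity table
#'
#' Three replicate wells per variant with percent-of-wild-type activity
#' centred at a class-typical value (severe 0.5, moderate 3, mild 8,
#' benign 60) plus Gaussian noise, back-converted to ion-ratio pairs
#' against synthetic wild-type wells (one plate, BLA control ratio 1, so a
#' variant's ARSA ratio equals its normalized activity). Round-tripping
#' through [percent_wt_activity()] reproduces the injected percentages.
#'
#' @param pool Variant pool from [generate_variant_pool()].
#' @param config A [synthetic_config()].
#' @param construct Construct label for the generated wells.
#' @return A well-level data.frame shaped like [parse_activity_table()]
#'   output, including wild-type wells under id `"WT"`.
#' @export
generate_activity_table <- function(pool, config, construct = "cds") {
  centres <- synthetic_class_activity()[pool$true_severity]
  n_rep <- 3L
  with_seed(config$seed + 2L, {
    pct <- rep(centres, each = n_rep) +
      stats::rnorm(nrow(pool) * n_rep, 0, config$activity_noise_sd)
    variant_rows <- data.frame(
      id = rep(pool$id, each = n_rep),
      construct = construct,
      plate_id = "plate1",
      replicate = rep(seq_len(n_rep), nrow(pool)),
      arsa_ion_ratio = pct / 100,
      bla_ion_ratio = 1,
      stringsAsFactors = FALSE
    )
    wt_rows <- data.frame(
      id = "WT",
      construct = construct,
      plate_id = "plate1",
      replicate = seq_len(n_rep),
      arsa_ion_ratio = 1,
      bla_ion_ratio = 1,
      stringsAsFactors = FALSE
    )
    rbind(wt_rows, variant_rows)
  })
}
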