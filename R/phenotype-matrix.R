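#' The default phenotype matrix
#'
#' A symmetric 5x5 look-up table mapping an unordered pair of allele
#' severity classes to the expected MLD phenotype. Disease severity is
#' modelled as additive in residual enzyme activity: two severe alleles
#' give the earliest-onset (infantile/late-infantile) form, each step of
#' residual activity delays onset, and pairings of mild alleles with mild,
#' moderate or benign alleles are expected to be asymptomatic. A genotype
#' containing an uncharacterized (`"unknown"`) allele is predictable only
#' when the other allele is benign.
#'
#' @return A 5x5 character matrix with severity classes as dimnames.
#' @seealso [predict_phenotype()], [read_phenotype_matrix()]
#' @export
default_phenotype_matrix <- function() {
  sev <- severity_levels()
  m <- matrix("unknown", 5, 5, dimnames = list(sev, sev))
  set <- function(a, b, ph) {
    m[a, b] <<- ph
    m[b, a] <<- ph
  }
  set("severe", "severe", "infantile")
  set("severe", "moderate", "juvenile")
  set("severe", "mild", "adult")
  set("moderate", "moderate", "adult")
  set("moderate", "mild", "asymptomatic")
  set("mild", "mild", "asymptomatic")
  for (s in c("severe", "moderate", "mild", "benign")) {
    set("benign", s, "asymptomatic")
  }
  set("unknown", "benign", "asymptomatic")
  # unknown paired with anything pathogenic or unknown stays unpredictable
  m
}

#' Predict MLD phenotype from a severity pair
#'
#' Symmetric matrix lookup: `predict_phenotype(a, b)` equals
#' `predict_phenotype(b, a)`. Vectorized over `s1`/`s2`.
#'
#' @param s1,s2 Severity classes (see [severity_levels()]).
#' @param matrix Phenotype matrix, by default [default_phenotype_matrix()].
#' @return Character vector of phenotypes.
#' @export
predict_phenotype <- function(s1, s2, matrix = default_phenotype_matrix()) {
  s1 <- canonical_severity(s1)
  s2 <- canonical_severity(s2)
  matrix[cbind(s1, s2)]
}

#' Read/write a phenotype matrix
#'
#' The on-disk form is a tab-separated 5x5 grid with severity labels as row
#' and column headers. Reading validates symmetry and completeness.
#'
#' @param path File path.
#' @return `read_phenotype_matrix()` returns the matrix;
#'   `write_phenotype_matrix()` returns `path` invisibly.
#' @export
read_phenotype_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                           colClasses = "character", check.names = FALSE)
  m <- as.matrix(tab)
  sev <- severity_levels()
  if (!setequal(rownames(m), sev) || !setequal(colnames(m), sev)) {
    stop("phenotype matrix must be labelled by the five severity classes",
         call. = FALSE)
  }
  m <- m[sev, sev]
  if (!all(m %in% phenotype_levels())) {
    stop("phenotype matrix cells must be phenotype categories", call. = FALSE)
  }
  if (!identical(m, t(m))) stop("phenotype matrix must be symmetric", call. = FALSE)
  m
}

#' @rdname read_phenotype_matrix
#' @param matrix A phenotype matrix.
#' @export
write_phenotype_matrix <- function(matrix, path) {
  utils::write.table(cbind(severity = rownames(matrix), matrix), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shannon entropy of a genotype's phenotype distribution
#'
#' `H = -sum(p_i * log(p_i))` (natural log) over the phenotype categories
#' observed with positive count, where `p_i` is the observed fraction of
#' phenotype `i` among patients with the genotype. A genotype that always
#' presents with the same phenotype has entropy 0; the maximum over `k`
#' observed categories is `log(k)`. Every observed category contributes,
#' including `"unknown"` phenotypes.
#'
#' @param phenotype_counts Non-negative numeric vector of per-phenotype
#'   counts (names optional); at least one must be positive.
#' @return Non-negative entropy in nats.
#' @export
genotype_entropy <- function(phenotype_counts) {
  counts <- as.numeric(phenotype_counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("phenotype counts must be non-negative numbers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("at least one phenotype count must be positive",
                            call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Accuracy of phenotype-matrix predictions on a patient cohort
#'
#' Restricts to complete records whose both alleles were each observed in
#' at least `min_patients` patients (and are not excluded), predicts each
#' record's phenotype from its allele severities via the matrix, and
#' reports the percentage of observed phenotypes matching the prediction.
#' Records with an unknown observed phenotype are dropped from the
#' denominator.
#'
#' @param records Patient records.
#' @param severities Named character vector mapping variant id to severity
#'   class; unmapped variants count as `"unknown"`.
#' @param matrix Phenotype matrix.
#' @param min_patients Per-allele observation threshold (default 5).
#' @param exclude Optional character vector of variant ids; genotypes
#'   containing any of them are left out.
#' @return A list with `overall_accuracy` (percent), `n_matched`,
#'   `n_evaluated`, and `per_genotype` (data.frame with key, predicted
#'   phenotype, per-genotype counts and accuracy).
#' @export
evaluate_matrix_accuracy <- function(records, severities,
                                     matrix = default_phenotype_matrix(),
                                     min_patients = 5, exclude = NULL) {
  obs <- count_variant_observations(records)
  counts <- stats::setNames(obs$patient_count, obs$id)
  complete <- records[!records$incomplete, , drop = FALSE]
  keep <- counts[complete$allele1] >= min_patients &
    counts[complete$allele2] >= min_patients
  if (!is.null(exclude)) {
    keep <- keep & !(complete$allele1 %in% exclude) &
      !(complete$allele2 %in% exclude)
  }
  complete <- complete[keep, , drop = FALSE]
  sev_of <- function(id) {
    s <- unname(severities[id])
    ifelse(is.na(s), "unknown", s)
  }
  predicted <- predict_phenotype(sev_of(complete$allele1),
                                 sev_of(complete$allele2), matrix)
  observed <- complete$phenotype
  evaluable <- observed != "unknown"
  if (!any(evaluable)) {
    stop("no evaluable records: every observed phenotype is unknown or no ",
         "genotype meets the observation threshold", call. = FALSE)
  }
  matched <- evaluable & observed == predicted
  key <- genotype_key(complete$allele1, complete$allele2)
  per_genotype <- do.call(rbind, lapply(split(seq_along(key), key), function(idx) {
    data.frame(
      key = key[idx[1]],
      predicted = predicted[idx[1]],
      n_patients = length(idx),
      n_evaluated = sum(evaluable[idx]),
      n_matched = sum(matched[idx]),
      accuracy = if (sum(evaluable[idx]) > 0) {
        100 * sum(matched[idx]) / sum(evaluable[idx])
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_genotype) <- NULL
  list(
    overall_accuracy = 100 * sum(matched) / sum(evaluable),
    n_matched = sum(matched),
    n_evaluated = sum(evaluable),
    per_genotype = per_genotype
  )
}

#' Summarize entropy across eligible genotypes
#'
#' Mean and standard deviation of per-genotype entropies, restricted to
#' genotypes whose both alleles were each observed in at least
#' `min_patients_per_allele` patients. The population (n-denominator)
#' standard deviation is reported.
#'
#' @param summaries Genotype table from [tabulate_genotypes()].
#' @param records The patient records the summaries were built from (used
#'   for per-variant observation counts).
#' @param min_patients_per_allele Per-allele observation threshold.
#' @return A list with `mean`, `sd`, `n_genotypes`, `n_patients`.
#' @export
entropy_summary <- function(summaries, records, min_patients_per_allele = 5) {
  obs <- count_variant_observations(records)
  counts <- stats::setNames(obs$patient_count, obs$id)
  keep <- counts[summaries$allele1] >= min_patients_per_allele &
    counts[summaries$allele2] >= min_patients_per_allele
  keep[is.na(keep)] <- FALSE
  eligible <- summaries[keep, , drop = FALSE]
  if (!nrow(eligible)) stop("no genotype meets the observation threshold",
                            call. = FALSE)
  h <- eligible$entropy
  list(
    mean = mean(h),
    sd = sqrt(mean((h - mean(h))^2)),
    n_genotypes = nrow(eligible),
    n_patients = sum(eligible$n_patients)
  )
}
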