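#' Read a curated MLD patient table
#'
#' Parses a tab-separated table of curated patients. Required columns:
#' `patient_id`, `allele1`, `allele2`, `phenotype`; optional columns
#' `age_of_onset_years` and `source_ref`. Empty cells are missing. A record
#' whose `allele2` is missing is flagged `incomplete = TRUE`: it is excluded
#' from genotype tabulation but still contributes its known allele to
#' per-variant tallies.
#'
#' Phenotype labels are matched case-insensitively
#' ("late-infantile", "infantile/late-infantile" etc. collapse onto
#' `"infantile"`). When both an onset age and a phenotype are given they are
#' checked against the onset cutoffs (below 2.5 years infantile, 2.5-16
#' juvenile, over 16 adult); inconsistencies warn, or fail when
#' `strict = TRUE`.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param strict Logical; treat phenotype/onset inconsistencies as errors.
#' @return A data.frame with columns `patient_id`, `allele1`, `allele2`,
#'   `phenotype`, `age_of_onset_years`, `source_ref`, `incomplete`.
#' @export
parse_patient_table <- function(path, strict = FALSE) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = c("", "NA"),
                           fileEncoding = "UTF-8", check.names = FALSE)
  required <- c("patient_id", "allele1", "allele2", "phenotype")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("patient table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    patient_id = trimws(raw$patient_id),
    allele1 = canonical_variant_id(raw$allele1),
    allele2 = canonical_variant_id(raw$allele2),
    phenotype = if (nrow(raw)) canonical_phenotype(raw$phenotype) else character(0),
    age_of_onset_years = if ("age_of_onset_years" %in% names(raw)) {
      as.numeric(raw$age_of_onset_years)
    } else rep(NA_real_, nrow(raw)),
    source_ref = if ("source_ref" %in% names(raw)) raw$source_ref
                 else rep(NA_character_, nrow(raw)),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$allele1)) {
    stop("allele1 is required for every record; missing in row(s) ",
         paste(which(is.na(out$allele1)), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(out$patient_id)
  if (any(dup)) {
    stop("duplicate patient_id(s): ",
         paste(unique(out$patient_id[dup]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(out$age_of_onset_years) & out$age_of_onset_years < 0)) {
    stop("age_of_onset_years must be non-negative", call. = FALSE)
  }
  out$incomplete <- is.na(out$allele2)
  check_onset_consistency(out, strict = strict)
  out
}

# HGVS ids are canonicalized by exact string: whitespace stripped and the
# "c."/"p." prefix kept as written (no transcript-coordinate conversion).
canonical_variant_id <- function(x) {
  x <- gsub("[[:space:]]+", "", x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

check_onset_consistency <- function(records, strict = FALSE) {
  has_both <- !is.na(records$age_of_onset_years) &
    records$phenotype %in% symptomatic_phenotypes()
  implied <- phenotype_from_onset(records$age_of_onset_years)
  bad <- has_both & implied != records$phenotype
  if (any(bad)) {
    msg <- paste0("phenotype/onset inconsistency for patient(s): ",
                  paste(records$patient_id[bad], collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(records)
}

#' Write a patient table
#'
#' Inverse of [parse_patient_table()]; writing then re-parsing reproduces
#' identical records.
#'
#' @param records Patient records as returned by [parse_patient_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(records, path) {
  cols <- c("patient_id", "allele1", "allele2", "phenotype",
            "age_of_onset_years", "source_ref")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ARSA variant annotation table
#'
#' Tab-separated with columns `id`, `hgvs_p`, `consequence`,
#' `clinvar_label`, per-population frequency/allele-number pairs
#' `freq_<pop>` and `an_<pop>` (populations typically all, afr, asj, amr,
#' eas, fin, nfe, sas, oth), and optional in-silico scores `sift`,
#' `polyphen`, `revel`. Severity columns (`patient_based_severity`,
#' `activity_based_severity_cds`, `activity_based_severity_genomic`,
#' `finalized_severity`) are read when present and default to `"unknown"`.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame, one row per variant.
#' @export
parse_variant_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = c("", "NA"),
                           fileEncoding = "UTF-8", check.names = FALSE)
  if (!"id" %in% names(raw)) stop("variant table lacks an 'id' column", call. = FALSE)
  out <- raw
  out$id <- canonical_variant_id(out$id)
  if (anyNA(out$id)) stop("variant ids must be non-empty", call. = FALSE)
  if (anyDuplicated(out$id)) {
    stop("duplicate variant id(s): ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "), call. = FALSE)
  }
  num_cols <- grep("^(freq_|an_)|^(sift|polyphen|revel)$", names(out), value = TRUE)
  for (cc in num_cols) out[[cc]] <- as.numeric(out[[cc]])
  freq_cols <- grep("^freq_", names(out), value = TRUE)
  for (cc in freq_cols) {
    bad <- !is.na(out[[cc]]) & (out[[cc]] < 0 | out[[cc]] > 1)
    if (any(bad)) {
      stop("allele frequencies must lie in [0, 1]; offending column ", cc,
           call. = FALSE)
    }
  }
  sev_cols <- c("patient_based_severity", "activity_based_severity_cds",
                "activity_based_severity_genomic", "finalized_severity")
  for (cc in sev_cols) {
    out[[cc]] <- if (cc %in% names(raw)) canonical_severity(raw[[cc]])
                 else rep("unknown", nrow(out))
  }
  out
}

#' Read an enzyme-activity measurement table
#'
#' Tab-separated with columns `id`, `construct` (`cds` or `genomic`),
#' `plate_id`, `replicate`, `arsa_ion_ratio`, `bla_ion_ratio`. Ion ratios
#' are blank-subtracted product/internal-standard ratios and may be
#' negative. Wild-type wells share the table under a reserved id
#' (conventionally `"WT"`).
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame, one row per well.
#' @export
parse_activity_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = c("", "NA"),
                           fileEncoding = "UTF-8", check.names = FALSE)
  required <- c("id", "construct", "plate_id", "replicate",
                "arsa_ion_ratio", "bla_ion_ratio")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("activity table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[, required]
  out$id <- canonical_variant_id(out$id)
  out$construct <- tolower(trimws(out$construct))
  if (!all(out$construct %in% c("cds", "genomic"))) {
    stop("construct must be 'cds' or 'genomic'", call. = FALSE)
  }
  out$replicate <- as.integer(out$replicate)
  out$arsa_ion_ratio <- as.numeric(out$arsa_ion_ratio)
  out$bla_ion_ratio <- as.numeric(out$bla_ion_ratio)
  if (!all(is.finite(out$arsa_ion_ratio)) || !all(is.finite(out$bla_ion_ratio))) {
    stop("ion ratios must be finite", call. = FALSE)
  }
  out
}

#' Unordered genotype key
#'
#' Builds the canonical key for a biallelic genotype: the two allele ids
#' sorted lexicographically and joined with `"/"`, so `key(a, b) == key(b, a)`
#' and homozygotes are keyed `a/a`.
#'
#' @param a,b Character vectors of variant ids (recycled).
#' @return Character vector of keys.
#' @export
genotype_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

#' Tabulate genotypes and their phenotype distributions
#'
#' Groups complete patient records by unordered genotype and counts
#' phenotypes per genotype. Per-genotype Shannon entropy
#' (see [genotype_entropy()]) and the mean onset age over records with onset
#' data are included.
#'
#' @param records Patient records; rows with `incomplete = TRUE` are excluded.
#' @return A data.frame with one row per genotype: `key`, `allele1`,
#'   `allele2` (sorted), `n_patients`, one `n_<phenotype>` count column per
#'   phenotype category, `entropy`, `mean_onset_years`.
#' @export
tabulate_genotypes <- function(records) {
  records <- records[!records$incomplete, , drop = FALSE]
  phen <- phenotype_levels()
  if (!nrow(records)) {
    out <- data.frame(key = character(0), allele1 = character(0),
                      allele2 = character(0), n_patients = integer(0),
                      stringsAsFactors = FALSE)
    for (p in phen) out[[paste0("n_", p)]] <- integer(0)
    out$entropy <- numeric(0)
    out$mean_onset_years <- numeric(0)
    return(out)
  }
  key <- genotype_key(records$allele1, records$allele2)
  split_idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(names(split_idx), function(k) {
    idx <- split_idx[[k]]
    counts <- table(factor(records$phenotype[idx], levels = phen))
    onset <- records$age_of_onset_years[idx]
    onset <- onset[!is.na(onset)]
    row <- data.frame(
      key = k,
      allele1 = strsplit(k, "/", fixed = TRUE)[[1]][1],
      allele2 = strsplit(k, "/", fixed = TRUE)[[1]][2],
      n_patients = length(idx),
      stringsAsFactors = FALSE
    )
    for (p in phen) row[[paste0("n_", p)]] <- as.integer(counts[[p]])
    row$entropy <- genotype_entropy(as.integer(counts))
    row$mean_onset_years <- if (length(onset)) mean(onset) else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count per-variant patient and allele observations
#'
#' `patient_count` is the number of records carrying at least one copy of
#' the variant (a homozygote counts once); `allele_count` is the number of
#' allele slots occupied (a homozygote counts twice). Incomplete records
#' contribute their one known allele to both tallies.
#'
#' @param records Patient records.
#' @return A data.frame with columns `id`, `patient_count`, `allele_count`.
#' @export
count_variant_observations <- function(records) {
  slots <- c(records$allele1, records$allele2)
  slots <- slots[!is.na(slots)]
  allele_count <- table(slots)
  per_patient <- mapply(function(a, b) {
    unique(c(a, if (!is.na(b)) b))
  }, records$allele1, records$allele2, SIMPLIFY = FALSE)
  patient_count <- table(unlist(per_patient))
  ids <- sort(names(allele_count))
  data.frame(
    id = ids,
    patient_count = as.integer(patient_count[ids]),
    allele_count = as.integer(allele_count[ids]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
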