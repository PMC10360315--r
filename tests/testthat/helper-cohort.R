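# Build patient-record data.frames in code, shaped like parse_patient_table()
# output. Each argument is recycled to the longest.
make_records <- function(allele1, allele2, phenotype,
                         age_of_onset_years = NA_real_,
                         patient_id = NULL) {
  n <- max(length(allele1), length(allele2), length(phenotype))
  out <- data.frame(
    patient_id = if (is.null(patient_id)) sprintf("PT%03d", seq_len(n))
                 else rep_len(patient_id, n),
    allele1 = rep_len(allele1, n),
    allele2 = rep_len(allele2, n),
    phenotype = rep_len(phenotype, n),
    age_of_onset_years = rep_len(age_of_onset_years, n),
    source_ref = NA_character_,
    stringsAsFactors = FALSE
  )
  out$incomplete <- is.na(out$allele2)
  out
}

# Replicate whole genotype rows n times (so every allele clears an
# observation threshold).
rep_records <- function(records, times) {
  out <- records[rep(seq_len(nrow(records)), each = times), , drop = FALSE]
  out$patient_id <- sprintf("PT%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Where the full curated data set (patient cohort, per-variant gnomAD
# frequencies, VUS activity panel) would live if a user installs it; it is
# not distributed with the package.
curated_table_path <- function(file) {
  system.file("extdata", "curated", file, package = "mldphen")
}
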