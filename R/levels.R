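#' Severity classes and phenotype categories
#'
#' ARSA variants are graded into four severity classes plus `"unknown"`;
#' MLD patients fall into three onset phenotypes plus `"asymptomatic"` and
#' `"unknown"`. The orderings returned here are used for rule precedence
#' (severe beats moderate beats mild beats benign) and for the monotone
#' matrix consistency checks (infantile is the earliest onset).
#'
#' @return Character vector of level names.
#' @export
severity_levels <- function() {
  c("severe", "moderate", "mild", "benign", "unknown")
}

#' @rdname severity_levels
#' @export
phenotype_levels <- function() {
  c("infantile", "juvenile", "adult", "asymptomatic", "unknown")
}

# ordinal rank used for reconciliation and precedence; unknown is NA
# (incomparable by design)
severity_rank <- function(x) {
  match(x, c("severe", "moderate", "mild", "benign"))
}

# onset order: smaller = earlier onset = more severe presentation
phenotype_onset_rank <- function(x) {
  match(x, c("infantile", "juvenile", "adult", "asymptomatic"))
}

symptomatic_phenotypes <- function() c("infantile", "juvenile", "adult")

#' Age-of-onset cutoffs for MLD phenotypes
#'
#' Onset before 2.5 years is infantile/late-infantile, 2.5 to 16 years is
#' juvenile, after 16 years is adult.
#'
#' @param age_years Numeric vector of onset ages in years.
#' @return Character vector of phenotype labels.
#' @export
phenotype_from_onset <- function(age_years) {
  ifelse(is.na(age_years), NA_character_,
    ifelse(age_years < 2.5, "infantile",
      ifelse(age_years <= 16, "juvenile", "adult")))
}

# Map free-text phenotype labels (case-insensitive) onto the canonical set.
# "infantile", "late-infantile" and combined spellings collapse to
# "infantile"; "early juvenile"/"late juvenile" collapse to "juvenile".
canonical_phenotype <- function(x) {
  key <- tolower(trimws(x))
  key <- gsub("[ _]+", "-", key)
  key[key == "" | is.na(key)] <- "unknown"
  map <- c(
    "infantile" = "infantile",
    "late-infantile" = "infantile",
    "infantile/late-infantile" = "infantile",
    "early-juvenile" = "juvenile",
    "late-juvenile" = "juvenile",
    "juvenile" = "juvenile",
    "adult" = "adult",
    "asymptomatic" = "asymptomatic",
    "unknown" = "unknown",
    "na" = "unknown"
  )
  out <- unname(map[key])
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("unrecognised phenotype label(s) in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

canonical_severity <- function(x) {
  key <- tolower(trimws(x))
  key[key == "" | is.na(key)] <- "unknown"
  bad <- !key %in% severity_levels()
  if (any(bad)) {
    stop("unrecognised severity label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  key
}

# Run code under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
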