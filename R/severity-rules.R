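#' Is a variant loss-of-function?
#'
#' Stop-gained and frameshift (out-of-frame indel) consequences are treated
#' as loss of function: they almost universally eradicate ARSA enzyme
#' activity. In-frame deletions are not LoF here; they are classified by
#' patient or activity evidence instead.
#'
#' @param consequence Character vector of consequence classes
#'   (`missense`, `stop_gained`, `frameshift`, `splice`, `inframe_deletion`,
#'   `synonymous`, `other`).
#' @return Logical vector.
#' @export
is_lof <- function(consequence) {
  consequence %in% c("stop_gained", "frameshift")
}

#' Default severity overrides
#'
#' Three variants shipped as benign overrides: p.T393S is a well-documented
#' pseudo-deficiency allele annotated benign in ClinVar despite appearing in
#' patients; p.P220L and c.466-7G>C are benign on population-frequency
#' grounds. The cohort ruleset cannot derive these because asymptomatic
#' individuals are not curated.
#'
#' @return Named character vector mapping variant id to severity class.
#' @export
default_severity_overrides <- function() {
  c("p.T393S" = "benign", "p.P220L" = "benign", "c.466-7G>C" = "benign")
}

#' Assign patient-based severity classes by iterating the cohort ruleset
#'
#' Applies the severity ruleset to a curated cohort until no rule fires:
#' \describe{
#'   \item{R1}{loss-of-function variants are severe (requires `variants`
#'     for consequence annotations).}
#'   \item{R2}{any variant carried by an infantile/late-infantile patient
#'     is severe.}
#'   \item{R3}{in a juvenile patient, the partner of a severe variant is
#'     moderate (a second severe allele would have produced infantile
#'     disease).}
#'   \item{R4}{the homozygous variant of an adult patient is moderate.}
#'   \item{R5}{in any symptomatic patient, an uncategorized partner of a
#'     moderate variant is moderate.}
#'   \item{R6}{in an adult patient, the partner of a severe variant is mild.}
#'   \item{R7}{in an asymptomatic individual, the partner of any pathogenic
#'     (severe/moderate/mild) variant is benign.}
#' }
#' Rules are staged (R1/R2 to convergence, then R3-R5, then R6, then R7) and
#' the whole cycle repeats to a fixpoint: severe variants are pinned down
#' first, these define the moderate list, and so on. On conflicting
#' evidence the most severe fired class wins; every fired rule is kept in
#' `rule_trace` for audit. Variants carried by fewer than `min_patients`
#' patients (homozygotes counting once) are ineligible and stay `"unknown"`.
#'
#' @param records Patient records (see [parse_patient_table()]).
#' @param variants Optional variant table providing a `consequence` column
#'   for rule R1.
#' @param min_patients Minimum patient count for classification (default 5).
#' @param overrides Named severity vector applied verbatim before the rules
#'   run; see [default_severity_overrides()].
#' @return A data.frame with columns `id`, `severity`, `eligible`,
#'   `rule_trace` (comma-separated fired rules, in firing order).
#' @export
assign_patient_based_severity <- function(records, variants = NULL,
                                          min_patients = 5,
                                          overrides = default_severity_overrides()) {
  obs <- count_variant_observations(records)
  ids <- obs$id
  eligible <- obs$patient_count >= min_patients
  names(eligible) <- ids
  sev <- stats::setNames(rep("unknown", length(ids)), ids)
  trace <- stats::setNames(vector("list", length(ids)), ids)

  locked <- intersect(names(overrides), ids)
  for (v in locked) {
    sev[[v]] <- unname(overrides[[v]])
    trace[[v]] <- paste0("override:", overrides[[v]])
  }

  # a rule may only upgrade toward severe; overridden variants are pinned
  fire <- function(v, rule, class) {
    if (!eligible[[v]] || v %in% locked) return(FALSE)
    changed <- FALSE
    if (!rule %in% trace[[v]]) {
      trace[[v]] <<- c(trace[[v]], rule)
      changed <- TRUE
    }
    cur <- sev[[v]]
    if (cur == "unknown" || severity_rank(class) < severity_rank(cur)) {
      sev[[v]] <<- class
      changed <- TRUE
    }
    changed
  }

  complete <- records[!records$incomplete, , drop = FALSE]
  pheno_all <- records$phenotype
  pheno_cpl <- complete$phenotype

  pass_r1_r2 <- function() {
    changed <- FALSE
    if (!is.null(variants) && "consequence" %in% names(variants)) {
      lof_ids <- intersect(variants$id[is_lof(variants$consequence)], ids)
      for (v in lof_ids) changed <- fire(v, "R1", "severe") || changed
    }
    inf_rows <- which(pheno_all == "infantile")
    carried <- unique(stats::na.omit(c(records$allele1[inf_rows],
                                       records$allele2[inf_rows])))
    for (v in carried) changed <- fire(v, "R2", "severe") || changed
    changed
  }

  # partner rules operate on complete records only
  partner_pass <- function(phenos, partner_class, rule, class,
                           require_uncategorized = FALSE,
                           homozygous_only = FALSE) {
    changed <- FALSE
    rows <- which(pheno_cpl %in% phenos)
    for (i in rows) {
      a <- complete$allele1[i]
      b <- complete$allele2[i]
      if (homozygous_only) {
        if (a == b) changed <- fire(a, rule, class) || changed
        next
      }
      for (pair in list(c(a, b), c(b, a))) {
        v <- pair[1]; partner <- pair[2]
        if (v == partner) next  # homozygotes carry no informative partner
        if (!sev[[partner]] %in% partner_class) next
        if (require_uncategorized && sev[[v]] != "unknown") next
        changed <- fire(v, rule, class) || changed
      }
    }
    changed
  }

  repeat {
    cycle_changed <- FALSE
    repeat {
      if (!pass_r1_r2()) break
      cycle_changed <- TRUE
    }
    repeat {
      ch <- partner_pass("juvenile", "severe", "R3", "moderate")
      ch <- partner_pass("adult", NULL, "R4", "moderate",
                         homozygous_only = TRUE) || ch
      ch <- partner_pass(symptomatic_phenotypes(), "moderate", "R5",
                         "moderate", require_uncategorized = TRUE) || ch
      if (!ch) break
      cycle_changed <- TRUE
    }
    if (partner_pass("adult", "severe", "R6", "mild")) cycle_changed <- TRUE
    if (partner_pass("asymptomatic", c("severe", "moderate", "mild"),
                     "R7", "benign")) cycle_changed <- TRUE
    if (!cycle_changed) break
  }

  data.frame(
    id = ids,
    severity = unname(sev[ids]),
    eligible = unname(eligible[ids]),
    rule_trace = vapply(trace[ids], function(tr) {
      if (is.null(tr)) "" else paste(tr, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
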