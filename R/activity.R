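#' Default activity-severity brackets
#'
#' Percent-of-wild-type activity cutpoints separating the severity classes:
#' below 2% severe, 2 to below 4% moderate, 4 to 13% mild, above 13%
#' benign. 13% is also the pathogenic threshold for the binary
#' pathogenic/benign call. The bounds were anchored by p.I181S (mild, 4.3%
#' of wild-type, the lowest-activity mild allele) and p.T393S (benign,
#' 14.7%, the lowest-activity benign allele).
#'
#' @return Named numeric vector with `severe_upper`, `moderate_upper`,
#'   `mild_upper`, `pathogenic_threshold`.
#' @export
default_severity_brackets <- function() {
  c(severe_upper = 2, moderate_upper = 4, mild_upper = 13,
    pathogenic_threshold = 13)
}

#' Percent-of-wild-type enzyme activity
#'
#' Per replicate, normalized activity is the blank-subtracted ARSA
#' product/internal-standard ion ratio divided by the matching BLA
#' (beta-lactamase transfection control) ion ratio; percent of wild-type is
#' `100 * normalized_variant / mean(normalized_wildtype)` with the wild-type
#' reference taken from wells of the same plate (this absorbs assay drift
#' between batches). Negative values can arise from blank subtraction near
#' zero activity and are preserved: they represent null enzymatic activity.
#'
#' @param variant Data.frame of the variant's wells (columns
#'   `arsa_ion_ratio`, `bla_ion_ratio`; see [parse_activity_table()]).
#' @param wildtype Data.frame of the same plate's wild-type wells.
#' @return A list with `mean_percent_wt`, `sd_percent_wt` (sd over
#'   replicates, `NA` for a single replicate), `percent_wt` (per-replicate
#'   values), `n_replicates`.
#' @export
percent_wt_activity <- function(variant, wildtype) {
  norm <- function(df, label) {
    zero <- df$bla_ion_ratio == 0
    if (any(zero)) {
      warning("dropping ", sum(zero), " ", label,
              " replicate(s) with zero BLA control ratio", call. = FALSE)
      df <- df[!zero, , drop = FALSE]
    }
    if (!nrow(df)) stop("no usable ", label, " replicates", call. = FALSE)
    df$arsa_ion_ratio / df$bla_ion_ratio
  }
  wt <- mean(norm(wildtype, "wild-type"))
  if (!is.finite(wt) || wt <= 0) {
    stop("mean wild-type normalized ratio must be strictly positive",
         call. = FALSE)
  }
  pct <- 100 * norm(variant, "variant") / wt
  list(
    mean_percent_wt = mean(pct),
    sd_percent_wt = if (length(pct) > 1) stats::sd(pct) else NA_real_,
    percent_wt = pct,
    n_replicates = length(pct)
  )
}

#' Summarize an activity table to per-variant percent of wild-type
#'
#' Applies [percent_wt_activity()] to every variant/construct group in a
#' well-level activity table, pairing each group with the wild-type wells
#' of its plate, and brackets the mean into an activity-based severity.
#'
#' @param measurements Well-level table (see [parse_activity_table()]).
#' @param wt_id Reserved id of the wild-type wells (default `"WT"`).
#' @param brackets Severity brackets (see [default_severity_brackets()]).
#' @return A data.frame with columns `id`, `construct`, `mean_percent_wt`,
#'   `sd_percent_wt`, `n_replicates`, `severity`.
#' @export
summarize_activity <- function(measurements, wt_id = "WT",
                               brackets = default_severity_brackets()) {
  wt <- measurements[measurements$id == wt_id, , drop = FALSE]
  if (!nrow(wt)) stop("no wild-type wells (id '", wt_id, "') in table",
                      call. = FALSE)
  var_rows <- measurements[measurements$id != wt_id, , drop = FALSE]
  groups <- split(seq_len(nrow(var_rows)),
                  list(var_rows$id, var_rows$construct, var_rows$plate_id),
                  drop = TRUE)
  rows <- lapply(groups, function(idx) {
    g <- var_rows[idx, , drop = FALSE]
    wt_g <- wt[wt$plate_id == g$plate_id[1] & wt$construct == g$construct[1], ,
               drop = FALSE]
    if (!nrow(wt_g)) {
      stop("no wild-type wells on plate ", g$plate_id[1], " (",
           g$construct[1], ")", call. = FALSE)
    }
    res <- percent_wt_activity(g, wt_g)
    data.frame(
      id = g$id[1],
      construct = g$construct[1],
      mean_percent_wt = res$mean_percent_wt,
      sd_percent_wt = res$sd_percent_wt,
      n_replicates = res$n_replicates,
      severity = activity_based_severity(res$mean_percent_wt, brackets),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$id, out$construct), , drop = FALSE]
}

#' Bracket percent-of-wild-type activity into a severity class
#'
#' A step function over the activity brackets: below `severe_upper`
#' (including negative values, which reflect null activity) is severe;
#' `[severe_upper, moderate_upper)` moderate; `[moderate_upper, mild_upper]`
#' mild (the mild bracket is closed at 13 because 13% is also the pathogenic
#' threshold); strictly above `mild_upper` benign.
#'
#' @param percent_wt Numeric vector of percent-of-wild-type activities.
#' @param brackets Severity brackets.
#' @return Character vector of severity classes.
#' @export
activity_based_severity <- function(percent_wt,
                                    brackets = default_severity_brackets()) {
  if (any(!is.finite(percent_wt))) {
    stop("percent_wt must be finite", call. = FALSE)
  }
  ifelse(percent_wt < brackets[["severe_upper"]], "severe",
    ifelse(percent_wt < brackets[["moderate_upper"]], "moderate",
      ifelse(percent_wt <= brackets[["mild_upper"]], "mild", "benign")))
}

#' Reconcile patient-based and activity-based severity calls
#'
#' Finalized severity defers to the consensus of the patient literature when
#' calls disagree: an explicit per-variant override wins outright; otherwise
#' if the CDS and genomic activity calls agree (or no genomic assay exists)
#' the activity call is used for variants without patient evidence, while a
#' known patient-based class beats a contradicting activity call; when CDS
#' and genomic calls differ, the one equal to (or ordinally closer to) the
#' patient-based class is taken, ties and missing patient evidence
#' resolving toward the more severe call (conservative for screening).
#'
#' @param patient_based,cds,genomic Severity classes (`"unknown"` or `NA`
#'   for absent calls); vectorized, recycled to a common length.
#' @param id Optional variant ids, consulted against `overrides`.
#' @param overrides Named severity vector applied verbatim (default ships
#'   p.P428L -> moderate: its patient-based class is moderate although its
#'   CDS activity is in the severe range, a mismatch attributed to
#'   cathepsin-L proteolysis not modelled here).
#' @return Character vector of finalized severity classes.
#' @export
finalize_severity <- function(patient_based, cds = "unknown",
                              genomic = "unknown", id = NULL,
                              overrides = c("p.P428L" = "moderate")) {
  fix <- function(x) {
    x[is.na(x)] <- "unknown"
    canonical_severity(x)
  }
  n <- max(length(patient_based), length(cds), length(genomic),
           length(id))
  patient_based <- rep_len(fix(patient_based), n)
  cds <- rep_len(fix(cds), n)
  genomic <- rep_len(fix(genomic), n)
  one <- function(p, cd, g, v) {
    if (!is.null(v) && !is.na(v) && v %in% names(overrides)) {
      return(unname(overrides[[v]]))
    }
    if (p == "unknown" && cd == "unknown" && g == "unknown") return("unknown")
    known_act <- unique(setdiff(c(cd, g), "unknown"))
    if (length(known_act) == 0) return(p)
    if (length(known_act) == 1) {
      if (p == "unknown") return(known_act)
      return(p)  # patient evidence beats a contradicting (or agreeing) call
    }
    # cds and genomic disagree, both known
    if (p == cd) return(cd)
    if (p == g) return(g)
    cand <- c(cd, g)
    if (p == "unknown") {
      return(cand[which.min(severity_rank(cand))])
    }
    d <- abs(severity_rank(cand) - severity_rank(p))
    best <- cand[d == min(d)]
    best[which.min(severity_rank(best))]
  }
  vapply(seq_len(n), function(i) {
    one(patient_based[i], cds[i], genomic[i],
        if (is.null(id)) NULL else id[i])
  }, character(1))
}

#' Diagnostic performance of the activity assay as a pathogenicity screen
#'
#' Variants are called pathogenic when their percent-of-wild-type activity
#' is at or below `threshold`, and compared with a truth labelling (derived
#' upstream from patient-based severity: severe/moderate/mild are
#' pathogenic, benign is benign). Ratios with zero denominators are
#' reported as infinite, not as errors: a screen with no false positives
#' has 100% specificity and infinite LR+ and diagnostic odds ratio.
#'
#' @param truth Named character vector (`"pathogenic"`/`"benign"`) keyed by
#'   variant id.
#' @param percent_wt Named numeric vector of activities keyed by variant id.
#' @param threshold Pathogenic activity threshold (default 13).
#' @return A list with `sensitivity` and `specificity` (percent), `lr_plus`,
#'   `dor`, and `confusion` (named counts TP/FP/FN/TN).
#' @export
diagnostic_metrics <- function(truth, percent_wt, threshold = 13) {
  ids <- intersect(names(truth), names(percent_wt))
  if (!length(ids)) stop("no variants shared between truth and activity",
                         call. = FALSE)
  call_path <- percent_wt[ids] <= threshold
  is_path <- truth[ids] == "pathogenic"
  tp <- sum(call_path & is_path)
  fp <- sum(call_path & !is_path)
  fn <- sum(!call_path & is_path)
  tn <- sum(!call_path & !is_path)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  ratio <- function(num, den) if (den == 0) Inf else num / den
  list(
    sensitivity = sens,
    specificity = spec,
    lr_plus = ratio(sens / 100, 1 - spec / 100),
    dor = ratio(tp * tn, fp * fn),
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn)
  )
}

#' Pearson correlation between enzyme activity and an in-silico predictor
#'
#' Product-moment correlation over the variants present in both vectors.
#' ClinVar-characterized variants should be excluded upstream (SIFT and
#' PolyPhen are trained on ClinVar).
#'
#' @param percent_wt Named numeric vector of mean percent-of-wild-type
#'   activities.
#' @param scores Named numeric vector of predictor scores.
#' @return Pearson r.
#' @export
predictor_correlation <- function(percent_wt, scores) {
  ids <- intersect(names(percent_wt), names(scores))
  x <- percent_wt[ids]
  y <- scores[ids]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in activity or scores", call. = FALSE)
  }
  stats::cor(x, y)
}
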