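#' Pooled severity-class allele frequencies and variances
#'
#' Pools the allele frequencies of all variants in each severity class for
#' one population, assuming variants never co-occur on the same ARSA copy,
#' so class frequency is the plain sum of member frequencies. Each
#' variant's sampling variance is the binomial `p(1 - p)/AN`, with `AN` the
#' population allele number (chromosomes sampled); class variance is the
#' sum of member variances.
#'
#' @param variants Variant table with `freq_<population>` (and optionally
#'   `an_<population>`) columns and a severity column.
#' @param severity_col Name of the severity column to pool by (for example
#'   `"patient_based_severity"` or `"finalized_severity"`).
#' @param population Population suffix, e.g. `"all"` or `"nfe"`.
#' @param default_allele_number Allele number used when `an_<population>`
#'   is absent or missing (default 1e5, the scale of gnomAD).
#' @return A data.frame with one row per severity class: `class`, `p_hat`,
#'   `var`, `n_variants`; member ids in `attr(, "members")`.
#' @export
severity_class_frequencies <- function(variants, severity_col, population,
                                       default_allele_number = 1e5) {
  freq_col <- paste0("freq_", population)
  an_col <- paste0("an_", population)
  if (!freq_col %in% names(variants)) {
    stop("no column '", freq_col, "' in the variant table", call. = FALSE)
  }
  if (!severity_col %in% names(variants)) {
    stop("no column '", severity_col, "' in the variant table", call. = FALSE)
  }
  p <- variants[[freq_col]]
  if (any(!is.na(p) & p < 0)) stop("negative allele frequency", call. = FALSE)
  if (anyNA(p)) {
    warning(sum(is.na(p)), " variant(s) lack a ", population,
            " frequency; treated as 0", call. = FALSE)
    p[is.na(p)] <- 0
  }
  an <- if (an_col %in% names(variants)) variants[[an_col]] else
    rep(NA_real_, length(p))
  an[is.na(an)] <- default_allele_number
  v <- p * (1 - p) / an
  cls <- canonical_severity(variants[[severity_col]])
  members <- list()
  out <- do.call(rbind, lapply(severity_levels(), function(s) {
    idx <- which(cls == s)
    members[[s]] <<- variants$id[idx]
    data.frame(class = s,
               p_hat = sum(p[idx]),
               var = sum(v[idx]),
               n_variants = length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

class_freq_lookup <- function(freqs) {
  p <- stats::setNames(freqs$p_hat, freqs$class)
  v <- stats::setNames(freqs$var, freqs$class)
  for (s in severity_levels()) {
    if (is.na(p[s])) p[s] <- 0
    if (is.na(v[s])) v[s] <- 0
  }
  list(p = p, v = v)
}

# Closed-form phenotype expectations under Hardy-Weinberg given pooled
# class frequencies (named vector p over the five classes). Shared between
# the analytic path and the bootstrap.
phenotype_expectations <- function(p) {
  pS <- p[["severe"]]; pM <- p[["moderate"]]; pL <- p[["mild"]]
  pB <- p[["benign"]]; pU <- p[["unknown"]]
  e <- c(
    infantile = pS^2,
    juvenile = 2 * pS * pM,
    adult = pM^2 + 2 * pS * pL,
    asymptomatic = pL^2 + 2 * pL * (pM + pB) + 2 * pB * (pS + pM) + pB^2 +
      2 * pU * pB,
    unknown = 2 * pU * (pS + pM + pL) + pU^2
  )
  c(e, overall = unname(e[["infantile"]] + e[["juvenile"]] + e[["adult"]]))
}

#' Expected phenotype incidence and variance from class frequencies
#'
#' Under Hardy-Weinberg with disjoint severity classes:
#' `E[Infantile] = pS^2` (two severe alleles), `E[Juvenile] = 2 pS pM`,
#' `E[Adult] = pM^2 + 2 pS pL`, and `Overall` is their sum. Asymptomatic
#' includes carrier pairings of benign with pathogenic alleles (plus
#' mild-mild, mild-moderate, benign-benign and benign-unknown), and the
#' genotype-of-unknown-significance rate pairs an uncharacterized allele
#' with any pathogenic one. Variances propagate the per-class sampling
#' variances through products of independent frequencies, e.g.
#' `Var[Infantile] = 2((Var[S] + pS^2)^2 - pS^4)`; the overall variance
#' adds the covariance terms that arise because the severe class feeds
#' several phenotypes. Asymptomatic and unknown variances are not computed
#' analytically (use [bootstrap_ci()]).
#'
#' As printed, the juvenile variance omits the severe-class variance term
#' present in the structurally similar severe-mild term; set
#' `symmetric_juvenile_variance = TRUE` for the symmetric form as a
#' sensitivity analysis.
#'
#' @param freqs Class frequency table from [severity_class_frequencies()].
#' @param symmetric_juvenile_variance Logical (default `FALSE`).
#' @return A data.frame with one row per phenotype (infantile, juvenile,
#'   adult, overall, asymptomatic, unknown): `phenotype`, `expected`,
#'   `variance`, `one_in` (reciprocal of `expected`, `Inf` when 0).
#' @export
phenotype_incidence <- function(freqs, symmetric_juvenile_variance = FALSE) {
  lk <- class_freq_lookup(freqs)
  p <- lk$p; v <- lk$v
  pS <- p[["severe"]]; pM <- p[["moderate"]]; pL <- p[["mild"]]
  vS <- v[["severe"]]; vM <- v[["moderate"]]; vL <- v[["mild"]]

  e <- phenotype_expectations(p)

  var_inf <- 2 * ((vS + pS^2)^2 - pS^4)
  var_juv <- if (symmetric_juvenile_variance) {
    4 * ((vS + pS^2) * (vM + pM^2) - pS^2 * pM^2)
  } else {
    4 * ((vM + pM^2) * pS^2 - pM^2 * pS^2)
  }
  var_mm <- 2 * ((vM + pM^2)^2 - pM^4)
  var_sl <- 4 * ((vS + pS^2) * (vL + pL^2) - pS^2 * pL^2)
  var_adult <- var_mm + var_sl
  var_sm <- 4 * ((vS + pS^2) * (vM + pM^2) - pS^2 * pM^2)
  var_s_lm <- 4 * (var_sl + var_sm + 2 * pM * pL * vS)
  cov_slm_inf <- 2 * pS * vS * 2 * (pL + pM)
  cov_slm_mm <- 2 * pM * vM * 2 * pS
  var_overall <- var_s_lm + var_inf + var_mm + 2 * cov_slm_inf + 2 * cov_slm_mm

  variance <- c(infantile = var_inf, juvenile = var_juv, adult = var_adult,
                asymptomatic = NA_real_, unknown = NA_real_,
                overall = var_overall)
  phen <- c("infantile", "juvenile", "adult", "overall", "asymptomatic",
            "unknown")
  out <- data.frame(
    phenotype = phen,
    expected = unname(e[phen]),
    variance = unname(variance[phen]),
    stringsAsFactors = FALSE
  )
  out$one_in <- ifelse(out$expected > 0, 1 / out$expected, Inf)
  out
}

#' Analytic 95% confidence interval by beta approximation
#'
#' Method-of-moments beta distribution matched to the estimate's mean and
#' variance; the interval is its 2.5th and 97.5th percentiles. Requires
#' `0 < expected < 1` and `0 < variance < expected * (1 - expected)` (the
#' variance of any distribution on `[0, 1]` with that mean), otherwise no
#' beta has those moments.
#'
#' @param expected Point estimate (a probability).
#' @param variance Its variance.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
analytic_ci <- function(expected, variance, conf = 0.95) {
  if (!is.finite(expected) || expected <= 0 || expected >= 1) {
    stop("expected must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.finite(variance) || variance <= 0) {
    stop("variance must be positive (a zero-variance estimate has a ",
         "degenerate interval)", call. = FALSE)
  }
  if (variance >= expected * (1 - expected)) {
    stop("variance >= expected * (1 - expected): no beta distribution has ",
         "these moments", call. = FALSE)
  }
  nu <- expected * (1 - expected) / variance - 1
  a <- expected * nu
  b <- (1 - expected) * nu
  alpha <- (1 - conf) / 2
  c(low = stats::qbeta(alpha, a, b), high = stats::qbeta(1 - alpha, a, b))
}

#' Bootstrap confidence intervals for phenotype incidence
#'
#' Parametric bootstrap over allele-frequency sampling: each iteration
#' redraws every variant's allele count as `Binomial(AN, p) / AN`, re-pools
#' the severity classes, and recomputes all phenotype incidences via the
#' same closed-form expectations as [phenotype_incidence()]. Intervals are
#' the empirical 2.5/97.5 percentiles. This is the only interval available
#' for the asymptomatic and unknown phenotypes.
#'
#' @inheritParams severity_class_frequencies
#' @param n_iter Bootstrap iterations (default 1e5).
#' @param seed RNG seed for reproducibility.
#' @param conf Confidence level (default 0.95).
#' @return A data.frame with `phenotype`, `expected` (point estimate),
#'   `ci_low`, `ci_high`, `one_in`, `one_in_low`, `one_in_high`.
#' @export
bootstrap_ci <- function(variants, severity_col, population,
                         n_iter = 1e5, seed = NULL,
                         default_allele_number = 1e5, conf = 0.95) {
  if (n_iter < 100) {
    warning("n_iter < 100 gives unstable percentile intervals", call. = FALSE)
  }
  freq_col <- paste0("freq_", population)
  an_col <- paste0("an_", population)
  p <- variants[[freq_col]]
  p[is.na(p)] <- 0
  an <- if (an_col %in% names(variants)) variants[[an_col]] else
    rep(NA_real_, length(p))
  an[is.na(an)] <- default_allele_number
  an <- round(an)
  cls <- canonical_severity(variants[[severity_col]])

  draws <- with_seed(seed, {
    # n_variants x n_iter matrix of resampled frequencies
    matrix(stats::rbinom(length(p) * n_iter, rep(an, n_iter),
                         rep(p, n_iter)) / rep(an, n_iter),
           nrow = length(p), ncol = n_iter)
  })
  class_p <- vapply(severity_levels(), function(s) {
    idx <- cls == s
    if (!any(idx)) rep(0, n_iter) else colSums(draws[idx, , drop = FALSE])
  }, numeric(n_iter))
  # class_p: n_iter x 5 with class names
  phen <- c("infantile", "juvenile", "adult", "overall", "asymptomatic",
            "unknown")
  es <- apply(class_p, 1, function(pc) phenotype_expectations(pc)[phen])
  qs <- apply(es, 1, stats::quantile,
              probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  point <- phenotype_expectations(stats::setNames(
    vapply(severity_levels(), function(s) sum(p[cls == s]), numeric(1)),
    severity_levels()))[phen]
  out <- data.frame(
    phenotype = phen,
    expected = unname(point),
    ci_low = qs[1, ],
    ci_high = qs[2, ],
    stringsAsFactors = FALSE
  )
  out$one_in <- ifelse(out$expected > 0, 1 / out$expected, Inf)
  out$one_in_low <- ifelse(out$ci_high > 0, 1 / out$ci_high, Inf)
  out$one_in_high <- ifelse(out$ci_low > 0, 1 / out$ci_low, Inf)
  out
}

#' Expected frequency of one biallelic genotype
#'
#' Hardy-Weinberg genotype frequency: `p^2` for a homozygote, `2 p q` for a
#' compound heterozygote (the factor 2 counts both phase arrangements).
#'
#' @param p_a,p_b Allele frequencies in `[0, 1]`.
#' @param homozygous Logical; when `TRUE`, `p_b` is ignored.
#' @return Numeric genotype frequency.
#' @export
genotype_incidence <- function(p_a, p_b = p_a, homozygous = FALSE) {
  stopifnot(all(p_a >= 0 & p_a <= 1), all(p_b >= 0 & p_b <= 1))
  ifelse(homozygous, p_a^2, 2 * p_a * p_b)
}
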