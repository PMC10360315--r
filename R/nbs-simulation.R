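#' Simulate the order of discovery of pathogenic alleles under screening
#'
#' Repeatedly generates "patients" — individuals with two pathogenic
#' alleles, drawn with replacement with probability proportional to allele
#' frequency (frequencies are renormalized over the variants considered) —
#' and records the patient index at which each additional distinct variant
#' is first observed. The first variant always appears with the first
#' patient; when one patient reveals two new variants both ranks are
#' credited to that patient. Means over `n_sims` simulations form the
#' discovery curve.
#'
#' @param freqs Named numeric vector of allele frequencies over the
#'   pathogenic variant pool; at least one must be positive. Zero-frequency
#'   variants are dropped.
#' @param n_sims Number of simulations (default 1e5).
#' @param seed RNG seed.
#' @param patient_cap Simulations needing more than this many patients are
#'   aborted with a warning (guards against near-zero-frequency tails).
#' @return A list of class `"discovery_curve"` with `rank` (1..n),
#'   `mean_patients` (mean first-appearance patient index per rank),
#'   `mean_gap` (differences of the mean curve, with leading `NA`),
#'   `n_variants`, `n_sims` (completed runs), `seed`.
#' @export
simulate_discovery <- function(freqs, n_sims = 1e5, seed = NULL,
                               patient_cap = 1e7) {
  freqs <- freqs[freqs > 0]
  n <- length(freqs)
  if (n == 0) stop("all frequencies are zero", call. = FALSE)
  w <- freqs / sum(freqs)
  totals <- rep(0, n)
  completed <- 0L
  with_seed(seed, {
    chunk <- max(64L, 4L * n)
    for (s in seq_len(n_sims)) {
      draws <- integer(0)
      repeat {
        draws <- c(draws, sample.int(n, chunk, replace = TRUE, prob = w))
        firsts <- which(!duplicated(draws))
        if (length(firsts) == n) break
        if (length(draws) / 2 > patient_cap) break
      }
      if (length(firsts) < n) {
        warning("simulation exceeded patient_cap and was dropped",
                call. = FALSE)
        next
      }
      totals <- totals + ceiling(firsts[seq_len(n)] / 2)
      completed <- completed + 1L
    }
  })
  if (completed == 0L) stop("no simulation completed within patient_cap",
                            call. = FALSE)
  mean_patients <- totals / completed
  structure(list(
    rank = seq_len(n),
    mean_patients = mean_patients,
    mean_gap = c(NA_real_, diff(mean_patients)),
    n_variants = n,
    n_sims = completed,
    seed = seed
  ), class = "discovery_curve")
}

#' @export
print.discovery_curve <- function(x, ...) {
  cat("Discovery curve over", x$n_variants, "variants (",
      x$n_sims, "simulations )\n")
  print(utils::head(data.frame(rank = x$rank,
                               mean_patients = x$mean_patients), 10))
  if (x$n_variants > 10) cat("...\n")
  invisible(x)
}

#' Extrapolate a discovery curve beyond the known variant pool
#'
#' Fits a monotone piecewise-cubic interpolant (Fritsch-Carlson
#' construction, which cannot oscillate the way an unconstrained cubic
#' can) to the mean discovery curve and evaluates it at ranks
#' `n + 1 .. n + extra_ranks`, predicting how many patients must be
#' screened before variants absent from the reference pool are
#' encountered.
#'
#' @param curve A `"discovery_curve"` from [simulate_discovery()].
#' @param extra_ranks Number of ranks to extrapolate (default 1).
#' @return A data.frame with `rank` and `mean_patients` for the
#'   extrapolated ranks.
#' @export
extrapolate_discovery <- function(curve, extra_ranks = 1) {
  if (length(curve$rank) < 4) {
    stop("need at least 4 ranks to fit the discovery curve", call. = FALSE)
  }
  stopifnot(extra_ranks >= 1)
  fit <- stats::splinefun(curve$rank, curve$mean_patients,
                          method = "monoH.FC")
  new_ranks <- curve$n_variants + seq_len(extra_ranks)
  pred <- fit(new_ranks)
  if (any(diff(c(curve$mean_patients[curve$n_variants], pred)) <= 0)) {
    stop("extrapolated discovery curve is not strictly increasing",
         call. = FALSE)
  }
  data.frame(rank = new_ranks, mean_patients = pred)
}

#' Births per novel allele
#'
#' Converts a discovery rate among affected, molecularly screened
#' individuals into a population birth rate: if a novel allele turns up
#' every `patients_per_novel` affected patients and one affected patient is
#' born every `births_per_patient` births, a novel allele is encountered
#' once in `patients_per_novel * births_per_patient` births.
#'
#' @param patients_per_novel Mean patients screened per novel allele.
#' @param births_per_patient Reciprocal disease incidence (births per
#'   affected individual).
#' @return The `N` of "1 in N births".
#' @export
births_per_novel_allele <- function(patients_per_novel, births_per_patient) {
  if (!is.finite(patients_per_novel) || patients_per_novel <= 0 ||
      !is.finite(births_per_patient) || births_per_patient <= 0) {
    stop("both rates must be positive and finite", call. = FALSE)
  }
  patients_per_novel * births_per_patient
}
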