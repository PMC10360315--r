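variant_pool <- function(p, classes, an = 1e5, pop = "all") {
  df <- data.frame(id = sprintf("c.V%02d", seq_along(p)),
                   finalized_severity = classes,
                   stringsAsFactors = FALSE)
  df[[paste0("freq_", pop)]] <- p
  df[[paste0("an_", pop)]] <- an
  df
}

test_that("class frequencies sum members and use binomial variance", {
  pool <- variant_pool(c(0.001, 0.002, 0.5), c("severe", "severe", "benign"),
                       an = 1000)
  f <- severity_class_frequencies(pool, "finalized_severity", "all")
  expect_equal(f$p_hat[f$class == "severe"], 0.003)
  # binomial variance oracle p(1-p)/AN
  expect_equal(f$var[f$class == "benign"], 0.5 * 0.5 / 1000)
  expect_equal(f$var[f$class == "severe"],
               0.001 * 0.999 / 1000 + 0.002 * 0.998 / 1000)
  # empty class contributes zeros
  expect_equal(f$p_hat[f$class == "mild"], 0)
  expect_equal(f$var[f$class == "mild"], 0)
  expect_error(severity_class_frequencies(variant_pool(-0.1, "severe"),
                                          "finalized_severity", "all"),
               "negative")
  pool$freq_all[1] <- NA
  expect_warning(severity_class_frequencies(pool, "finalized_severity", "all"),
                 "treated as 0")
})

test_that("phenotype expectations follow the Hardy-Weinberg composition", {
  f <- data.frame(class = c("severe", "moderate", "mild", "benign", "unknown"),
                  p_hat = c(0.001, 0.001, 0, 0, 0),
                  var = 0, stringsAsFactors = FALSE)
  inc <- phenotype_incidence(f)
  expect_equal(inc$expected[inc$phenotype == "infantile"], 1e-6)
  expect_equal(inc$expected[inc$phenotype == "juvenile"], 2e-6)
  expect_equal(inc$variance[inc$phenotype == "infantile"], 0)
  # overall is exactly the sum of the three symptomatic phenotypes
  expect_equal(inc$expected[inc$phenotype == "overall"],
               sum(inc$expected[inc$phenotype %in%
                                  c("infantile", "juvenile", "adult")]))

  # GUS pairs an unknown allele with any pathogenic one
  f2 <- f
  f2$p_hat <- c(0.001, 0.002, 0.003, 0.004, 0.005)
  inc2 <- phenotype_incidence(f2)
  expect_equal(inc2$expected[inc2$phenotype == "unknown"],
               2 * 0.005 * (0.001 + 0.002 + 0.003) + 0.005^2)
  expect_equal(inc2$expected[inc2$phenotype == "asymptomatic"],
               0.003^2 + 2 * 0.003 * (0.002 + 0.004) +
                 2 * 0.004 * (0.001 + 0.002) + 0.004^2 + 2 * 0.005 * 0.004)
})

test_that("zero per-variant variance zeroes every propagated variance formula", {
  for (i in 1:20) {
    set.seed(i)
    f <- data.frame(class = c("severe", "moderate", "mild", "benign",
                              "unknown"),
                    p_hat = stats::runif(5, 0, 0.01),
                    var = 0, stringsAsFactors = FALSE)
    inc <- phenotype_incidence(f)
    analytic <- inc$variance[inc$phenotype %in%
                               c("infantile", "juvenile", "adult", "overall")]
    expect_equal(analytic, rep(0, 4), tolerance = 1e-18)
    incs <- phenotype_incidence(f, symmetric_juvenile_variance = TRUE)
    expect_equal(incs$variance[incs$phenotype == "juvenile"], 0,
                 tolerance = 1e-18)
  }
})

test_that("genotype frequencies conserve mass and scale quadratically", {
  set.seed(5)
  p <- stats::runif(5, 0, 0.02)
  # sum over the 15 unordered class-pair genotypes == (sum p)^2
  pairs <- which(upper.tri(diag(5), diag = TRUE), arr.ind = TRUE)
  total <- sum(genotype_incidence(p[pairs[, 1]], p[pairs[, 2]],
                                  homozygous = pairs[, 1] == pairs[, 2]))
  expect_equal(total, sum(p)^2)

  # scale property: frequencies times c scale every expectation by c^2
  f <- data.frame(class = c("severe", "moderate", "mild", "benign", "unknown"),
                  p_hat = p, var = 0, stringsAsFactors = FALSE)
  f2 <- f
  f2$p_hat <- 3 * f$p_hat
  expect_equal(phenotype_incidence(f2)$expected,
               9 * phenotype_incidence(f)$expected)

  expect_equal(genotype_incidence(0.5, 0.5), 0.5)
  expect_equal(genotype_incidence(0.5, homozygous = TRUE), 0.25)
})

test_that("published per-genotype incidences are recovered from NFE frequencies", {
  # c.465+1G>A homozygote at the printed 3-s.f. NFE frequency
  one_in_hom <- 1 / genotype_incidence(1.21e-3, homozygous = TRUE)
  expect_equal(one_in_hom, 683188, tolerance = 1e-3)
  # the heterozygote factor 2 is what makes the printed value reachable
  one_in_het <- 1 / genotype_incidence(1.21e-3, 6.3e-4)
  expect_equal(one_in_het, 651761, tolerance = 2e-2)
  expect_gt(1 / (1.21e-3 * 6.3e-4), 2 * 651761 * 0.98)  # without 2pq: off 2x
})

test_that("the beta interval matches moment oracles and degenerates correctly", {
  # uniform moments give Beta(1,1): quantiles 0.025 / 0.975
  ci <- analytic_ci(0.5, 1 / 12)
  expect_equal(unname(ci), c(0.025, 0.975))
  # shrinking variance collapses the interval onto the mean
  widths <- vapply(c(1e-4, 1e-6, 1e-8), function(v) {
    ci <- analytic_ci(0.01, v)
    ci[["high"]] - ci[["low"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], 1e-3)
  ci2 <- analytic_ci(0.3, 1e-4)
  expect_lt(ci2[["low"]], 0.3)
  expect_gt(ci2[["high"]], 0.3)
  expect_error(analytic_ci(0.5, 0.3), "no beta")
  expect_error(analytic_ci(0, 1e-4), "inside")
})

test_that("bootstrap intervals collapse without sampling noise and stay ordered", {
  pool <- variant_pool(c(2e-3, 1e-3, 5e-4), c("severe", "moderate", "mild"),
                       an = 1e9)
  # enormous allele numbers: resampling noise vanishes, CI pinches to a point
  bs <- bootstrap_ci(pool, "finalized_severity", "all", n_iter = 300, seed = 4)
  inf <- bs[bs$phenotype == "infantile", ]
  expect_equal(inf$ci_low, inf$expected, tolerance = 1e-3)
  expect_equal(inf$ci_high, inf$expected, tolerance = 1e-3)
  expect_true(all(bs$ci_low <= bs$ci_high))
  expect_warning(bootstrap_ci(pool, "finalized_severity", "all", n_iter = 50,
                              seed = 1), "unstable")
})

test_that("analytic and bootstrap intervals agree for infantile incidence", {
  pool <- variant_pool(c(1e-3, 8e-4, 2e-4), rep("severe", 3), an = 1e5)
  f <- severity_class_frequencies(pool, "finalized_severity", "all")
  inc <- phenotype_incidence(f)
  inf <- inc[inc$phenotype == "infantile", ]
  aci <- analytic_ci(inf$expected, inf$variance)
  bs <- bootstrap_ci(pool, "finalized_severity", "all", n_iter = 4000,
                     seed = 11)
  binf <- bs[bs$phenotype == "infantile", ]
  expect_equal(binf$ci_low, unname(aci["low"]), tolerance = 0.05)
  expect_equal(binf$ci_high, unname(aci["high"]), tolerance = 0.05)
})
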