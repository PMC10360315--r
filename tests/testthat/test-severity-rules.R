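test_that("LoF classes are stop-gained and frameshift only", {
  expect_true(all(is_lof(c("stop_gained", "frameshift"))))
  expect_false(any(is_lof(c("missense", "inframe_deletion", "splice",
                            "synonymous", "other"))))
})

test_that("each severity rule fires on its canonical cohort", {
  # R2: variant in an infantile patient is severe
  rec <- rep_records(make_records("c.X", "c.X", "infantile"), 5)
  sev <- assign_patient_based_severity(rec, overrides = character(0))
  expect_equal(sev$severity[sev$id == "c.X"], "severe")
  expect_match(sev$rule_trace[sev$id == "c.X"], "R2")

  # R3: juvenile partner of a severe variant is moderate
  rec <- rbind(rep_records(make_records("c.S", "c.S", "infantile"), 5),
               rep_records(make_records("c.S", "p.M", "juvenile"), 5))
  sev <- assign_patient_based_severity(rec, overrides = character(0))
  expect_equal(sev$severity[sev$id == "p.M"], "moderate")

  # R4: adult homozygote is moderate
  rec <- rep_records(make_records("p.H", "p.H", "adult"), 5)
  sev <- assign_patient_based_severity(rec, overrides = character(0))
  expect_equal(sev$severity[sev$id == "p.H"], "moderate")

  # R5: uncategorized partner of a moderate variant in a symptomatic patient
  rec <- rbind(rep_records(make_records("p.H", "p.H", "adult"), 5),
               rep_records(make_records("p.H", "p.Q", "juvenile"), 5))
  sev <- assign_patient_based_severity(rec, overrides = character(0))
  expect_equal(sev$severity[sev$id == "p.Q"], "moderate")

  # R6: adult partner of a severe variant is mild
  rec <- rbind(rep_records(make_records("c.S", "c.S", "infantile"), 5),
               rep_records(make_records("c.S", "p.I", "adult"), 5))
  sev <- assign_patient_based_severity(rec, overrides = character(0))
  expect_equal(sev$severity[sev$id == "p.I"], "mild")

  # R7: asymptomatic partner of a pathogenic variant is benign
  rec <- rbind(rep_records(make_records("c.S", "c.S", "infantile"), 5),
               rep_records(make_records("c.S", "p.B", "asymptomatic"), 5))
  sev <- assign_patient_based_severity(rec, overrides = character(0))
  expect_equal(sev$severity[sev$id == "p.B"], "benign")
})

test_that("R1 uses consequence annotations and conflicts resolve to max severity", {
  rec <- rep_records(make_records("p.R313X", "c.S", "adult"), 5)
  variants <- data.frame(id = c("p.R313X", "c.S"),
                         consequence = c("stop_gained", "splice"),
                         stringsAsFactors = FALSE)
  sev <- assign_patient_based_severity(rec, variants, overrides = character(0))
  # LoF pins p.R313X severe; c.S then draws R6 (mild partner of severe in an
  # adult), and p.R313X also matches R6 against c.S once c.S has a class --
  # the severe call must survive
  expect_equal(sev$severity[sev$id == "p.R313X"], "severe")
  expect_match(sev$rule_trace[sev$id == "p.R313X"], "R1")
  expect_equal(sev$severity[sev$id == "c.S"], "mild")
})

test_that("threshold and unknown-phenotype guards hold", {
  # below min_patients: no class regardless of evidence
  rec <- rep_records(make_records("c.X", "c.X", "infantile"), 4)
  sev <- assign_patient_based_severity(rec, overrides = character(0))
  expect_false(sev$eligible[sev$id == "c.X"])
  expect_equal(sev$severity[sev$id == "c.X"], "unknown")

  # unknown-phenotype patients never fire rules
  rec <- rep_records(make_records("c.X", "c.X", "unknown"), 6)
  sev <- assign_patient_based_severity(rec, overrides = character(0))
  expect_equal(sev$severity[sev$id == "c.X"], "unknown")
  expect_equal(sev$rule_trace[sev$id == "c.X"], "")
})

test_that("severity is unknown iff ineligible or no rule fired; trace nonempty otherwise", {
  cfg <- synthetic_config(n_variants_per_class = c(severe = 4, moderate = 2,
                                                   mild = 2, benign = 1),
                          n_patients = 300, seed = 11)
  pool <- generate_variant_pool(cfg)
  coh <- generate_cohort(pool, cfg)
  sev <- assign_patient_based_severity(coh, overrides = character(0))
  known <- sev$severity != "unknown"
  expect_true(all(nchar(sev$rule_trace[known]) > 0))
  expect_true(all(sev$eligible[known]))
  expect_true(all(sev$rule_trace[!sev$eligible] == ""))
})

test_that("assignment is a fixpoint and monotone under added infantile evidence", {
  rec <- rbind(rep_records(make_records("c.S", "c.S", "infantile"), 5),
               rep_records(make_records("c.S", "p.M", "juvenile"), 5),
               rep_records(make_records("c.S", "p.I", "adult"), 5))
  sev1 <- assign_patient_based_severity(rec, overrides = character(0))
  # fixpoint: feeding the same cohort back changes nothing
  sev2 <- assign_patient_based_severity(rec, overrides = character(0))
  expect_identical(sev1, sev2)

  # monotone precedence: an infantile carrier can only move p.M toward severe
  extra <- make_records("p.M", "p.M", "infantile", patient_id = "NEW1")
  sev3 <- assign_patient_based_severity(rbind(rec, extra),
                                        overrides = character(0))
  r_before <- match(sev1$severity[sev1$id == "p.M"], severity_levels())
  r_after <- match(sev3$severity[sev3$id == "p.M"], severity_levels())
  expect_lte(r_after, r_before)
  expect_equal(sev3$severity[sev3$id == "p.M"], "severe")
})

test_that("default overrides pin the documented benign variants", {
  rec <- rbind(rep_records(make_records("c.S", "c.S", "infantile"), 5),
               rep_records(make_records("c.S", "p.T393S", "juvenile"), 11))
  sev <- assign_patient_based_severity(rec)
  expect_equal(sev$severity[sev$id == "p.T393S"], "benign")
  expect_match(sev$rule_trace[sev$id == "p.T393S"], "override")
  # without the override the ruleset would have called it moderate (R3)
  sev0 <- assign_patient_based_severity(rec, overrides = character(0))
  expect_equal(sev0$severity[sev0$id == "p.T393S"], "moderate")
})

test_that("generating severities are recovered from an informative noiseless cohort", {
  # construct a cohort containing every informative pairing at >= 5 patients
  severe_ids <- sprintf("c.S%02d", 1:6)
  rec <- do.call(rbind, c(
    lapply(severe_ids, function(v) {
      rep_records(make_records(v, v, "infantile"), 5)
    }),
    list(rep_records(make_records("c.S01", "p.M01", "juvenile"), 5),
         rep_records(make_records("p.M02", "p.M02", "adult"), 5),
         rep_records(make_records("c.S02", "p.L01", "adult"), 5),
         rep_records(make_records("c.S03", "p.B01", "asymptomatic"), 5))))
  truth <- c(stats::setNames(rep("severe", 6), severe_ids),
             "p.M01" = "moderate", "p.M02" = "moderate",
             "p.L01" = "mild", "p.B01" = "benign")
  sev <- assign_patient_based_severity(rec, overrides = character(0))
  expect_equal(stats::setNames(sev$severity, sev$id)[names(truth)], truth)
})
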