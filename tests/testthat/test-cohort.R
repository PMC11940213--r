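test_that("default cohort reproduces the study bookkeeping", {
  co <- generate_cohort(cohort_spec(seed = 1))
  s <- co$subjects
  expect_equal(nrow(s), 80L)
  expect_equal(as.vector(table(factor(s$mutation_class,
                                      c("classical", "nonclassical", "VUS")))),
               c(18L, 54L, 8L))
  expect_equal(sum(s$sex == "male"), 38L)
  expect_equal(sum(s$retest), 16L)
  expect_equal(as.vector(table(co$samples$reader)), c(384L, 384L))
  expect_equal(nrow(unique(co$samples[, c("subject_id", "visit")])), 96L)
  expect_equal(nrow(co$retest), 16L * 4L * 2L)
  # BMI consistent with height and weight to rounding
  expect_lt(max(abs(s$bmi_kg_m2 - s$weight_kg / (s$height_cm / 100)^2)),
            0.06)
})

test_that("the degenerate noise-free limit collapses to a single T2", {
  sp <- cohort_spec(t2_classical_ms = 95, t2_nonclassical_ms = 95,
                    s1_l5_t2_ratio = 1, sd_subject_t2 = 0, sd_drg_t2 = 0,
                    sd_reader_t2 = 0, sd_visit_t2 = 0,
                    bmi_t2_correlation = 0)
  co <- generate_cohort(sp)
  expect_true(all(co$samples$t2_ms == 95))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_subjects = 0L), "sum to n_subjects")
  expect_error(cohort_spec(group_counts = c(classical = 20L,
                                            nonclassical = 54L, VUS = 8L)),
               "sum to n_subjects")
  expect_error(cohort_spec(n_retest = 100L), "n_retest")
  expect_error(cohort_spec(bmi_t2_correlation = -1), "correlation")
  expect_error(cohort_spec(male_counts = c(classical = 30L,
                                           nonclassical = 24L, VUS = 4L)),
               "male_counts")
})

test_that("the configured group T2 gap is realised on average", {
  gaps <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_spec(seed = s))
    base <- co$samples[co$samples$visit == "baseline", ]
    subj <- tapply(base$t2_ms, base$subject_id, mean)
    cls <- co$subjects$mutation_class[match(names(subj),
                                            co$subjects$subject_id)]
    median(subj[cls == "classical"]) - median(subj[cls == "nonclassical"])
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 8.8), 2)
})

test_that("seeded cohorts are reproducible and couple BMI to T2 negatively", {
  a <- generate_cohort(cohort_spec(seed = 42))
  b <- generate_cohort(cohort_spec(seed = 42))
  expect_identical(a, b)

  rhos <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_spec(seed = s))
    base <- co$samples[co$samples$visit == "baseline", ]
    subj <- tapply(base$t2_ms, base$subject_id, mean)
    bmi <- co$subjects$bmi_kg_m2[match(names(subj), co$subjects$subject_id)]
    cor(subj, bmi, method = "spearman")
  }, numeric(1))
  expect_lt(mean(rhos), -0.2)
  expect_gt(mean(rhos), -0.45)
})
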