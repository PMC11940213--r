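# Reliability analysis on the simulated cohort written by
# 01_simulate_cohort.R: inter-rater ICC on per-DRG baseline T2 (readers as
# raters) and test-retest ICC on subject-level consensus DRG-T2 (visits as
# raters).

source("analysis/00_config.R")

samples <- read.csv(file.path(RESULTS_DIR, "drg_samples.csv"))
consensus <- read.csv(file.path(RESULTS_DIR, "drg_consensus.csv"))

base <- samples[samples$visit == "baseline", ]
wide <- reshape(base[, c("subject_id", "level", "side", "reader", "t2_ms")],
                idvar = c("subject_id", "level", "side"),
                timevar = "reader", direction = "wide")
inter_rater <- icc_two_way_agreement(
  as.matrix(wide[, grep("^t2_ms\\.", names(wide))]))

retest_ids <- unique(consensus$subject_id[consensus$visit == "retest"])
v1 <- summarise_cohort(consensus[consensus$subject_id %in% retest_ids, ],
                       "baseline")
v2 <- summarise_cohort(consensus[consensus$subject_id %in% retest_ids, ],
                       "retest")
v2 <- v2[match(v1$subject_id, v2$subject_id), ]
test_retest <- test_retest_icc(v1$drg_t2_ms, v2$drg_t2_ms)

print(inter_rater)
print(test_retest)

jsonlite::write_json(list(inter_rater = unclass(inter_rater),
                          test_retest = unclass(test_retest)),
                     file.path(RESULTS_DIR, "reliability.json"),
                     auto_unbox = TRUE, digits = NA)
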