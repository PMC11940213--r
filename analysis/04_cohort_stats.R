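# Cohort statistics on the tables written by 01_simulate_cohort.R:
# stratified descriptive tables (mutation class, sex), paired level
# contrasts, the Spearman correlation screen and the headline percent
# differences.

source("analysis/00_config.R")

subjects_raw <- read.csv(file.path(RESULTS_DIR, "subjects.csv"))
consensus <- read.csv(file.path(RESULTS_DIR, "drg_consensus.csv"))

subjects <- merge(subjects_raw, summarise_cohort(consensus, "baseline"),
                  by = "subject_id")

tab_mut <- build_cohort_tables(subjects, "mutation_class",
                               variables = c("drg_t2_ms", "t2_l5_ms",
                                             "t2_s1_ms", "drg_vol_mm3",
                                             "age_years", "height_cm",
                                             "weight_kg", "bmi_kg_m2",
                                             "gla_activity_nmol_min_mg",
                                             "lyso_gb3_ng_ml"))
tab_sex <- build_cohort_tables(subjects, "sex",
                               variables = c("drg_t2_ms", "drg_vol_mm3",
                                             "vol_l5_mm3", "vol_s1_mm3",
                                             "age_years", "height_cm",
                                             "weight_kg", "bmi_kg_m2"))
write.csv(tab_mut, file.path(RESULTS_DIR, "table_mutation.csv"),
          row.names = FALSE)
write.csv(tab_sex, file.path(RESULTS_DIR, "table_sex.csv"),
          row.names = FALSE)

level_t2 <- wilcoxon_signed_rank(subjects$t2_s1_ms, subjects$t2_l5_ms)
level_vol <- wilcoxon_signed_rank(subjects$vol_s1_mm3, subjects$vol_l5_mm3)
correlations <- lapply(
  c(age = "age_years", height = "height_cm", weight = "weight_kg",
    bmi = "bmi_kg_m2", gla = "gla_activity_nmol_min_mg",
    lyso_gb3 = "lyso_gb3_ng_ml", volume = "drg_vol_mm3"),
  function(v) spearman_rho(subjects$drg_t2_ms, subjects[[v]]))

cls <- subjects$mutation_class
contrasts <- list(
  t2_s1_vs_l5 = percent_difference(median(subjects$t2_s1_ms),
                                   median(subjects$t2_l5_ms)),
  vol_s1_vs_l5 = percent_difference(median(subjects$vol_s1_mm3),
                                    median(subjects$vol_l5_mm3)),
  t2_classical_vs_nonclassical = percent_difference(
    median(subjects$drg_t2_ms[cls == "classical"]),
    median(subjects$drg_t2_ms[cls == "nonclassical"])),
  vol_male_vs_female = percent_difference(
    median(subjects$drg_vol_mm3[subjects$sex == "male"]),
    median(subjects$drg_vol_mm3[subjects$sex == "female"])))

jsonlite::write_json(list(level_contrast_t2 = unclass(level_t2),
                          level_contrast_vol = unclass(level_vol),
                          correlations = lapply(correlations, unclass),
                          contrasts = contrasts),
                     file.path(RESULTS_DIR, "cohort_stats.json"),
                     auto_unbox = TRUE, digits = NA)

print(tab_mut)
print(level_t2)
cat("percent differences:\n"); str(contrasts, give.attr = FALSE)
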