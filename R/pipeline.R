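#' Pipeline configuration
#'
#' Bundles the stage specifications of the end-to-end analysis: cohort
#' simulation, optional image-level phantom validation, reliability and
#' cohort statistics. Every section is validated by its owning constructor
#' before any computation starts.
#'
#' @param cohort A \code{\link{cohort_spec}}.
#' @param phantom A \code{\link{phantom_spec}} used as the template for the
#'   image-level validation subjects, or \code{NULL} to skip image-level
#'   stages.
#' @param n_phantom_subjects Number of phantom subjects to simulate, fit and
#'   extract.
#' @param fit A \code{\link{fit_config}}.
#' @param reader_perturb_rate Boundary toggle rate for simulated reader
#'   segmentations of the phantom masks.
#' @param summary VOI summary statistic.
#' @param seed Global seed; stage seeds are derived deterministically from
#'   it (stage index offsets), so a config + seed pair fixes every draw.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            phantom = phantom_spec(),
                            n_phantom_subjects = 2L,
                            fit = fit_config("epg_dict"),
                            reader_perturb_rate = 0.05,
                            summary = "median",
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"),
            is.null(phantom) || inherits(phantom, "phantom_spec"),
            inherits(fit, "fit_config"))
  if (n_phantom_subjects < 0L) stop("n_phantom_subjects must be >= 0")
  structure(list(cohort = cohort, phantom = phantom,
                 n_phantom_subjects = as.integer(n_phantom_subjects),
                 fit = fit, reader_perturb_rate = reader_perturb_rate,
                 summary = summary, seed = as.integer(seed)),
            class = "pipeline_config")
}

# derive a stage seed from the global seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1013L + stage * 9176L) %% 2147483629L
}

#' Run the phantom image-level validation arm
#'
#' For each phantom subject: simulate the multi-echo acquisition, fit the
#' configured T2 map, extract each ganglion with two simulated readers'
#' perturbed masks, and average readers to consensus.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List with \code{samples} (per-reader DRG rows),
#'   \code{consensus} (reader-averaged rows) and \code{truth} (per-ganglion
#'   true T2/volume per subject).
#' @export
run_phantom_arm <- function(config) {
  spec0 <- config$phantom
  if (is.null(spec0) || config$n_phantom_subjects == 0L)
    return(NULL)
  all_samples <- list(); truth <- list()
  for (s in seq_len(config$n_phantom_subjects)) {
    spec <- spec0
    spec$seed <- stage_seed(config$seed, 100L + s)
    ph <- generate_phantom(spec)
    tmap <- fit_volume(ph, config$fit)
    for (rd in 1:2) {
      m <- perturb_mask_as_reader(ph$mask, reader_id = rd,
                                  seed = stage_seed(config$seed, 200L + s),
                                  rate = config$reader_perturb_rate)
      for (i in seq_len(nrow(spec$drg_defs))) {
        d <- spec$drg_defs[i, ]
        voi <- extract_voi(tmap, m, d$label, summary = config$summary)
        all_samples[[length(all_samples) + 1L]] <- data.frame(
          subject_id = sprintf("P%02d", s), visit = "baseline",
          reader = paste0("R", rd), level = d$level, side = d$side,
          t2_ms = voi$t2_ms,
          volume_mm3 = compute_volume(m, d$label, spec$voxel_dims_mm),
          n_voxels = voi$n_voxels, stringsAsFactors = FALSE)
      }
    }
    truth[[s]] <- cbind(subject_id = sprintf("P%02d", s),
                        spec$drg_defs[, c("label", "level", "side",
                                          "true_t2_ms")])
  }
  samples <- do.call(rbind, all_samples)
  list(samples = samples,
       consensus = average_readers(samples[, setdiff(names(samples),
                                                     "n_voxels")]),
       truth = do.call(rbind, truth))
}

#' Run the full analysis pipeline
#'
#' Executes cohort simulation, reader averaging, subject summaries,
#' inter-rater and test-retest reliability, cohort tables, the paired
#' level contrast, the correlation screen and (optionally) the phantom
#' image-level validation arm, writing every artefact as CSV/JSON under
#' \code{out_dir} together with a manifest of MD5 checksums. Identical
#' config and seed yield identical checksums.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory (created if needed), or \code{NULL} to
#'   skip writing files.
#' @return List of stage results (invisibly includes the manifest when
#'   files are written).
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cspec <- config$cohort
  cspec$seed <- stage_seed(config$seed, 1L)
  cohort <- generate_cohort(cspec)

  consensus <- average_readers(cohort$samples)
  subj_base <- summarise_cohort(consensus, "baseline")
  subjects <- merge(cohort$subjects, subj_base, by = "subject_id")

  # inter-rater: per-DRG baseline T2, readers as raters
  base <- cohort$samples[cohort$samples$visit == "baseline", ]
  wide <- stats::reshape(
    base[, c("subject_id", "level", "side", "reader", "t2_ms")],
    idvar = c("subject_id", "level", "side"), timevar = "reader",
    direction = "wide")
  rater_cols <- grep("^t2_ms\\.", names(wide), value = TRUE)
  inter_rater <- icc_two_way_agreement(as.matrix(wide[, rater_cols]))

  # test-retest: subject-level consensus DRG-T2, visits as raters
  retest_ids <- unique(consensus$subject_id[consensus$visit == "retest"])
  trt <- NULL
  if (length(retest_ids) >= 2L) {
    v1 <- summarise_cohort(
      consensus[consensus$subject_id %in% retest_ids, ], "baseline")
    v2 <- summarise_cohort(
      consensus[consensus$subject_id %in% retest_ids, ], "retest")
    v2 <- v2[match(v1$subject_id, v2$subject_id), ]
    trt <- test_retest_icc(v1$drg_t2_ms, v2$drg_t2_ms)
  }

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

  level_t2 <- wilcoxon_signed_rank(subjects$t2_s1_ms, subjects$t2_l5_ms)
  level_vol <- wilcoxon_signed_rank(subjects$vol_s1_mm3,
                                    subjects$vol_l5_mm3)
  correlations <- lapply(
    c(age = "age_years", height = "height_cm", weight = "weight_kg",
      bmi = "bmi_kg_m2", gla = "gla_activity_nmol_min_mg",
      lyso_gb3 = "lyso_gb3_ng_ml", volume = "drg_vol_mm3"),
    function(v) spearman_rho(subjects$drg_t2_ms, subjects[[v]]))

  contrasts <- list(
    t2_s1_vs_l5 = percent_difference(
      stats::median(subjects$t2_s1_ms), stats::median(subjects$t2_l5_ms)),
    vol_s1_vs_l5 = percent_difference(
      stats::median(subjects$vol_s1_mm3),
      stats::median(subjects$vol_l5_mm3)),
    t2_classical_vs_nonclassical = percent_difference(
      stats::median(subjects$drg_t2_ms[subjects$mutation_class ==
                                         "classical"]),
      stats::median(subjects$drg_t2_ms[subjects$mutation_class ==
                                         "nonclassical"])),
    vol_male_vs_female = percent_difference(
      stats::median(subjects$drg_vol_mm3[subjects$sex == "male"]),
      stats::median(subjects$drg_vol_mm3[subjects$sex == "female"])))

  phantom <- run_phantom_arm(config)

  res <- list(cohort = cohort, consensus = consensus, subjects = subjects,
              inter_rater = inter_rater, test_retest = trt,
              table_mutation = tab_mut, table_sex = tab_sex,
              level_contrast_t2 = level_t2, level_contrast_vol = level_vol,
              correlations = correlations, contrasts = contrasts,
              phantom = phantom)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    paths <- c(
      wr(cohort$subjects, "subjects.csv"),
      wr(cohort$samples, "drg_samples.csv"),
      wr(consensus, "drg_consensus.csv"),
      wr(subjects, "subject_summaries.csv"),
      wr(tab_mut, "table_mutation.csv"),
      wr(tab_sex, "table_sex.csv"))
    stats_json <- file.path(out_dir, "stats.json")
    jsonlite::write_json(list(
      inter_rater = unclass(inter_rater),
      test_retest = if (!is.null(trt)) unclass(trt),
      level_contrast_t2 = unclass(level_t2),
      level_contrast_vol = unclass(level_vol),
      correlations = lapply(correlations, unclass),
      contrasts = contrasts), stats_json, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, stats_json)
    if (!is.null(phantom)) {
      paths <- c(paths, wr(phantom$samples, "phantom_samples.csv"),
                 wr(phantom$consensus, "phantom_consensus.csv"),
                 wr(phantom$truth, "phantom_truth.csv"))
    }
    manifest <- data.frame(file = basename(paths),
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    res$manifest <- manifest
  }
  res
}
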