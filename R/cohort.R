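#' Synthetic cohort specification
#'
#' Parameters of the table-level cohort generator. The defaults emulate the
#' design and group structure of an 80-patient Fabry-disease DRG study:
#' 18 classical / 54 nonclassical / 8 VUS subjects with the observed sex
#' split per group, a 16-subject retest subcohort, group DRG-T2 locations
#' of 102.4 ms (classical) and 93.6 ms (nonclassical; VUS follows the
#' nonclassical distribution), an S1:L5 T2 ratio of 1.042, an S1:L5 volume
#' ratio of 1.462, a male:female volume ratio of 1.359, and a negative
#' BMI-T2 rank correlation of about -0.32 induced through a shared latent
#' factor.
#'
#' @param n_subjects Total number of subjects.
#' @param group_counts Named counts for classical / nonclassical / VUS.
#' @param male_counts Named male counts per group (females are the rest).
#' @param n_retest Size of the retest subcohort.
#' @param t2_classical_ms,t2_nonclassical_ms Group DRG-T2 locations (ms).
#' @param s1_l5_t2_ratio S1:L5 T2 ratio (applied symmetrically so the
#'   subject mean equals the group location).
#' @param s1_l5_vol_ratio S1:L5 volume ratio.
#' @param male_female_volume_ratio Male:female DRG volume ratio.
#' @param vol_female_mm3 Female per-DRG volume scale (mm^3).
#' @param bmi_t2_correlation Target Spearman correlation between BMI and
#'   subject DRG-T2 (must lie in (-1, 1)).
#' @param sd_subject_t2 Between-subject T2 SD (ms).
#' @param sd_drg_t2 Within-subject between-DRG T2 SD (ms), shared between
#'   readers (it is a property of the ganglion, not of the reader).
#' @param sd_reader_t2 Per-reader measurement SD (ms).
#' @param sd_visit_t2 Between-visit (biological/positioning drift) SD (ms).
#' @param sdlog_vol_subject,sdlog_vol_drg,sdlog_vol_reader Log-normal SDs of
#'   the subject, per-ganglion and per-reader volume factors.
#' @param readers Reader identifiers.
#' @param seed Integer seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 80L,
                        group_counts = c(classical = 18L, nonclassical = 54L,
                                         VUS = 8L),
                        male_counts = c(classical = 10L, nonclassical = 24L,
                                        VUS = 4L),
                        n_retest = 16L,
                        t2_classical_ms = 102.4, t2_nonclassical_ms = 93.6,
                        s1_l5_t2_ratio = 1.042,
                        s1_l5_vol_ratio = 1.462,
                        male_female_volume_ratio = 1.359,
                        vol_female_mm3 = 990,
                        bmi_t2_correlation = -0.32,
                        sd_subject_t2 = 11, sd_drg_t2 = 6, sd_reader_t2 = 7,
                        sd_visit_t2 = 2,
                        sdlog_vol_subject = 0.30, sdlog_vol_drg = 0.12,
                        sdlog_vol_reader = 0.04,
                        readers = c("R1", "R2"), seed = 1L) {
  if (sum(group_counts) != n_subjects)
    stop("group_counts must sum to n_subjects")
  if (any(male_counts > group_counts))
    stop("male_counts cannot exceed group_counts")
  if (n_retest > n_subjects) stop("n_retest cannot exceed n_subjects")
  if (abs(bmi_t2_correlation) >= 1)
    stop("bmi_t2_correlation must lie in (-1, 1)")
  if (s1_l5_t2_ratio <= 0 || s1_l5_vol_ratio <= 0 ||
      male_female_volume_ratio <= 0)
    stop("ratios must be positive")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic DRG cohort
#'
#' Draws a subject table (covariates calibrated approximately to the
#' marginal medians/IQRs of the emulated study: sex-specific normal
#' anthropometrics, log-normal GLA activity and lyso-Gb3) and a per-DRG
#' sample table with 4 ganglia (bilateral L5 and S1) per subject per visit
#' per reader. DRG-T2 is a group location times symmetric level factors
#' plus subject, visit, ganglion and reader effects; volumes are log-normal
#' around sex- and level-scaled locations. A latent standard-normal factor
#' loads positively on BMI and negatively on the subject T2 effect so the
#' configured BMI-T2 rank correlation holds in expectation.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return List: \code{subjects} (one row per subject), \code{samples}
#'   (per-DRG, per-reader rows for every visit), \code{retest} (the retest
#'   visit subset of \code{samples}).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_subjects
    gc <- spec$group_counts
    class_vec <- rep(names(gc), gc)
    sex_vec <- unlist(lapply(names(gc), function(g)
      rep(c("male", "female"),
          c(spec$male_counts[[g]], gc[[g]] - spec$male_counts[[g]]))))
    ids <- sprintf("S%03d", seq_len(n))
    male <- sex_vec == "male"
    classical <- class_vec == "classical"

    # shared latent factor coupling BMI (+) and subject T2 (-).
    # Target Pearson r on the latent scale from the Spearman target via
    # the bivariate-normal relation rho_s = (6/pi) asin(r/2), inflated for
    # the dilution of the subject T2 effect by averaged measurement noise.
    z <- stats::rnorm(n)
    r_target <- 2 * sin(pi * abs(spec$bmi_t2_correlation) / 6)
    extra_var <- (spec$sd_drg_t2^2 + spec$sd_reader_t2^2 / 2) / 4
    a <- if (spec$sd_subject_t2 > 0) {
      dilution <- spec$sd_subject_t2 /
        sqrt(spec$sd_subject_t2^2 + extra_var)
      sqrt(min(r_target / dilution, 0.95))
    } else 0

    age <- round(pmin(pmax(
      stats::rnorm(n, ifelse(male, 37, 50), ifelse(male, 10, 15)), 18), 81))
    height <- round(stats::rnorm(n, ifelse(male, 178, 165),
                                 ifelse(male, 7, 4)), 1)
    bmi_mu <- ifelse(male, 24.7, 24.8) - 2.0 * classical
    bmi_sd <- ifelse(male, 2.8, 4.5)
    bmi <- bmi_mu + bmi_sd * (a * z + sqrt(1 - a^2) * stats::rnorm(n))
    bmi <- pmax(bmi, 15)
    weight <- round(bmi * (height / 100)^2, 1)
    bmi <- round(weight / (height / 100)^2, 1)

    gla <- signif(stats::rlnorm(n, meanlog = log(ifelse(male, 0.045, 0.28)),
                                sdlog = ifelse(male, 0.5, 0.4)), 2)
    lyso_mu <- log(c(classical = 40, nonclassical = 5, VUS = 1.5))[class_vec]
    lyso <- signif(stats::rlnorm(n, meanlog = lyso_mu + 0.6 * male,
                                 sdlog = 1.1), 3)

    t2_loc <- ifelse(classical, spec$t2_classical_ms,
                     spec$t2_nonclassical_ms)
    t2_subj <- t2_loc + spec$sd_subject_t2 *
      (-a * z + sqrt(1 - a^2) * stats::rnorm(n))
    vol_subj <- spec$vol_female_mm3 *
      ifelse(male, spec$male_female_volume_ratio, 1) *
      exp(stats::rnorm(n, sd = spec$sdlog_vol_subject))

    subjects <- data.frame(
      subject_id = ids, sex = sex_vec, mutation_class = class_vec,
      age_years = age, height_cm = height, weight_kg = weight,
      bmi_kg_m2 = bmi, gla_activity_nmol_min_mg = gla,
      lyso_gb3_ng_ml = lyso, stringsAsFactors = FALSE)

    retest_ids <- sort(sample(ids, spec$n_retest))
    subjects$retest <- subjects$subject_id %in% retest_ids

    # symmetric level factors: mean(L5, S1) = 1, S1/L5 = configured ratio
    rt <- spec$s1_l5_t2_ratio
    t2_fac <- c(L5 = 2 / (1 + rt), S1 = 2 * rt / (1 + rt))
    rv <- spec$s1_l5_vol_ratio
    vol_fac <- c(L5 = 2 / (1 + rv), S1 = 2 * rv / (1 + rv))

    make_visit <- function(id_sel, visit) {
      idx <- match(id_sel, ids)
      grid <- expand.grid(side = c("left", "right"), level = c("L5", "S1"),
                          subject_id = id_sel, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      si <- match(grid$subject_id, ids)
      visit_eff <- if (visit == "baseline") rep(0, length(idx))
        else stats::rnorm(length(idx), sd = spec$sd_visit_t2)
      names(visit_eff) <- id_sel
      # per-ganglion true values, shared across readers
      t2_true <- t2_subj[si] * t2_fac[grid$level] +
        visit_eff[grid$subject_id] +
        stats::rnorm(nrow(grid), sd = spec$sd_drg_t2)
      vol_true <- vol_subj[si] * vol_fac[grid$level] *
        exp(stats::rnorm(nrow(grid), sd = spec$sdlog_vol_drg))
      do.call(rbind, lapply(spec$readers, function(r) {
        data.frame(subject_id = grid$subject_id, visit = visit, reader = r,
                   level = grid$level, side = grid$side,
                   t2_ms = t2_true +
                     stats::rnorm(nrow(grid), sd = spec$sd_reader_t2),
                   volume_mm3 = vol_true *
                     exp(stats::rnorm(nrow(grid),
                                      sd = spec$sdlog_vol_reader)),
                   stringsAsFactors = FALSE)
      }))
    }
    samples <- rbind(make_visit(ids, "baseline"),
                     make_visit(retest_ids, "retest"))
    samples$t2_ms <- pmax(samples$t2_ms, 1)
    rownames(samples) <- NULL
    list(subjects = subjects, samples = samples,
         retest = samples[samples$visit == "retest", , drop = FALSE])
  })
}
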