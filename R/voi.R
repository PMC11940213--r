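#' Extract the T2 summary of one labelled VOI
#'
#' Applies a label mask to a T2 map and summarises the fitted voxels under
#' the label. The default summary is the median, matching how per-ganglion
#' T2 is usually reported; voxels the fit flagged as unfittable are excluded
#' from the T2 summary (but still count toward volume, which is defined by
#' the segmentation alone).
#'
#' @param t2_map A \code{t2_map} from \code{\link{fit_volume}}.
#' @param mask 3D integer label mask with the same grid and voxel
#'   dimensions as the map.
#' @param label Integer label to extract.
#' @param summary \code{"median"} or \code{"mean"}.
#' @return List: \code{t2_ms}, \code{n_voxels} (all voxels under the
#'   label), \code{n_excluded} (unfittable voxels excluded from the
#'   summary).
#' @export
extract_voi <- function(t2_map, mask, label, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  if (!identical(dim(t2_map$t2_ms), dim(mask)))
    stop("mask and T2 map grids differ")
  if (max(abs(t2_map$voxel_dims_mm - attr_voxel_dims(mask, t2_map))) > 1e-9)
    stop("mask and T2 map voxel dimensions differ")
  sel <- mask == label
  n_vox <- sum(sel)
  if (n_vox == 0L) stop("label ", label, " is empty")
  use <- sel & t2_map$fitted_mask
  if (!any(use)) stop("all voxels under label ", label, " are unfittable")
  vals <- t2_map$t2_ms[use]
  list(t2_ms = if (summary == "median") stats::median(vals) else mean(vals),
       n_voxels = n_vox, n_excluded = n_vox - sum(use))
}

# voxel dims attached to a mask (attribute) or inherited from the map
attr_voxel_dims <- function(mask, t2_map) {
  vd <- attr(mask, "voxel_dims_mm")
  if (is.null(vd)) t2_map$voxel_dims_mm else vd
}

#' VOI volume from voxel count
#'
#' Volume of a labelled VOI as the number of voxels under the label times
#' the voxel volume.
#'
#' @param mask 3D integer label mask.
#' @param label Integer label.
#' @param voxel_dims_mm Voxel dimensions in mm.
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask, label, voxel_dims_mm = c(1.5, 1.5, 1.8)) {
  n <- sum(mask == label)
  if (n == 0L) stop("label ", label, " is empty")
  n * prod(voxel_dims_mm)
}

#' Average per-DRG measurements across readers
#'
#' Collapses a per-reader DRG sample table to reader-consensus values: the
#' arithmetic mean of T2 (and of volume) across readers within each
#' (subject, visit, level, side) group. Every group must contain exactly
#' the full reader set.
#'
#' @param samples Data frame with columns \code{subject_id}, \code{visit},
#'   \code{reader}, \code{level}, \code{side}, \code{t2_ms},
#'   \code{volume_mm3}.
#' @param readers Expected reader identifiers; defaults to all readers
#'   present.
#' @return Data frame with one consensus row per group
#'   (\code{reader = "consensus"}).
#' @export
average_readers <- function(samples, readers = NULL) {
  if (is.null(readers)) readers <- sort(unique(samples$reader))
  key <- interaction(samples$subject_id, samples$visit, samples$level,
                     samples$side, drop = TRUE)
  counts <- table(key)
  bad <- names(counts)[counts != length(readers)]
  got <- tapply(samples$reader, key, function(r)
    length(unique(r)) == length(readers) && all(sort(unique(r)) == readers))
  bad <- union(bad, names(got)[!got])
  if (length(bad))
    stop("missing or duplicated reader measurements for: ",
         paste(utils::head(sort(bad), 5), collapse = ", "))
  agg <- stats::aggregate(samples[, c("t2_ms", "volume_mm3")],
                          by = list(subject_id = samples$subject_id,
                                    visit = samples$visit,
                                    level = samples$level,
                                    side = samples$side),
                          FUN = mean)
  agg$reader <- "consensus"
  agg[order(agg$subject_id, agg$visit, agg$level, agg$side),
      c("subject_id", "visit", "reader", "level", "side",
        "t2_ms", "volume_mm3")]
}

#' Summarise one subject-visit from its DRG samples
#'
#' Per-subject summaries are the mean of all DRG samples analysed for that
#' subject (this is also what removes the need for multiple-testing
#' adjustment downstream: one value per subject per quantity). Per-level
#' summaries use only that level's samples.
#'
#' @param samples Data frame of DRG samples for a single subject-visit with
#'   columns \code{level}, \code{t2_ms}, \code{volume_mm3}.
#' @return One-row data frame: \code{drg_t2_ms}, \code{drg_vol_mm3},
#'   \code{t2_l5_ms}, \code{t2_s1_ms}, \code{vol_l5_mm3}, \code{vol_s1_mm3},
#'   \code{n_drg}.
#' @export
summarise_subject <- function(samples) {
  if (nrow(samples) == 0L) stop("no samples for subject")
  lv <- function(l, col) {
    v <- samples[samples$level == l, col]
    if (length(v)) mean(v) else NA_real_
  }
  data.frame(drg_t2_ms = mean(samples$t2_ms),
             drg_vol_mm3 = mean(samples$volume_mm3),
             t2_l5_ms = lv("L5", "t2_ms"), t2_s1_ms = lv("S1", "t2_ms"),
             vol_l5_mm3 = lv("L5", "volume_mm3"),
             vol_s1_mm3 = lv("S1", "volume_mm3"),
             n_drg = nrow(samples))
}

#' Subject-level summary table from a consensus sample table
#'
#' Applies \code{\link{summarise_subject}} to every subject-visit in a
#' sample table (typically reader-consensus output of
#' \code{\link{average_readers}}).
#'
#' @param samples DRG sample table.
#' @param visit Which visit to summarise (default \code{"baseline"}).
#' @return Data frame with one row per subject.
#' @export
summarise_cohort <- function(samples, visit = "baseline") {
  samples <- samples[samples$visit == visit, , drop = FALSE]
  ids <- unique(samples$subject_id)
  out <- do.call(rbind, lapply(ids, function(id)
    summarise_subject(samples[samples$subject_id == id, , drop = FALSE])))
  cbind(data.frame(subject_id = ids, visit = visit,
                   stringsAsFactors = FALSE), out)
}
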