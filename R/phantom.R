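#' Default DRG ellipsoid definitions
#'
#' Four ellipsoidal ganglia (bilateral L5 and S1) sized so the S1 volume is
#' about 1.46 times the L5 volume, with absolute volumes near cohort-median
#' DRG volumes (roughly 900 and 1300 mm^3). Centres assume the default
#' 32 x 32 x 12 grid at 1.5 x 1.5 x 1.8 mm voxels (48 x 48 x 21.6 mm field
#' of view).
#'
#' @param t2_l5_ms,t2_s1_ms True T2 values (ms) assigned to the L5 and S1
#'   ganglia. Defaults sit near the cohort per-level medians and on the
#'   1 ms dictionary grid so noiseless recovery is exact.
#' @param pd Proton density of ganglion tissue (arbitrary units).
#' @return Data frame with one row per ganglion: \code{label} (integer mask
#'   value), \code{level}, \code{side}, centre (mm), semi-axes (mm),
#'   \code{true_t2_ms}, \code{true_pd}.
#' @export
default_drg_defs <- function(t2_l5_ms = 93, t2_s1_ms = 97, pd = 1) {
  r_l5 <- 6.0                      # (4/3) pi r^3 ~ 905 mm^3
  r_s1 <- 6.0 * 1.462^(1 / 3)      # ~1.46 x L5 volume
  data.frame(
    label = 1:4,
    level = c("L5", "L5", "S1", "S1"),
    side = c("left", "right", "left", "right"),
    cx_mm = c(12, 36, 12, 36),
    cy_mm = c(12, 12, 36, 36),
    cz_mm = rep(10.8, 4),
    ax_mm = c(r_l5, r_l5, r_s1, r_s1),
    ay_mm = c(r_l5, r_l5, r_s1, r_s1),
    az_mm = c(r_l5, r_l5, r_s1, r_s1),
    true_t2_ms = c(t2_l5_ms, t2_l5_ms, t2_s1_ms, t2_s1_ms),
    true_pd = pd,
    stringsAsFactors = FALSE
  )
}

#' Digital DRG phantom specification
#'
#' Describes a synthetic multi-echo acquisition over a voxel grid containing
#' ellipsoidal ganglia embedded in a uniform background, traversed by a
#' smooth multiplicative B1 (flip-angle scale) field, and observed with
#' Rician noise.
#'
#' @param grid_shape Integer vector of three voxel counts.
#' @param voxel_dims_mm Voxel dimensions in mm.
#' @param drg_defs Ganglion table as from \code{\link{default_drg_defs}}.
#' @param background_t2_ms,background_pd Background tissue T2 (ms) and
#'   proton density.
#' @param b1_field B1 field description: either
#'   \code{list(kind = "uniform", value = v)} or
#'   \code{list(kind = "gaussian_bump", base, amplitude, centre_frac,
#'   width_frac)} (a smooth bump; values are clipped to [0.6, 1.1]) or
#'   \code{list(kind = "random")}, which draws bump coefficients from the
#'   phantom seed.
#' @param snr Signal-to-noise ratio at the first echo relative to the
#'   maximum proton density; \code{Inf} gives a noiseless phantom.
#' @param t1_ms Assumed longitudinal relaxation time (ms), shared with the
#'   fitting defaults.
#' @param params Acquisition descriptor (\code{\link{echo_train_params}});
#'   its \code{voxel_dims_mm} is overridden by this spec's.
#' @param seed Integer seed for the noise (and random B1) draws.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 12L),
                         voxel_dims_mm = c(1.5, 1.5, 1.8),
                         drg_defs = default_drg_defs(),
                         background_t2_ms = 45, background_pd = 0.5,
                         b1_field = list(kind = "gaussian_bump", base = 0.82,
                                         amplitude = 0.22,
                                         centre_frac = c(0.5, 0.5, 0.5),
                                         width_frac = 0.7),
                         snr = 50, t1_ms = 1000,
                         params = echo_train_params(), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be three positive integers")
  if (any(voxel_dims_mm <= 0)) stop("voxel_dims_mm must be positive")
  if (!is.data.frame(drg_defs) || nrow(drg_defs) < 1L)
    stop("drg_defs must be a non-empty data frame")
  if (any(drg_defs[, c("ax_mm", "ay_mm", "az_mm")] <= 0))
    stop("ellipsoid semi-axes must be positive")
  if (any(drg_defs$true_t2_ms <= 10 | drg_defs$true_t2_ms >= 500))
    stop("true_t2_ms must lie in (10, 500) ms")
  if (!is.infinite(snr) && snr <= 0) stop("snr must be > 0")
  params$voxel_dims_mm <- voxel_dims_mm
  structure(list(grid_shape = grid_shape, voxel_dims_mm = voxel_dims_mm,
                 drg_defs = drg_defs, background_t2_ms = background_t2_ms,
                 background_pd = background_pd, b1_field = b1_field,
                 snr = snr, t1_ms = t1_ms, params = params,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre world coordinates (mm) along each axis
voxel_centres_mm <- function(grid_shape, voxel_dims_mm) {
  lapply(1:3, function(i) (seq_len(grid_shape[i]) - 0.5) * voxel_dims_mm[i])
}

# evaluate the B1 (flip-scale) field on the grid; returns a 3D array
evaluate_b1_field <- function(spec) {
  b1 <- spec$b1_field
  dims <- spec$grid_shape
  if (identical(b1$kind, "uniform")) {
    return(array(b1$value, dim = dims))
  }
  if (identical(b1$kind, "random")) {
    coef <- withr::with_seed(spec$seed + 7919L, list(
      base = stats::runif(1, 0.75, 0.95),
      amplitude = stats::runif(1, 0.05, 0.15),
      centre_frac = stats::runif(3, 0.3, 0.7),
      width_frac = stats::runif(1, 0.4, 0.9)
    ))
    b1 <- c(list(kind = "gaussian_bump"), coef)
  }
  if (!identical(b1$kind, "gaussian_bump"))
    stop("unknown b1_field kind: ", b1$kind)
  ext <- dims * spec$voxel_dims_mm
  cc <- voxel_centres_mm(dims, spec$voxel_dims_mm)
  ctr <- b1$centre_frac * ext
  w <- b1$width_frac * max(ext)
  d2 <- outer(outer((cc[[1]] - ctr[1])^2, (cc[[2]] - ctr[2])^2, `+`),
              (cc[[3]] - ctr[3])^2, `+`)
  field <- b1$base + b1$amplitude * exp(-d2 / (2 * w^2))
  field[field < 0.6] <- 0.6
  field[field > 1.1] <- 1.1
  field
}

# rasterise the ellipsoids into an integer label mask; errors on overlap
rasterise_drg <- function(spec) {
  dims <- spec$grid_shape
  cc <- voxel_centres_mm(dims, spec$voxel_dims_mm)
  mask <- array(0L, dim = dims)
  for (i in seq_len(nrow(spec$drg_defs))) {
    d <- spec$drg_defs[i, ]
    q <- outer(outer(((cc[[1]] - d$cx_mm) / d$ax_mm)^2,
                     ((cc[[2]] - d$cy_mm) / d$ay_mm)^2, `+`),
               ((cc[[3]] - d$cz_mm) / d$az_mm)^2, `+`)
    inside <- q <= 1
    if (any(mask[inside] != 0L))
      stop("DRG ellipsoids overlap on the grid (labels ",
           unique(mask[inside][mask[inside] != 0L])[1], " and ", d$label, ")")
    mask[inside] <- as.integer(d$label)
  }
  mask
}

#' Generate a digital DRG phantom
#'
#' Builds a noiseless multi-echo volume from the EPG signal model (per-voxel
#' signal = PD x EPG echo amplitudes at the voxel's true T2 and local B1
#' scale), then applies Rician noise: two independent Gaussian channels of
#' standard deviation \code{max(PD)/snr} added in quadrature, as arises in
#' magnitude MRI.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A list of class \code{drg_phantom}: \code{volume} (4D array,
#'   x,y,z,echo), \code{mask} (3D integer labels), \code{truth} (list with
#'   per-voxel \code{t2_ms}, \code{pd}, \code{b1} arrays and the
#'   \code{drg_defs} table), \code{echo_times_ms}, \code{voxel_dims_mm},
#'   \code{params}, \code{spec}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  mask <- rasterise_drg(spec)
  b1 <- evaluate_b1_field(spec)

  t2 <- array(spec$background_t2_ms, dim = dims)
  pd <- array(spec$background_pd, dim = dims)
  for (i in seq_len(nrow(spec$drg_defs))) {
    d <- spec$drg_defs[i, ]
    sel <- mask == d$label
    t2[sel] <- d$true_t2_ms
    pd[sel] <- d$true_pd
  }

  ne <- spec$params$n_echoes
  sig <- epg_cpmg_batch(as.vector(t2), as.vector(b1), t1_ms = spec$t1_ms,
                        params = spec$params)
  sig <- sig * as.vector(pd)

  if (!is.infinite(spec$snr)) {
    sigma <- max(pd) / spec$snr
    sig <- withr::with_seed(spec$seed, {
      n1 <- matrix(stats::rnorm(length(sig), sd = sigma), nrow(sig), ne)
      n2 <- matrix(stats::rnorm(length(sig), sd = sigma), nrow(sig), ne)
      sqrt((sig + n1)^2 + n2^2)
    })
  }
  vol <- array(sig, dim = c(dims, ne))

  structure(list(volume = vol, mask = mask,
                 truth = list(t2_ms = t2, pd = pd, b1 = b1,
                              drg_defs = spec$drg_defs),
                 echo_times_ms = echo_times(spec$params),
                 voxel_dims_mm = spec$voxel_dims_mm,
                 params = spec$params, spec = spec),
            class = "drg_phantom")
}

# logical array of voxels 6-adjacent to `sel` (excluding sel itself),
# and of sel voxels having at least one neighbour outside sel
shift_any <- function(sel) {
  d <- dim(sel)
  out <- array(FALSE, dim = d)
  idx <- function(n, off) {
    i <- seq_len(n) + off
    i[i < 1L | i > n] <- NA
    i
  }
  for (ax in 1:3) for (off in c(-1L, 1L)) {
    ii <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ii[[ax]] <- idx(d[ax], off)
    sh <- array(FALSE, dim = d)
    ok <- !is.na(ii[[ax]])
    ji <- ii
    ji[[ax]] <- ii[[ax]][ok]
    ki <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ki[[ax]] <- which(ok)
    sh[ki[[1]], ki[[2]], ki[[3]]] <- sel[ji[[1]], ji[[2]], ji[[3]]]
    out <- out | sh
  }
  out
}

#' Simulate a reader's manual segmentation of a mask
#'
#' Emulates inter-reader segmentation variability by randomly toggling
#' boundary voxels of each label: surface voxels of the label may be removed
#' and background voxels touching the label may be added, each independently
#' with probability \code{rate}. Removals are restricted to surface voxels
#' (the interior is never carved out), so moderate rates preserve
#' connectivity; additions never overwrite a different label.
#'
#' @param mask 3D integer label mask.
#' @param reader_id Identifier mixed into the random stream so different
#'   readers perturb differently under the same seed.
#' @param seed Integer seed.
#' @param rate Per-boundary-voxel toggle probability in [0, 0.5].
#' @param labels Labels to perturb; defaults to all non-zero labels.
#' @return Perturbed copy of \code{mask}.
#' @export
perturb_mask_as_reader <- function(mask, reader_id = 1L, seed = 1L,
                                   rate = 0.05, labels = NULL) {
  if (rate < 0 || rate > 0.5) stop("rate must be in [0, 0.5]")
  if (is.null(labels)) labels <- sort(setdiff(unique(as.vector(mask)), 0L))
  if (length(labels) == 0L) stop("mask has no labels")
  if (rate == 0) return(mask)
  out <- mask
  withr::with_seed(as.integer(seed) + 1000003L * as.integer(reader_id), {
    for (lab in labels) {
      sel <- out == lab
      if (!any(sel)) stop("label ", lab, " absent from mask")
      touch <- shift_any(sel)
      add_cand <- which(touch & out == 0L)
      rem_cand <- which(sel & shift_any(!sel))
      add <- add_cand[stats::runif(length(add_cand)) < rate]
      rem <- rem_cand[stats::runif(length(rem_cand)) < rate]
      if (sum(sel) - length(rem) + length(add) < 1L)
        stop("perturbation would empty label ", lab)
      out[rem] <- 0L
      out[add] <- as.integer(lab)
    }
  })
  out
}
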