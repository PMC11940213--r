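#' Echo-train acquisition parameters
#'
#' Describes a multi-echo spin-echo (CPMG) acquisition: a 90 degree
#' excitation followed by a train of nominally 180 degree refocusing pulses
#' at constant spacing. Defaults match a 3T lumbosacral DRG protocol with
#' ten echoes spaced 15 ms apart.
#'
#' @param n_echoes Number of echoes in the train (>= 1).
#' @param delta_te_ms Echo spacing in milliseconds (> 0).
#' @param tr_s Repetition time in seconds (informational; long TR is assumed
#'   so longitudinal magnetization is fully recovered at excitation).
#' @param nominal_refocus_deg Nominal refocusing flip angle in degrees.
#' @param excitation_deg Excitation flip angle in degrees (treated as ideal).
#' @param voxel_dims_mm Voxel dimensions in mm (in-plane x, in-plane y,
#'   slice), used by the phantom and volumetry code.
#' @return An object of class \code{echo_train_params}.
#' @export
echo_train_params <- function(n_echoes = 10L, delta_te_ms = 15, tr_s = 4.8,
                              nominal_refocus_deg = 180, excitation_deg = 90,
                              voxel_dims_mm = c(1.5, 1.5, 1.8)) {
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 1L) stop("n_echoes must be >= 1")
  if (delta_te_ms <= 0) stop("delta_te_ms must be > 0")
  if (length(voxel_dims_mm) != 3L || any(voxel_dims_mm <= 0))
    stop("voxel_dims_mm must be three positive values")
  structure(list(n_echoes = n_echoes, delta_te_ms = delta_te_ms, tr_s = tr_s,
                 nominal_refocus_deg = nominal_refocus_deg,
                 excitation_deg = excitation_deg,
                 voxel_dims_mm = voxel_dims_mm),
            class = "echo_train_params")
}

#' Echo times of an echo train
#'
#' @param params An \code{echo_train_params} object.
#' @return Numeric vector of echo times in ms (\code{delta_te_ms * 1:n}).
#' @export
echo_times <- function(params = echo_train_params()) {
  params$delta_te_ms * seq_len(params$n_echoes)
}

#' CPMG echo amplitudes by the extended phase graph recursion
#'
#' Computes the echo amplitudes of a CPMG multi-echo spin-echo train under
#' an imperfect refocusing flip angle, using the extended phase graph (EPG)
#' formalism. Dephasing is tracked in integer configuration orders (ideal
#' crushers, no diffusion); the excitation pulse is treated as an ideal 90
#' degree pulse about x and refocusing pulses are applied about y with
#' effective flip angle \code{b1_scale * nominal_refocus_deg} (the CPMG phase
#' convention). T1 recovery of the longitudinal configuration of order zero
#' is included; stimulated-echo pathways arising from imperfect refocusing
#' are fully represented. At \code{b1_scale = 1} the result is the ideal
#' mono-exponential decay \code{exp(-TE/T2)}.
#'
#' @param t2_ms Transverse relaxation time in ms (> 0).
#' @param t1_ms Longitudinal relaxation time in ms (>= t2_ms).
#' @param b1_scale Multiplicative flip-angle scale (0 < b1_scale <= 1.2).
#' @param params Acquisition descriptor, see \code{\link{echo_train_params}}.
#' @return Numeric vector of \code{n_echoes} echo amplitudes on the unit
#'   magnetization scale (all in \code{[0, 1]}).
#' @seealso \code{\link{isochromat_cpmg}} for a brute-force Bloch-simulation
#'   cross-check, \code{\link{epg_cpmg_batch}} for the vectorised form used
#'   to build fitting dictionaries.
#' @export
epg_cpmg <- function(t2_ms, t1_ms = 1000, b1_scale = 1,
                     params = echo_train_params()) {
  drop(epg_cpmg_batch(t2_ms, b1_scale, t1_ms = t1_ms, params = params))
}

#' Vectorised EPG CPMG signal model
#'
#' Batch form of \code{\link{epg_cpmg}}: evaluates the echo train for many
#' (T2, B1) pairs at once. \code{t2_ms} and \code{b1_scale} are recycled to a
#' common length.
#'
#' @inheritParams epg_cpmg
#' @return Matrix of dim \code{length(pairs) x n_echoes} of echo amplitudes.
#' @export
epg_cpmg_batch <- function(t2_ms, b1_scale, t1_ms = 1000,
                           params = echo_train_params()) {
  n <- max(length(t2_ms), length(b1_scale))
  t2_ms <- rep_len(t2_ms, n)
  b1_scale <- rep_len(b1_scale, n)
  if (any(t2_ms <= 0)) stop("t2_ms must be > 0")
  if (any(b1_scale <= 0)) stop("b1_scale must be > 0")
  if (any(b1_scale > 1.2)) stop("b1_scale must be <= 1.2")
  if (any(t1_ms < t2_ms)) stop("t1_ms must be >= t2_ms")

  ne <- params$n_echoes
  nk <- ne + 2L                      # configuration orders 0..ne+1
  tau <- params$delta_te_ms / 2      # half echo spacing
  e2 <- exp(-tau / t2_ms)
  e1 <- exp(-tau / rep_len(t1_ms, n))

  alpha <- b1_scale * params$nominal_refocus_deg * pi / 180
  ca2 <- cos(alpha / 2)^2
  sa2 <- sin(alpha / 2)^2
  sa <- sin(alpha)
  ca <- cos(alpha)

  # state matrices, one row per (t2, b1) pair, one column per order k = 0..nk-1
  Fp <- matrix(0 + 0i, n, nk)
  Fm <- matrix(0 + 0i, n, nk)
  Z  <- matrix(0 + 0i, n, nk)
  Fp[, 1L] <- -1i                    # ideal 90x excitation: M+ = -i

  zero_col <- matrix(0 + 0i, n, 1L)
  out <- matrix(0, n, ne)
  for (e in seq_len(ne)) {
    # relax over tau (Z0 recovers toward equilibrium)
    Fp <- Fp * e2; Fm <- Fm * e2
    Z <- Z * e1; Z[, 1L] <- Z[, 1L] + (1 - e1)
    # dephase one order
    Fp <- cbind(Conj(Fm[, 2L, drop = FALSE]), Fp[, -nk, drop = FALSE])
    Fm <- cbind(Fm[, -1L, drop = FALSE], zero_col)
    # refocusing pulse about y (angle alpha); coefficients recycle down rows
    # so states are laid out pairs x orders
    Fp2 <- ca2 * Fp - sa2 * Fm + sa * Z
    Fm2 <- -sa2 * Fp + ca2 * Fm + sa * Z
    Z   <- -(sa / 2) * Fp - (sa / 2) * Fm + ca * Z
    Fp <- Fp2; Fm <- Fm2
    # dephase one order
    Fp <- cbind(Conj(Fm[, 2L, drop = FALSE]), Fp[, -nk, drop = FALSE])
    Fm <- cbind(Fm[, -1L, drop = FALSE], zero_col)
    # relax over tau; echo forms at order zero
    Fp <- Fp * e2; Fm <- Fm * e2
    Z <- Z * e1; Z[, 1L] <- Z[, 1L] + (1 - e1)
    out[, e] <- Mod(Fp[, 1L])
  }
  out
}

#' Brute-force isochromat CPMG simulation
#'
#' Independent validation oracle for \code{\link{epg_cpmg}}: simulates
#' \code{n_spins} isochromats whose intravoxel dephasing angles uniformly
#' span one crusher cycle per half echo spacing, applies per-spin Bloch
#' rotations (ideal 90x excitation, refocusing about y at the effective flip
#' angle) with T2/T1 relaxation, and returns the magnitude of the complex
#' mean transverse magnetization at each echo. Converges to the EPG result
#' as \code{n_spins} grows.
#'
#' @inheritParams epg_cpmg
#' @param n_spins Number of isochromats (>= 100).
#' @return Numeric vector of \code{n_echoes} echo amplitudes.
#' @export
isochromat_cpmg <- function(t2_ms, t1_ms = 1000, b1_scale = 1,
                            params = echo_train_params(), n_spins = 2000L) {
  if (t2_ms <= 0) stop("t2_ms must be > 0")
  if (b1_scale <= 0) stop("b1_scale must be > 0")
  if (n_spins < 100L) stop("n_spins must be >= 100")

  ne <- params$n_echoes
  tau <- params$delta_te_ms / 2
  e2 <- exp(-tau / t2_ms)
  e1 <- exp(-tau / t1_ms)
  alpha <- b1_scale * params$nominal_refocus_deg * pi / 180

  # deterministic midpoint grid over one cycle of crusher dephasing per tau
  theta <- 2 * pi * (seq_len(n_spins) - 0.5) / n_spins
  ct <- cos(theta); st <- sin(theta)

  # after ideal 90x excitation: M = (0, -1, 0) for every spin
  mx <- rep(0, n_spins); my <- rep(-1, n_spins); mz <- rep(0, n_spins)
  ca <- cos(alpha); sa <- sin(alpha)

  relax_precess <- function() {
    mx2 <- (mx * ct - my * st) * e2
    my2 <- (mx * st + my * ct) * e2
    mx <<- mx2; my <<- my2
    mz <<- mz * e1 + (1 - e1)
  }
  out <- numeric(ne)
  for (e in seq_len(ne)) {
    relax_precess()
    # refocusing rotation about y
    mx2 <- mx * ca + mz * sa
    mz2 <- -mx * sa + mz * ca
    mx <- mx2; mz <- mz2
    relax_precess()
    out[e] <- Mod(complex(real = mean(mx), imaginary = mean(my)))
  }
  out
}
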