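#' Voxelwise T2 fitting configuration
#'
#' @param method One of \code{"epg_dict"} (B1-corrected dictionary matching,
#'   the default map-generation method), \code{"loglinear"} (weighted
#'   log-linear baseline) or \code{"nlls"} (bounded nonlinear least squares).
#' @param t2_bounds_ms Lower/upper T2 bounds (ms); estimates are clipped to
#'   these bounds and flagged, not rejected.
#' @param dict_t2_grid T2 grid (ms) of the EPG dictionary.
#' @param dict_b1_grid B1 flip-scale grid of the EPG dictionary.
#' @param t1_assumed_ms Assumed T1 (ms) shared with the simulator.
#' @param first_echo_policy \code{"keep"} or \code{"drop"}; \code{NULL}
#'   selects the per-method default: \code{drop} for the pure-exponential
#'   fits (echo 1 is the echo whose amplitude deviates most from the
#'   mono-exponential under imperfect refocusing) and \code{keep} for
#'   \code{epg_dict}, which models that deviation.
#' @param background_threshold Minimum first-echo signal, as a fraction of
#'   the volume maximum, below which a voxel is not fitted.
#' @param params Acquisition descriptor used to build the dictionary.
#' @return An object of class \code{fit_config}.
#' @export
fit_config <- function(method = c("epg_dict", "loglinear", "nlls"),
                       t2_bounds_ms = c(10, 500),
                       dict_t2_grid = seq(10, 300, by = 1),
                       dict_b1_grid = seq(0.50, 1.20, by = 0.01),
                       t1_assumed_ms = 1000,
                       first_echo_policy = NULL,
                       background_threshold = 0.05,
                       params = echo_train_params()) {
  method <- match.arg(method)
  if (any(t2_bounds_ms <= 0) || diff(t2_bounds_ms) <= 0)
    stop("t2_bounds_ms must be positive and increasing")
  if (is.unsorted(dict_t2_grid, strictly = TRUE) ||
      is.unsorted(dict_b1_grid, strictly = TRUE))
    stop("dictionary grids must be strictly increasing")
  if (background_threshold < 0 || background_threshold >= 1)
    stop("background_threshold must be in [0, 1)")
  if (is.null(first_echo_policy))
    first_echo_policy <- if (method == "epg_dict") "keep" else "drop"
  first_echo_policy <- match.arg(first_echo_policy, c("keep", "drop"))
  structure(list(method = method, t2_bounds_ms = t2_bounds_ms,
                 dict_t2_grid = dict_t2_grid, dict_b1_grid = dict_b1_grid,
                 t1_assumed_ms = t1_assumed_ms,
                 first_echo_policy = first_echo_policy,
                 background_threshold = background_threshold,
                 params = params),
            class = "fit_config")
}

apply_first_echo_policy <- function(signals, tes, policy) {
  if (policy == "drop" && length(tes) > 2L) {
    list(signals = signals[, -1L, drop = FALSE], tes = tes[-1L])
  } else {
    list(signals = signals, tes = tes)
  }
}

as_signal_matrix <- function(echo_signals) {
  if (is.matrix(echo_signals)) echo_signals
  else matrix(echo_signals, nrow = 1L)
}

#' Log-linear mono-exponential T2 fit
#'
#' Weighted least squares of \code{log(signal)} on echo time with weights
#' proportional to \code{signal^2}, undoing the heteroscedasticity induced
#' by the log transform; \code{T2 = -1/slope}. Voxels with any non-positive
#' retained signal are marked unfittable; estimates outside the bounds are
#' clipped and flagged.
#'
#' @param echo_signals Numeric vector (one voxel) or matrix (voxels x
#'   echoes) of magnitude signals.
#' @param echo_times_ms Echo times (ms), one per column.
#' @param config A \code{\link{fit_config}}.
#' @return Data frame with one row per voxel: \code{t2_ms}, \code{s0},
#'   \code{residual_rms}, \code{clipped}, \code{unfittable}.
#' @export
fit_loglinear <- function(echo_signals, echo_times_ms,
                          config = fit_config("loglinear")) {
  S <- as_signal_matrix(echo_signals)
  if (ncol(S) != length(echo_times_ms))
    stop("echo count does not match echo_times_ms")
  fe <- apply_first_echo_policy(S, echo_times_ms, config$first_echo_policy)
  S <- fe$signals; tes <- fe$tes
  if (ncol(S) < 2L) stop("need >= 2 retained echoes")

  ok <- rowSums(S <= 0) == 0L
  n <- nrow(S)
  t2 <- s0 <- res <- rep(NA_real_, n)
  clipped <- rep(FALSE, n)
  if (any(ok)) {
    Y <- log(S[ok, , drop = FALSE])
    W <- S[ok, , drop = FALSE]^2
    sw <- rowSums(W)
    xbar <- (W %*% tes) / sw
    ybar <- rowSums(W * Y) / sw
    xc <- outer(as.vector(xbar), tes, function(a, b) b - a)
    sxx <- rowSums(W * xc^2)
    sxy <- rowSums(W * xc * (Y - as.vector(ybar)))
    slope <- sxy / sxx
    t2ok <- ifelse(slope < 0, -1 / slope, Inf)
    lo <- config$t2_bounds_ms[1]; hi <- config$t2_bounds_ms[2]
    cl <- t2ok < lo | t2ok > hi
    t2ok <- pmin(pmax(t2ok, lo), hi)
    s0ok <- exp(as.vector(ybar) + as.vector(xbar) / t2ok)
    pred <- s0ok * exp(-outer(1 / t2ok, tes))
    resok <- sqrt(rowMeans((S[ok, , drop = FALSE] - pred)^2))
    t2[ok] <- t2ok; s0[ok] <- s0ok; res[ok] <- resok; clipped[ok] <- cl
  }
  data.frame(t2_ms = t2, s0 = s0, residual_rms = res,
             clipped = clipped, unfittable = !ok)
}

#' Nonlinear least-squares mono-exponential T2 fit
#'
#' Bounded Levenberg-Marquardt fit of \code{S0 * exp(-TE/T2)} per voxel,
#' initialised from the log-linear estimate. If the optimiser fails the
#' log-linear estimate is returned with \code{fallback = TRUE}.
#'
#' @inheritParams fit_loglinear
#' @param init_t2_ms Optional starting T2 (recycled over voxels), replacing
#'   the log-linear initialisation; useful for probing convergence from
#'   poor starts.
#' @return Data frame per voxel: \code{t2_ms}, \code{s0},
#'   \code{residual_rms}, \code{clipped}, \code{unfittable},
#'   \code{fallback}.
#' @export
fit_nlls <- function(echo_signals, echo_times_ms,
                     config = fit_config("nlls"), init_t2_ms = NULL) {
  S <- as_signal_matrix(echo_signals)
  if (ncol(S) != length(echo_times_ms))
    stop("echo count does not match echo_times_ms")
  fe <- apply_first_echo_policy(S, echo_times_ms, config$first_echo_policy)
  Sr <- fe$signals; tes <- fe$tes
  if (ncol(Sr) < 3L) stop("need >= 3 retained echoes")

  # initial values: log-linear on positive part, else crude moment guess
  init <- fit_loglinear(echo_signals, echo_times_ms,
                        fit_config("loglinear",
                                   t2_bounds_ms = config$t2_bounds_ms,
                                   first_echo_policy = config$first_echo_policy))
  lo <- config$t2_bounds_ms[1]; hi <- config$t2_bounds_ms[2]
  n <- nrow(Sr)
  t2 <- s0 <- res <- rep(NA_real_, n)
  clipped <- fallback <- rep(FALSE, n)
  unfit <- rowSums(Sr != 0) == 0L
  for (i in seq_len(n)) {
    if (unfit[i]) next
    y <- Sr[i, ]
    start <- c(s0 = if (is.na(init$s0[i])) max(y) else init$s0[i],
               t2 = if (!is.null(init_t2_ms)) rep_len(init_t2_ms, n)[i]
                    else if (is.na(init$t2_ms[i])) mean(config$t2_bounds_ms)
                    else init$t2_ms[i])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        lower = c(0, lo), upper = c(Inf, hi),
        fn = function(p) y - p[1] * exp(-tes / p[2])),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0L, 5L)) {
      if (!is.na(init$t2_ms[i])) {
        t2[i] <- init$t2_ms[i]; s0[i] <- init$s0[i]
        res[i] <- init$residual_rms[i]; clipped[i] <- init$clipped[i]
        fallback[i] <- TRUE
      } else unfit[i] <- TRUE
      next
    }
    p <- fit$par
    t2[i] <- p[2]; s0[i] <- p[1]
    res[i] <- sqrt(mean((y - p[1] * exp(-tes / p[2]))^2))
    clipped[i] <- p[2] <= lo || p[2] >= hi
    # guarantee: never worse than the log-linear solution on the same echoes
    if (!is.na(init$residual_rms[i]) && res[i] > init$residual_rms[i] + 1e-12) {
      t2[i] <- init$t2_ms[i]; s0[i] <- init$s0[i]
      res[i] <- init$residual_rms[i]; clipped[i] <- init$clipped[i]
      fallback[i] <- TRUE
    }
  }
  data.frame(t2_ms = t2, s0 = s0, residual_rms = res, clipped = clipped,
             unfittable = unfit, fallback = fallback)
}

# dictionary cache, keyed by grids + train parameters
.dict_cache <- new.env(parent = emptyenv())

#' Build (or fetch from cache) the EPG matching dictionary
#'
#' Unit-normalised EPG echo signatures over the (T2, B1) grid of a
#' \code{\link{fit_config}}. Atoms are ordered T2-major then B1 so that
#' index ties resolve toward the smallest T2, then the smallest B1.
#'
#' @param config A \code{\link{fit_config}}.
#' @return List: \code{t2} and \code{b1} per atom, \code{atoms} (atoms x
#'   echoes, unit rows), \code{norms} (pre-normalisation row norms),
#'   \code{echo_times_ms}.
#' @export
build_epg_dictionary <- function(config = fit_config("epg_dict")) {
  key <- paste(c(config$dict_t2_grid[1], utils::tail(config$dict_t2_grid, 1),
                 length(config$dict_t2_grid),
                 config$dict_b1_grid[1], utils::tail(config$dict_b1_grid, 1),
                 length(config$dict_b1_grid), config$t1_assumed_ms,
                 config$params$n_echoes, config$params$delta_te_ms,
                 config$params$nominal_refocus_deg,
                 config$first_echo_policy),
               collapse = "|")
  if (!is.null(.dict_cache[[key]])) return(.dict_cache[[key]])
  grid <- expand.grid(b1 = config$dict_b1_grid, t2 = config$dict_t2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  # reorder T2-major for the tie-break convention
  grid <- grid[order(grid$t2, grid$b1), ]
  A <- epg_cpmg_batch(grid$t2, grid$b1, t1_ms = config$t1_assumed_ms,
                      params = config$params)
  tes <- echo_times(config$params)
  if (config$first_echo_policy == "drop") {
    A <- A[, -1L, drop = FALSE]
    tes <- tes[-1L]
  }
  norms <- sqrt(rowSums(A^2))
  dict <- list(t2 = grid$t2, b1 = grid$b1, atoms = A / norms, norms = norms,
               echo_times_ms = tes)
  .dict_cache[[key]] <- dict
  dict
}

#' B1-corrected T2 estimation by EPG dictionary matching
#'
#' Matches each voxel's echo series against unit-normalised EPG signatures
#' over a (T2, B1) grid, maximising the normalised inner product
#' (equivalently minimising the residual after optimal scaling). This is the
#' package's B1-inhomogeneity correction: the imperfect-refocusing signal
#' shape is modelled rather than treated as extra decay. Exact inner-product
#' ties resolve toward the smallest T2, then the smallest B1.
#'
#' @inheritParams fit_loglinear
#' @param b1_known Optional vector of known B1 scales (recycled over
#'   voxels); the search is then restricted to the nearest B1 grid line.
#' @return Data frame per voxel: \code{t2_ms}, \code{b1_hat}, \code{s0},
#'   \code{residual_rms}, \code{unfittable}, \code{clipped} (always FALSE:
#'   grid estimates cannot leave the grid).
#' @export
fit_epg_dictionary <- function(echo_signals, echo_times_ms,
                               config = fit_config("epg_dict"),
                               b1_known = NULL) {
  V <- as_signal_matrix(echo_signals)
  tes_full <- echo_times(config$params)
  if (ncol(V) != length(echo_times_ms) ||
      length(echo_times_ms) != length(tes_full) ||
      max(abs(echo_times_ms - tes_full)) > 1e-9)
    stop("echo times do not match the dictionary's echo train")
  dict <- build_epg_dictionary(config)
  if (config$first_echo_policy == "drop") V <- V[, -1L, drop = FALSE]

  n <- nrow(V)
  vnorm <- sqrt(rowSums(V^2))
  unfit <- vnorm == 0
  t2 <- b1h <- s0 <- res <- rep(NA_real_, n)

  col_sel <- seq_along(dict$t2)
  fit_rows <- function(rows, cols) {
    G <- V[rows, , drop = FALSE] %*% t(dict$atoms[cols, , drop = FALSE])
    # ties (including the exact alpha <-> 360 - alpha magnitude degeneracy
    # between b1 and 2 - b1 atoms) resolve to the smallest T2 then smallest
    # B1; a relative tolerance keeps the resolution stable against
    # floating-point noise
    mv <- G[cbind(seq_along(rows), max.col(G, ties.method = "first"))]
    best <- max.col(G >= mv - pmax(1e-9 * abs(mv), 1e-13),
                    ties.method = "first")
    ip <- G[cbind(seq_along(rows), best)]
    atom <- cols[best]
    t2[rows] <<- dict$t2[atom]
    b1h[rows] <<- dict$b1[atom]
    s0[rows] <<- ip / dict$norms[atom]
    res[rows] <<- sqrt(pmax(vnorm[rows]^2 - ip^2, 0) / ncol(V))
  }
  todo <- which(!unfit)
  if (is.null(b1_known)) {
    for (chunk in split(todo, ceiling(seq_along(todo) / 512)))
      fit_rows(chunk, col_sel)
  } else {
    b1_known <- rep_len(b1_known, n)
    near <- vapply(b1_known[todo],
                   function(b) config$dict_b1_grid[
                     which.min(abs(config$dict_b1_grid - b))], numeric(1))
    for (b in unique(near)) {
      rows <- todo[near == b]
      cols <- which(dict$b1 == b)
      for (chunk in split(rows, ceiling(seq_along(rows) / 512)))
        fit_rows(chunk, cols)
    }
  }
  data.frame(t2_ms = t2, b1_hat = b1h, s0 = s0, residual_rms = res,
             unfittable = unfit, clipped = FALSE)
}

#' Fit a whole multi-echo volume
#'
#' Applies the configured voxelwise estimator to every voxel whose
#' first-echo signal exceeds \code{background_threshold} times the volume's
#' first-echo maximum, and assembles T2/S0/B1/residual maps.
#'
#' @param volume 4D array (x, y, z, echo) of magnitude signals, or a
#'   \code{drg_phantom}.
#' @param config A \code{\link{fit_config}}.
#' @param echo_times_ms Echo times; taken from the phantom or config when
#'   omitted.
#' @param b1_map Optional 3D array of known B1 scales (epg_dict only).
#' @return An object of class \code{t2_map}: 3D arrays \code{t2_ms},
#'   \code{s0}, \code{b1_hat}, \code{residual_rms}, logical
#'   \code{fitted_mask} and \code{clipped}, plus \code{voxel_dims_mm},
#'   \code{method} and a \code{counts} list (fitted / clipped / unfittable /
#'   below_threshold).
#' @export
fit_volume <- function(volume, config = fit_config(), echo_times_ms = NULL,
                       b1_map = NULL) {
  voxel_dims <- config$params$voxel_dims_mm
  if (inherits(volume, "drg_phantom")) {
    if (is.null(echo_times_ms)) echo_times_ms <- volume$echo_times_ms
    voxel_dims <- volume$voxel_dims_mm
    volume <- volume$volume
  }
  if (is.null(echo_times_ms)) echo_times_ms <- echo_times(config$params)
  d <- dim(volume)
  if (length(d) != 4L) stop("volume must be a 4D array (x, y, z, echo)")
  if (d[4] != length(echo_times_ms))
    stop("echo count (", d[4], ") does not match echo_times_ms (",
         length(echo_times_ms), ")")

  nvox <- prod(d[1:3])
  S <- matrix(volume, nvox, d[4])
  thr <- config$background_threshold * max(S[, 1])
  fit_idx <- which(S[, 1] >= thr)

  mk <- function(x = NA_real_) array(x, dim = d[1:3])
  t2 <- mk(); s0 <- mk(); b1h <- mk(); res <- mk()
  fitted <- array(FALSE, dim = d[1:3])
  clipped <- array(FALSE, dim = d[1:3])
  unfittable <- 0L

  if (length(fit_idx)) {
    Sf <- S[fit_idx, , drop = FALSE]
    fr <- switch(config$method,
      loglinear = fit_loglinear(Sf, echo_times_ms, config),
      nlls = fit_nlls(Sf, echo_times_ms, config),
      epg_dict = fit_epg_dictionary(Sf, echo_times_ms, config,
        b1_known = if (!is.null(b1_map)) as.vector(b1_map)[fit_idx]))
    ok <- !fr$unfittable
    t2[fit_idx] <- fr$t2_ms
    s0[fit_idx] <- fr$s0
    if (!is.null(fr$b1_hat)) b1h[fit_idx] <- fr$b1_hat
    res[fit_idx] <- fr$residual_rms
    fitted[fit_idx] <- ok
    clipped[fit_idx] <- fr$clipped
    unfittable <- sum(!ok)
  }
  structure(list(t2_ms = t2, s0 = s0, b1_hat = b1h, residual_rms = res,
                 fitted_mask = fitted, clipped = clipped,
                 voxel_dims_mm = voxel_dims, method = config$method,
                 counts = list(fitted = sum(fitted), clipped = sum(clipped),
                               unfittable = unfittable,
                               below_threshold = nvox - length(fit_idx))),
            class = "t2_map")
}
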