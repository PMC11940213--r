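# build a minimal t2_map object around a given 3D array
fake_map <- function(t2, fitted = NULL, voxel_dims = c(1.5, 1.5, 1.8)) {
  if (is.null(fitted)) fitted <- !is.na(t2)
  structure(list(t2_ms = t2, s0 = t2 * 0 + 1, b1_hat = t2 * 0 + 1,
                 residual_rms = t2 * 0, fitted_mask = fitted,
                 clipped = array(FALSE, dim(t2)),
                 voxel_dims_mm = voxel_dims, method = "epg_dict",
                 counts = list()), class = "t2_map")
}

test_that("VOI extraction summarises fitted voxels under the label", {
  t2 <- array(100, c(4, 4, 2))
  mask <- array(0L, c(4, 4, 2)); mask[1:2, 1:2, 1] <- 1L
  m <- fake_map(t2)
  expect_equal(extract_voi(m, mask, 1, "median")$t2_ms, 100)
  expect_equal(extract_voi(m, mask, 1, "mean")$t2_ms, 100)

  t2b <- array(NA_real_, c(5, 1, 1))
  t2b[, 1, 1] <- c(80, 90, 100, 110, 200)
  maskb <- array(1L, c(5, 1, 1))
  expect_equal(extract_voi(fake_map(t2b), maskb, 1)$t2_ms, 100)

  # unfittable voxels are excluded from the summary but reported
  fitted <- array(TRUE, c(5, 1, 1)); fitted[5] <- FALSE
  v <- extract_voi(fake_map(t2b, fitted), maskb, 1)
  expect_equal(v$t2_ms, 95)
  expect_equal(v$n_excluded, 1L)
  expect_equal(v$n_voxels, 5L)
})

test_that("geometry mismatches and empty labels are rejected", {
  m <- fake_map(array(100, c(4, 4, 2)))
  expect_error(extract_voi(m, array(1L, c(4, 4, 3)), 1), "grids differ")
  mism <- array(1L, c(4, 4, 2))
  attr(mism, "voxel_dims_mm") <- c(1, 1, 1)
  expect_error(extract_voi(m, mism, 1), "voxel dimensions")
  expect_error(extract_voi(m, array(0L, c(4, 4, 2)), 1), "empty")
})

test_that("volume is voxel count times voxel volume", {
  mask <- array(0L, c(10, 10, 2)); mask[1:100] <- 1L
  expect_equal(compute_volume(mask, 1, c(1.5, 1.5, 1.8)), 405)
  mask1 <- array(0L, c(2, 2, 2)); mask1[1] <- 1L
  expect_equal(compute_volume(mask1, 1, c(1.5, 1.5, 1.8)), 4.05)
  mask10 <- array(0L, c(5, 2, 2)); mask10[1:10] <- 3L
  expect_equal(compute_volume(mask10, 3, c(1, 1, 2)), 20)
  expect_error(compute_volume(mask10, 7), "empty")

  # oracle equivalence on random masks: brute-force voxel enumeration
  set.seed(20)
  for (i in 1:5) {
    m <- array(sample(0:3, 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
    vd <- runif(3, 0.5, 3)
    lab <- sample(1:3, 1)
    if (!any(m == lab)) next
    brute <- length(which(as.vector(m) == lab)) * vd[1] * vd[2] * vd[3]
    expect_equal(compute_volume(m, lab, vd), brute)
  }
})

test_that("reader averaging is the arithmetic mean and validates readers", {
  base <- expand.grid(subject_id = "S1", visit = "baseline",
                      level = c("L5", "S1"), side = c("left", "right"),
                      stringsAsFactors = FALSE)
  s <- rbind(cbind(base, reader = "R1", t2_ms = 94, volume_mm3 = 900),
             cbind(base, reader = "R2", t2_ms = 96, volume_mm3 = 1100))
  cons <- average_readers(s)
  expect_equal(nrow(cons), 4L)
  expect_true(all(cons$t2_ms == 95))
  expect_true(all(cons$volume_mm3 == 1000))
  expect_true(all(cons$reader == "consensus"))

  s2 <- s; s2$t2_ms <- 95.6
  expect_true(all(average_readers(s2)$t2_ms == 95.6))

  expect_error(average_readers(s[-1, ]), "missing")
})

test_that("subject summaries are means of DRG samples, overall and by level", {
  s <- data.frame(level = c("L5", "L5", "S1", "S1"),
                  t2_ms = c(90, 92, 94, 96),
                  volume_mm3 = c(800, 820, 1200, 1240))
  out <- summarise_subject(s)
  expect_equal(out$drg_t2_ms, 93)
  expect_equal(out$t2_l5_ms, 91)
  expect_equal(out$t2_s1_ms, 95)
  expect_equal(out$drg_vol_mm3, 1015)
  expect_equal(summarise_subject(s[1, , drop = FALSE])$drg_t2_ms, 90)

  s2 <- data.frame(level = c("L5", "L5", "S1", "S1"),
                   t2_ms = c(90, 92, 100, 102), volume_mm3 = 1)
  out2 <- summarise_subject(s2)
  expect_equal(c(out2$drg_t2_ms, out2$t2_l5_ms, out2$t2_s1_ms),
               c(96, 91, 101))
})

test_that("reader averaging commutes with subject summaries on balanced designs", {
  set.seed(33)
  grid <- expand.grid(subject_id = "S1", visit = "baseline",
                      level = c("L5", "S1"), side = c("left", "right"),
                      reader = c("R1", "R2"), stringsAsFactors = FALSE)
  grid$t2_ms <- rnorm(nrow(grid), 95, 5)
  grid$volume_mm3 <- rnorm(nrow(grid), 1000, 100)
  a <- summarise_subject(average_readers(grid))$drg_t2_ms
  b <- mean(grid$t2_ms)          # mean of means equals the grand mean
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("noiseless phantom pipeline recovers ground truth through the VOI", {
  sp <- tiny_phantom_spec(snr = Inf)
  ph <- generate_phantom(sp)
  tmap <- fit_volume(ph, fit_config("epg_dict", params = sp$params))
  for (i in seq_len(nrow(sp$drg_defs))) {
    d <- sp$drg_defs[i, ]
    v <- extract_voi(tmap, ph$mask, d$label)
    expect_lte(abs(v$t2_ms - d$true_t2_ms), 0.1)
  }
})
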