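test_that("noiseless ideal-B1 phantom is mono-exponential in every DRG voxel", {
  sp <- tiny_phantom_spec(snr = Inf,
                          b1_field = list(kind = "uniform", value = 1),
                          drg_defs = tiny_drg_defs(100, 100))
  ph <- generate_phantom(sp)
  sel <- which(ph$mask > 0)
  S <- matrix(ph$volume, prod(dim(ph$mask)), length(ph$echo_times_ms))
  ideal <- exp(-outer(rep(1 / 100, length(sel)), ph$echo_times_ms))
  expect_lt(max(abs(S[sel, ] - ideal)), 1e-12)
})

test_that("phantoms are reproducible under a fixed seed", {
  a <- generate_phantom(tiny_phantom_spec(seed = 11))
  b <- generate_phantom(tiny_phantom_spec(seed = 11))
  expect_identical(a$volume, b$volume)
  expect_identical(a$mask, b$mask)
  c <- generate_phantom(tiny_phantom_spec(seed = 12))
  expect_false(identical(a$volume, c$volume))
})

test_that("lower SNR yields larger first-echo error", {
  sp50 <- tiny_phantom_spec(snr = 50, seed = 5)
  sp10 <- tiny_phantom_spec(snr = 10, seed = 5)
  noiseless <- generate_phantom(tiny_phantom_spec(snr = Inf))$volume[, , , 1]
  e50 <- generate_phantom(sp50)$volume[, , , 1]
  e10 <- generate_phantom(sp10)$volume[, , , 1]
  vox <- which(noiseless > 0)[1:100]
  rmse <- function(x) sqrt(mean((x[vox] - noiseless[vox])^2))
  expect_gt(rmse(e10), rmse(e50))
})

test_that("Rician noise floor in zero-PD voxels matches sigma * sqrt(pi/2)", {
  sp <- phantom_spec(grid_shape = c(32L, 32L, 12L), background_pd = 0,
                     snr = 5, seed = 9)
  ph <- generate_phantom(sp)
  bg <- which(ph$mask == 0)
  expect_gt(length(bg), 1e4)
  sigma <- 1 / sp$snr     # max PD is the DRG PD of 1
  m <- mean(ph$volume[, , , 1][bg])
  expect_lt(abs(m - sigma * sqrt(pi / 2)) / (sigma * sqrt(pi / 2)), 0.05)
})

test_that("invalid phantom specifications are rejected", {
  d <- tiny_drg_defs()
  d$cx_mm <- c(6, 7, 6, 18)      # first two ellipsoids collide
  expect_error(generate_phantom(
    phantom_spec(grid_shape = c(16L, 16L, 8L), drg_defs = d)), "overlap")
  expect_error(phantom_spec(snr = 0), "snr")
  expect_error(phantom_spec(snr = -3), "snr")
  d2 <- tiny_drg_defs(); d2$true_t2_ms[1] <- 5
  expect_error(phantom_spec(drg_defs = d2), "true_t2_ms")
})

test_that("b1 field stays in its documented range", {
  for (seed in 1:3) {
    sp <- tiny_phantom_spec(b1_field = list(kind = "random"), seed = seed)
    ph <- generate_phantom(sp)
    expect_true(all(ph$truth$b1 >= 0.6 & ph$truth$b1 <= 1.1))
  }
})

test_that("reader perturbation preserves size within the binomial bound", {
  # a single ~1000-voxel ellipsoid label
  d <- tiny_drg_defs()[1, ]
  d$cx_mm <- 15; d$cy_mm <- 15; d$cz_mm <- 9
  d[, c("ax_mm", "ay_mm")] <- 11; d$az_mm <- 8
  sp <- phantom_spec(grid_shape = c(20L, 20L, 10L), drg_defs = d)
  mask <- generate_phantom(sp)$mask
  n0 <- sum(mask == 1)
  expect_gt(n0, 900)
  sizes <- vapply(1:100, function(s)
    sum(perturb_mask_as_reader(mask, 1, seed = s, rate = 0.05) == 1L),
    numeric(1))
  expect_true(all(sizes >= 0.9 * n0 & sizes <= 1.1 * n0))
})

test_that("reader perturbation edge cases behave", {
  mask <- generate_phantom(tiny_phantom_spec())$mask
  expect_identical(perturb_mask_as_reader(mask, 1, 1, rate = 0), mask)
  expect_error(perturb_mask_as_reader(mask, 1, 1, labels = 9L), "absent")
  p1 <- perturb_mask_as_reader(mask, 1, seed = 3, rate = 0.05)
  p2 <- perturb_mask_as_reader(mask, 2, seed = 3, rate = 0.05)
  expect_false(identical(p1, p2))    # readers differ under the same seed
  expect_identical(p1, perturb_mask_as_reader(mask, 1, seed = 3, rate = 0.05))
})
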