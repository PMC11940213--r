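tes10 <- echo_times(echo_train_params())

test_that("log-linear fit recovers noiseless exponentials exactly", {
  s <- 1000 * exp(-tes10 / 93.6)
  f <- fit_loglinear(s, tes10)
  expect_equal(f$t2_ms, 93.6, tolerance = 1e-9)
  expect_equal(f$s0, 1000, tolerance = 1e-6)
  expect_false(f$unfittable)
})

test_that("non-positive retained signals mark a voxel unfittable", {
  s <- 1000 * exp(-tes10 / 90)
  s[5] <- 0
  f <- fit_loglinear(s, tes10)
  expect_true(f$unfittable)
  expect_true(is.na(f$t2_ms))
})

test_that("NLLS recovers noiseless decay and is robust to bound starts", {
  s <- 500 * exp(-tes10 / 100)
  f <- fit_nlls(s, tes10)
  expect_equal(f$t2_ms, 100, tolerance = 1e-6)
  for (init in c(10, 500)) {
    fb <- fit_nlls(s, tes10, init_t2_ms = init)
    expect_equal(fb$t2_ms, 100, tolerance = 1e-4)
  }
})

test_that("NLLS is approximately unbiased on Rician data at SNR 50", {
  set.seed(101)
  n <- 1000
  s <- exp(-tes10 / 100)
  S <- matrix(rep(s, each = n), n, 10)
  S <- sqrt((S + matrix(rnorm(n * 10, sd = 1 / 50), n, 10))^2 +
              matrix(rnorm(n * 10, sd = 1 / 50), n, 10)^2)
  f <- fit_nlls(S, tes10)
  expect_gt(mean(f$t2_ms), 95)
  expect_lt(mean(f$t2_ms), 105)
  # and never beats its own residual guarantee vs the log-linear start
  fl <- fit_loglinear(S, tes10)
  ok <- !f$unfittable & !fl$unfittable
  expect_true(all(f$residual_rms[ok] <= fl$residual_rms[ok] + 1e-9))
})

test_that("dictionary matching is self-consistent at grid points", {
  p <- echo_train_params()
  f <- fit_epg_dictionary(epg_cpmg(94, 1000, 0.90, p), tes10)
  expect_identical(f$t2_ms, 94)
  expect_identical(f$b1_hat, 0.90)
  # global-minimum check over a sub-grid of generating points (b1 <= 1:
  # refocusing angles alpha and 360 - alpha give identical magnitudes, so
  # b1 > 1 atoms coincide with their 2 - b1 mirror)
  sub <- expand.grid(t2 = seq(40, 220, by = 20), b1 = seq(0.6, 1.0, by = 0.1))
  sig <- epg_cpmg_batch(sub$t2, sub$b1, params = p)
  fg <- fit_epg_dictionary(sig, tes10)
  expect_equal(fg$t2_ms, sub$t2)
  expect_equal(fg$b1_hat, sub$b1)
})

test_that("b1 and 2 - b1 dictionary atoms are magnitude-degenerate", {
  p <- echo_train_params()
  expect_equal(epg_cpmg(94, 1000, 1.1, p), epg_cpmg(94, 1000, 0.9, p),
               tolerance = 1e-12)
  f <- fit_epg_dictionary(epg_cpmg(94, 1000, 1.1, p), tes10)
  expect_identical(f$t2_ms, 94)
  expect_identical(f$b1_hat, 0.90)   # tie resolves to the sub-unity mirror
})

test_that("dictionary matching handles off-grid and degenerate input", {
  f <- fit_epg_dictionary(exp(-tes10 / 100), tes10)
  expect_lte(abs(f$t2_ms - 100), 1)
  expect_lte(abs(f$b1_hat - 1), 0.01)
  f0 <- fit_epg_dictionary(rbind(exp(-tes10 / 80), rep(0, 10)), tes10)
  expect_false(f0$unfittable[1])
  expect_true(f0$unfittable[2])
  expect_error(fit_epg_dictionary(exp(-tes10 / 100), tes10 + 1), "echo times")
})

test_that("dictionary matching agrees with NLLS on noiseless exponentials", {
  for (t2 in c(40, 94, 150)) {
    s <- exp(-tes10 / t2)
    fd <- fit_epg_dictionary(s, tes10)
    fn <- fit_nlls(s, tes10)
    expect_lte(abs(fd$t2_ms - fn$t2_ms), 1)
    expect_lte(abs(fd$b1_hat - 1), 0.01)
  }
})

test_that("B1-corrected matching beats the log-linear fit under B1 error", {
  p <- echo_train_params()
  for (b1 in c(0.75, 0.85)) {
    sig <- epg_cpmg(100, 1000, b1, p)
    set.seed(7 + round(100 * b1))
    n <- 500
    S <- matrix(rep(sig, each = n), n, 10)
    S <- sqrt((S + matrix(rnorm(n * 10, sd = 1 / 50), n, 10))^2 +
                matrix(rnorm(n * 10, sd = 1 / 50), n, 10)^2)
    bias_dict <- abs(mean(fit_epg_dictionary(S, tes10)$t2_ms) - 100)
    bias_ll <- abs(mean(fit_loglinear(S, tes10)$t2_ms) - 100)
    expect_lt(bias_dict, 3)
    expect_lt(bias_dict, bias_ll)
  }
})

test_that("known-B1 matching restricts the search to one grid line", {
  p <- echo_train_params()
  sig <- epg_cpmg_batch(c(85, 120), c(0.8, 0.8), params = p)
  f <- fit_epg_dictionary(sig, tes10, b1_known = 0.802)
  expect_equal(f$b1_hat, c(0.8, 0.8))
  expect_equal(f$t2_ms, c(85, 120))
})

test_that("volume fitting composes, thresholds background and is deterministic", {
  sp <- tiny_phantom_spec(snr = Inf)
  ph <- generate_phantom(sp)
  cfg <- fit_config("epg_dict", params = sp$params)
  m1 <- fit_volume(ph, cfg)
  for (i in seq_len(nrow(sp$drg_defs))) {
    d <- sp$drg_defs[i, ]
    expect_lte(max(abs(m1$t2_ms[ph$mask == d$label] - d$true_t2_ms)), 1)
  }
  m2 <- fit_volume(ph, cfg)
  expect_identical(m1$t2_ms, m2$t2_ms)

  # pure-noise background voxels are excluded by the signal threshold
  spn <- tiny_phantom_spec(background_pd = 0, snr = 100, seed = 4)
  phn <- generate_phantom(spn)
  mn <- fit_volume(phn, cfg)
  bg <- phn$mask == 0
  expect_lt(mean(mn$fitted_mask[bg]), 0.01)

  expect_error(fit_volume(ph$volume, cfg, echo_times_ms = tes10[1:9]),
               "echo count")
})
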