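test_that("LED alignment check reports per-half deviations and flags misalignment", {
  u <- matrix(1, 16, 16)
  fr <- dpc_frameset(u, u, u, u)
  rep0 <- check_led_alignment(fr)
  expect_equal(unname(rep0$relative_deviation), rep(0, 4))
  expect_true(rep0$aligned)

  # top scaled x1.2: deviation (1.2 - 1.05) / 1.05
  fr2 <- dpc_frameset(1.2 * u, u, u, u)
  rep2 <- check_led_alignment(fr2)
  expect_equal(rep2$relative_deviation[["top"]], (1.2 - 1.05) / 1.05,
               tolerance = 1e-12)
  expect_false(rep2$aligned)

  # all within the 5% instrument tolerance
  fr3 <- dpc_frameset(1.04 * u, u, 0.97 * u, 1.01 * u)
  expect_true(check_led_alignment(fr3, tolerance = 0.05)$aligned)

  expect_error(check_led_alignment(dpc_frameset(0 * u, u, u, u)),
               "zero-intensity")
})

test_that("phase gradient is the bounded normalized difference", {
  a <- matrix(3, 8, 8); b <- matrix(1, 8, 8)
  expect_equal(compute_phase_gradient(a, a), matrix(0, 8, 8))
  expect_equal(compute_phase_gradient(a, b), matrix(0.5, 8, 8))
  expect_error(compute_phase_gradient(a, matrix(1, 4, 4)), "shape")
  expect_warning(g0 <- compute_phase_gradient(matrix(0, 4, 4),
                                              matrix(0, 4, 4)),
                 "zero-sum")
  expect_true(all(is.finite(g0)))

  # forward model of a linear phase ramp: vertical-axis gradient image is
  # antisymmetric about the ramp centre (up to FFT wrap effects at edges)
  cfg <- test_config()
  n <- 64
  ramp <- matrix(rep(seq(-0.2, 0.2, length.out = n), each = n), n, n)
  ramp <- bandlimit_phantom(phase_image(t(ramp), cfg$pixel_size_um), cfg)
  fr <- simulate_dpc_frames(ramp, cfg)
  gv <- compute_phase_gradient(fr$top, fr$bottom)
  expect_gt(stats::sd(gv), 0)
})

test_that("phase transfer function has DC zero, antisymmetry, and cutoff", {
  cfg <- test_config()
  d <- c(96L, 96L)
  for (axis in c(90, 180)) {
    H <- build_phase_transfer_function(cfg, axis, d)
    expect_equal(max(abs(Re(H))), 0)          # purely imaginary
    expect_equal(H[1, 1], 0 + 0i)             # zero at DC
    # H(-u) = -H(u) on the FFT grid
    mir <- H[c(1, d[1]:2), c(1, d[2]:2)]
    expect_lt(max(abs(H + mir)), 1e-14)
    # zero beyond the partially coherent cutoff (NA_obj + NA_ill) / lambda
    fy <- qpiscreen:::fft_freq(d[1], cfg$pixel_size_um)
    fx <- qpiscreen:::fft_freq(d[2], cfg$pixel_size_um)
    R <- sqrt(outer(fy^2, fx^2, "+"))
    cutoff <- (cfg$na_objective + cfg$na_illumination) / cfg$wavelength_um
    expect_equal(max(Mod(H)[R > cutoff]), 0)
    expect_equal(max(Mod(H)), 1)              # unit-max normalization
  }
  expect_error(build_phase_transfer_function(cfg, 45, d), "axis")
})

test_that("Tikhonov reconstruction round-trips band-limited phantoms", {
  cfg <- test_config()
  set.seed(42)
  blob <- gauss_blob(128, cx = 70, cy = 60, peak = 0.5, sigma = 8) +
    gauss_blob(128, cx = 40, cy = 90, peak = 0.3, sigma = 6)
  ph <- bandlimit_phantom(phase_image(blob, cfg$pixel_size_um), cfg)
  expect_lt(max(abs(ph$phase)), 0.5)
  fr <- simulate_dpc_frames(ph, cfg)
  rec <- reconstruct_phase(fr, cfg)
  rel <- sqrt(sum((rec$phase - ph$phase)^2) / sum(ph$phase^2))
  expect_lt(rel, 0.05)
  expect_gt(stats::cor(c(rec$phase), c(ph$phase)), 0.99)

  # zero gradients give a zero phase image
  Hv <- build_phase_transfer_function(cfg, 90, c(32L, 32L))
  z <- tikhonov_reconstruct(list(matrix(0, 32, 32)), list(Hv))
  expect_equal(z$phase, matrix(0, 32, 32))
  expect_error(tikhonov_reconstruct(list(matrix(0, 32, 32)), list(Hv),
                                    beta = 0), "beta")
})

test_that("reconstruction is linear and damped monotonically in beta", {
  cfg <- test_config()
  ph <- bandlimit_phantom(
    phase_image(gauss_blob(96, sigma = 7), cfg$pixel_size_um), cfg)
  fr1 <- simulate_dpc_frames(ph, cfg)
  fr2 <- simulate_dpc_frames(phase_image(0.5 * ph$phase, cfg$pixel_size_um),
                             cfg)
  r1 <- reconstruct_phase(fr1, cfg)
  r2 <- reconstruct_phase(fr2, cfg)
  expect_equal(r2$phase, 0.5 * r1$phase, tolerance = 1e-10)

  # per-frequency amplitude is non-increasing when beta doubles
  gv <- compute_phase_gradient(fr1$top, fr1$bottom)
  gh <- compute_phase_gradient(fr1$left, fr1$right)
  Hv <- build_phase_transfer_function(cfg, 90, dim(gv))
  Hh <- build_phase_transfer_function(cfg, 180, dim(gv))
  amp <- function(beta) {
    den <- Mod(Hv)^2 + Mod(Hh)^2 + beta
    Mod((Conj(Hv) * stats::fft(gv) + Conj(Hh) * stats::fft(gh)) / den)
  }
  a1 <- amp(1e-3); a2 <- amp(2e-3)
  expect_true(all(a2 <= a1 + 1e-12 * max(a1)))
})

test_that("forward simulator is deterministic and encodes phase gradients", {
  cfg <- test_config()
  z <- phase_image(matrix(0, 48, 48), cfg$pixel_size_um)
  fr <- simulate_dpc_frames(z, cfg)
  expect_equal(fr$top, fr$bottom)
  expect_equal(fr$left, fr$right)
  expect_equal(fr$top, matrix(1, 48, 48))

  ph <- bandlimit_phantom(
    phase_image(gauss_blob(48, sigma = 5, peak = 0.4), cfg$pixel_size_um),
    cfg)
  fa <- simulate_dpc_frames(ph, cfg, noise_level = 0.01, seed = 7)
  fb <- simulate_dpc_frames(ph, cfg, noise_level = 0.01, seed = 7)
  expect_identical(fa$top, fb$top)
  expect_identical(fa$right, fb$right)
  fc <- simulate_dpc_frames(ph, cfg)
  expect_gt(max(abs(fc$top - fc$bottom)), 0)
})

test_that("bead calibration recovers the polystyrene refractive index", {
  cfg <- test_config()
  bf <- bead_field()
  # zero phase over the bead recovers the medium index
  z <- phase_image(matrix(0, 64, 64), cfg$pixel_size_um)
  cal0 <- calibrate_with_beads(z, data.frame(x = 32, y = 32), 2,
                               medium_index = 1.56, config = cfg)
  expect_equal(cal0$mean_refractive_index, 1.56)

  ph <- bead_phantom(bf$shape, bf$centers, bf$radius_um, n_bead = 1.583,
                     n_medium = 1.56, config = cfg)
  fr <- simulate_dpc_frames(ph, cfg)
  rec <- reconstruct_phase(fr, cfg)
  cal <- calibrate_with_beads(rec, bf$centers, bf$radius_um,
                              medium_index = 1.56, config = cfg)
  expect_lt(abs(cal$mean_refractive_index - 1.583) / 1.583, 0.001)

  # border bead excluded with warning
  ctr2 <- rbind(bf$centers, data.frame(x = 2, y = 2))
  expect_warning(calibrate_with_beads(rec, ctr2, bf$radius_um, 1.56, cfg),
                 "border")
})

test_that("temporal CV over repeated noisy frames equals the sample CV", {
  cfg <- test_config()
  ctr <- data.frame(x = c(40, 90), y = c(40, 90))
  ph <- bead_phantom(c(128, 128), ctr, 2, config = cfg)
  recs <- lapply(1:8, function(s) {
    reconstruct_phase(simulate_dpc_frames(ph, cfg, noise_level = 0.02,
                                          seed = s), cfg)
  })
  cal <- calibrate_with_beads(recs, ctr, 2, config = cfg)
  means <- vapply(recs, function(r)
    mean(calibrate_with_beads(r, ctr, 2, config = cfg)$per_bead_indices),
    numeric(1))
  expect_equal(cal$temporal_cv, stats::sd(means) / mean(means),
               tolerance = 1e-12)
})

test_that("phase images and DPC frames round-trip through TIFF", {
  dir <- withr::local_tempdir()
  cfg <- test_config()
  m <- matrix(stats::rnorm(256, sd = 0.3), 16, 16)
  p <- file.path(dir, "phase.tif")
  write_phase_tiff(phase_image(m, 0.54, timestamp = 1.5), p)
  r <- read_phase_tiff(p)
  expect_equal(r$phase, m, tolerance = 1e-6)
  expect_equal(r$pixel_size_um, 0.54)

  for (h in c("top", "bottom", "left", "right")) {
    tiff::writeTIFF(matrix(stats::runif(64), 8, 8),
                    file.path(dir, sprintf("A01x_3_%s.tif", h)))
  }
  fs <- read_dpc_frames(dir, "A01x", 3)
  expect_s3_class(fs, "dpc_frameset")
  expect_equal(dim(fs$top), c(8L, 8L))
})
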