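test_that("segmentation finds blobs with area near the half-maximum support", {
  cfg <- test_config()
  lab0 <- segment_cells(phase_image(matrix(0, 64, 64), 0.54))
  expect_equal(max(lab0), 0)

  blob <- gauss_blob(128, peak = 0.5, sigma = 10)
  lab <- segment_cells(phase_image(blob, 0.54))
  expect_equal(max(lab), 1)
  target <- sum(blob > 0.25)     # area above half maximum
  expect_lt(abs(sum(lab > 0) - target) / target, 0.2)
})

test_that("watershed splits touching blobs with distinct peaks", {
  b2 <- gauss_blob(128, cx = 55, cy = 64, sigma = 8) +
    gauss_blob(128, cx = 80, cy = 64, sigma = 8)
  ph <- phase_image(b2, 0.54)
  expect_equal(max(segment_cells(ph, segmentation_params())), 1)
  expect_equal(max(segment_cells(ph,
                                 segmentation_params(use_watershed = TRUE))),
               2)
})

test_that("background correction removes its own polynomial model class", {
  n <- 96
  xs <- matrix(seq(-1, 1, length.out = n), n, n, byrow = TRUE)
  ys <- t(xs)
  surf <- 0.3 * xs^8 + 0.2 * ys^5 * xs^2 - 0.1 * ys + 0.05
  out <- correct_background(phase_image(surf, 0.54), NULL,
                            rolling_ball = FALSE)
  expect_lt(max(abs(out$phase)) / diff(range(surf)), 1e-6)
})

test_that("background correction preserves blob mass under a tilted plane", {
  n <- 128
  xs <- matrix(seq(-1, 1, length.out = n), n, n, byrow = TRUE)
  blob <- gauss_blob(n, sigma = 8)
  plane <- 0.1 * xs + 0.15 * t(xs)
  mask <- matrix(0L, n, n); mask[blob > 0.05] <- 1L
  c1 <- correct_background(phase_image(blob, 0.54), mask)
  c2 <- correct_background(phase_image(blob + plane, 0.54), mask)
  i1 <- sum(c1$phase[mask == 1]); i2 <- sum(c2$phase[mask == 1])
  expect_lt(abs(i2 - i1) / abs(i1), 0.05)
})

test_that("degenerate all-cell mask falls back to a lower polynomial order", {
  m <- matrix(stats::rnorm(64), 8, 8)
  mask <- matrix(1L, 8, 8)  # 0 background pixels
  expect_warning(correct_background(phase_image(m, 0.54), mask,
                                    rolling_ball = FALSE),
                 "order reduced")
})

test_that("background correction is nearly idempotent", {
  set.seed(9)
  n <- 96
  img <- gauss_blob(n, sigma = 8) + 0.02 * matrix(stats::rnorm(n^2), n, n)
  mask <- matrix(0L, n, n); mask[gauss_blob(n, sigma = 8) > 0.05] <- 1L
  p <- segmentation_params(rolling_ball_radius = 30)
  c1 <- correct_background(phase_image(img, 0.54), mask, p)
  c2 <- correct_background(c1, mask, p)
  # RMS change under a second application, relative to the dynamic range
  expect_lt(sqrt(mean((c2$phase - c1$phase)^2)) / diff(range(c1$phase)),
            0.01)
})

test_that("mass follows the specific refractive increment conversion", {
  cfg <- test_config()
  z <- phase_image(matrix(0, 32, 32), 0.54)
  expect_equal(compute_mass(z, NULL, cfg), 0)

  # uniform phi = pi over 100 um^2 at lambda 0.624 um: 173.3 pg
  npx <- round(100 / 0.54^2)
  m <- matrix(0, 64, 64); sel <- matrix(FALSE, 64, 64)
  sel[seq_len(npx)] <- TRUE; m[sel] <- pi
  got <- compute_mass(phase_image(m, 0.54), sel, cfg)
  oracle <- (0.624 / (2 * pi)) * pi * npx * 0.54^2 / 0.18
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(oracle, 173.3, tolerance = 1e-3)

  # additive over disjoint regions
  s1 <- sel; s1[, 33:64] <- FALSE
  s2 <- sel & !s1
  expect_equal(compute_mass(phase_image(m, 0.54), s1, cfg) +
                 compute_mass(phase_image(m, 0.54), s2, cfg), got)

  expect_warning(compute_mass(phase_image(-m, 0.54), sel, cfg), "negative")
})

test_that("total mass is invariant to how labels partition the image", {
  set.seed(3)
  cfg <- test_config()
  m <- matrix(abs(stats::rnorm(32^2, 0.1, 0.05)), 32, 32)
  ph <- phase_image(m, 0.54)
  whole <- compute_mass(ph, NULL, cfg)
  lab <- matrix(sample(1:4, 32^2, TRUE), 32, 32)
  parts <- vapply(1:4, function(k) compute_mass(ph, lab == k, cfg),
                  numeric(1))
  expect_equal(sum(parts), whole, tolerance = 1e-10)
})

test_that("tracking links stationary objects and respects mass continuity", {
  ob <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame_index = f, time_h = f / 3, label = 1:2,
               x = c(10, 100), y = c(10, 100), mass_pg = c(200, 400))))
  tr <- link_tracks(ob)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_true(all(table(tr$track_id) == 5))
  expect_true(all(vapply(split(tr$mass_pg, tr$track_id),
                         function(v) length(unique(v)) == 1, logical(1))))

  # mass term resolves an ambiguity pure position linking would swap:
  # the light and heavy object exchange positions between frames
  f1 <- data.frame(frame_index = 1, time_h = 0, label = 1:2,
                   x = c(50, 56), y = c(50, 50), mass_pg = c(100, 1000))
  f2 <- data.frame(frame_index = 2, time_h = 1 / 3, label = 1:2,
                   x = c(56, 50), y = c(50, 50), mass_pg = c(100, 1000))
  # enumerate both assignments: mass-continuity pairing costs
  # 2*(6/10)^2 = 0.72; position pairing costs 2*(900/500)^2 = 6.48
  tr2 <- link_tracks(rbind(f1, f2), position_scale = 10, mass_scale = 500)
  expect_true(all(vapply(split(tr2$mass_pg, tr2$track_id),
                         function(v) length(unique(v)) == 1, logical(1))))
})

test_that("tracking is deterministic and starts/ends tracks on mismatch", {
  set.seed(11)
  obs <- do.call(rbind, lapply(1:4, function(f) {
    k <- c(3, 3, 4, 2)[f]  # appearing and disappearing objects
    data.frame(frame_index = f, time_h = f / 3, label = seq_len(k),
               x = stats::runif(k, 0, 100), y = stats::runif(k, 0, 100),
               mass_pg = stats::runif(k, 100, 500))
  }))
  t1 <- link_tracks(obs)
  t2 <- link_tracks(obs)
  expect_identical(t1, t2)
  expect_true(length(unique(t1$track_id)) >= 4)
})

test_that("measure_cells reports centroid, area, and mass per object", {
  cfg <- test_config()
  m <- matrix(0, 64, 64)
  m[20:29, 20:29] <- 0.4   # 100 px square
  lab <- matrix(0L, 64, 64); lab[m > 0] <- 1L
  ob <- measure_cells(phase_image(m, 0.54), lab, frame_index = 3,
                      time_h = 1, config = cfg)
  expect_equal(nrow(ob), 1)
  expect_equal(ob$area_um2, 100 * 0.54^2)
  expect_equal(ob$mean_phase, 0.4)
  expect_equal(ob$mass_pg,
               (0.624 / (2 * pi)) * 0.4 * 100 * 0.54^2 / 0.18,
               tolerance = 1e-12)
})
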