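test_that("SGR histograms are normalized and placed correctly", {
  s1 <- discretize_sgr_distribution(0.0213)
  expect_equal(sum(s1$p), 1)
  expect_equal(sum(s1$p > 0), 1)
  expect_lt(abs(s1$mids[which(s1$p > 0)] - 0.0213), 1e-4)

  # uniform over k bins
  k <- 10
  vals <- -0.3 + 1e-4 * (seq_len(k) - 0.5)
  su <- discretize_sgr_distribution(vals)
  expect_equal(unname(su$p[1:k]), rep(1 / k, k))

  set.seed(4)
  x <- stats::rnorm(1e4, 0.02, 0.01)
  sn <- discretize_sgr_distribution(x)
  m <- sum(sn$mids * sn$p)
  expect_lt(abs(m - 0.02), 3 * 0.01 / sqrt(1e4))

  expect_warning(discretize_sgr_distribution(c(0.02, 0.9)), "clipped")
  expect_error(discretize_sgr_distribution(numeric(0)), "empty")
})

test_that("Hellinger distance identities and Gaussian closed form hold", {
  S <- normal_sgr_distribution(0.02, 0.008)
  expect_equal(hellinger_distance(S, S), 0)

  a <- discretize_sgr_distribution(rep(-0.1, 5))
  b <- discretize_sgr_distribution(rep(0.1, 5))
  expect_equal(hellinger_distance(a, b), 1)

  # closed form for two normals, discretized at bin 1e-4
  cases <- list(c(0.02, 0.008, 0.005, 0.01), c(0, 0.01, 0, 0.02),
                c(-0.05, 0.015, 0.06, 0.004))
  for (cs in cases) {
    S1 <- normal_sgr_distribution(cs[1], cs[2])
    S2 <- normal_sgr_distribution(cs[3], cs[4])
    expect_equal(hellinger_distance(S1, S2),
                 gaussian_hellinger(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-3)
  }
})

test_that("Hellinger distance is symmetric, triangular, and mean-monotone", {
  set.seed(6)
  for (i in 1:5) {
    A <- normal_sgr_distribution(stats::runif(1, -0.05, 0.05),
                                 stats::runif(1, 0.004, 0.02))
    B <- normal_sgr_distribution(stats::runif(1, -0.05, 0.05),
                                 stats::runif(1, 0.004, 0.02))
    C <- normal_sgr_distribution(stats::runif(1, -0.05, 0.05),
                                 stats::runif(1, 0.004, 0.02))
    expect_equal(hellinger_distance(A, B), hellinger_distance(B, A))
    expect_lte(hellinger_distance(A, C),
               hellinger_distance(A, B) + hellinger_distance(B, C) + 1e-12)
  }
  shifts <- c(0, 0.002, 0.005, 0.01, 0.03)
  base <- normal_sgr_distribution(0, 0.008)
  hs <- vapply(shifts, function(d)
    hellinger_distance(base, normal_sgr_distribution(d, 0.008)), numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("control-derived threshold is the maximum control distance", {
  set.seed(12)
  times <- seq(14, 58, by = 4)
  same <- lapply(times, function(t) stats::rnorm(500, 0.02, 0.008))
  hs0 <- hellinger_series(same, same, times)
  expect_equal(hellinger_threshold(hs0), 0)

  other <- lapply(times, function(t) stats::rnorm(500, 0.02, 0.008))
  hs1 <- hellinger_series(same, other, times)
  thr <- hellinger_threshold(hs1)
  expect_gt(thr, 0)

  # a mean shift at one time point puts the maximum there
  shifted <- other
  shifted[[5]] <- shifted[[5]] + 0.01
  hs2 <- hellinger_series(same, shifted, times)
  expect_equal(which.max(hs2$distance), 5)

  # sampling noise decreases with n (distribution-level limit is 0)
  small <- hellinger_series(
    lapply(times, function(t) stats::rnorm(60, 0.02, 0.008)),
    lapply(times, function(t) stats::rnorm(60, 0.02, 0.008)), times)
  expect_gt(hellinger_threshold(small), thr)
})

test_that("ToR model fit recovers exact parameters and degenerates safely", {
  t <- seq(2, 70, by = 4)
  H <- 0.6 - 0.55 * exp(-0.1 * t)
  fit <- fit_tor_model(data.frame(time_h = t, distance = H))
  expect_equal(fit$a, 0.6, tolerance = 1e-4)
  expect_equal(fit$b, 0.55, tolerance = 1e-4)
  expect_equal(fit$c, -0.1, tolerance = 1e-4)

  const <- fit_tor_model(data.frame(time_h = t, distance = rep(0.3, 18)))
  expect_true(const$degenerate)
  expect_equal(const$a, 0.3)
  expect_equal(compute_tor(const, 0.2)$status, "no_response")

  # optimality: fitted rss no worse than hand-tried parameter triples
  set.seed(3)
  Hn <- H + stats::rnorm(length(t), 0, 0.01)
  fn <- fit_tor_model(data.frame(time_h = t, distance = Hn))
  for (p in list(c(0.6, 0.55, -0.1), c(0.7, 0.6, -0.08),
                 c(0.55, 0.5, -0.12))) {
    rss_try <- sum((Hn - (p[1] - p[2] * exp(p[3] * t)))^2)
    expect_lte(fn$rss, rss_try + 1e-12)
  }
  expect_error(fit_tor_model(data.frame(time_h = 1:3, distance = 1:3 / 10)),
               "4 time points")
})

test_that("ToR inversion matches forward evaluation and boundary cases", {
  fit <- structure(list(a = 0.6, b = 0.55, c = -0.1, degenerate = FALSE,
                        converged = TRUE), class = "tor_fit")
  tor <- compute_tor(fit, 0.3)
  expect_equal(tor$status, "response")
  expect_equal(tor$tor_h, 6.06, tolerance = 1e-3)
  # forward model at the computed time reproduces the threshold
  expect_equal(0.6 - 0.55 * exp(-0.1 * tor$tor_h), 0.3, tolerance = 1e-6)

  # boundary: threshold at H(0) = a - b gives t = 0 -> still a response
  expect_equal(compute_tor(fit, 0.6 - 0.55)$tor_h, 0, tolerance = 1e-12)

  # plateau below threshold
  low <- structure(list(a = 0.2, b = 0.15, c = -0.1, degenerate = FALSE,
                        converged = TRUE), class = "tor_fit")
  expect_equal(compute_tor(low, 0.3)$status, "no_response")
  neg <- structure(list(a = 0.6, b = -0.1, c = -0.1, degenerate = FALSE,
                        converged = TRUE), class = "tor_fit")
  expect_equal(compute_tor(neg, 0.3)$status, "no_response")
})

test_that("end-to-end ToR lands near the generating crossing time", {
  # treated population mean decays toward a lower plateau from t0 = 18 h;
  # the generating model's own crossing of the fitted threshold is the
  # oracle, and the pipeline estimate must land within 2 time bins
  set.seed(19)
  times <- seq(14, 58, by = 4)
  ctrl <- lapply(times, function(t) stats::rnorm(3000, 0.022, 0.008))
  mean_t <- function(t) 0.022 - 0.028 * (1 - exp(-pmax(t - 18, 0) / 12))
  trt <- lapply(times, function(t) stats::rnorm(3000, mean_t(t), 0.008))
  ctrl2 <- lapply(times, function(t) stats::rnorm(3000, 0.022, 0.008))

  thr <- hellinger_threshold(hellinger_series(ctrl, ctrl2, times))
  hs <- hellinger_series(trt, ctrl, times)
  tor <- compute_tor(fit_tor_model(hs), thr)
  expect_equal(tor$status, "response")
  first_cross <- times[which(hs$distance > thr)[1]]
  expect_lt(abs(tor$tor_h - first_cross), 2 * 4)
})

test_that("ToR at EC50 selects the tested concentration just above", {
  tab <- data.frame(concentration_uM = c(0.8, 4, 20),
                    tor_h = c(40, 12, 6))
  expect_equal(tor_at_ec50(tab, 1.5)$concentration_uM, 4)
  expect_equal(tor_at_ec50(tab, 1.5)$tor_h, 12)
  # exact tie goes to the next concentration above
  expect_equal(tor_at_ec50(tab, 4)$concentration_uM, 20)
  expect_warning(out <- tor_at_ec50(tab, 30), "undefined")
  expect_true(is.na(out$tor_h))
})
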