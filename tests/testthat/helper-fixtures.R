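# Shared fixtures: all synthetic, built in code at test time.

# Gaussian blob phase phantom
gauss_blob <- function(n = 128, cx = n / 2, cy = n / 2, peak = 0.5,
                       sigma = 10) {
  x <- seq_len(n)
  peak * exp(-(outer((x - cy)^2, (x - cx)^2, "+")) / (2 * sigma^2))
}

# Closed-form Hellinger distance between two normals
gaussian_hellinger <- function(m1, s1, m2, s2) {
  sqrt(1 - sqrt(2 * s1 * s2 / (s1^2 + s2^2)) *
         exp(-(m1 - m2)^2 / (4 * (s1^2 + s2^2))))
}

# Exact normal bin masses on the standard SGR grid
normal_sgr_distribution <- function(mean, sd, bin_width = 1e-4,
                                    range = c(-0.3, 0.3)) {
  br <- seq(range[1], range[2], by = bin_width)
  p <- diff(stats::pnorm(br, mean, sd))
  sgr_distribution(p / sum(p), br)
}

# Default optics used across tests
test_config <- function() optical_config()

# Well-separated bead field on a 256x256 image
bead_field <- function() {
  list(centers = data.frame(x = c(64, 128, 192, 96, 176, 220, 40, 150),
                            y = c(64, 96, 160, 200, 60, 220, 150, 230)),
       radius_um = 2.0, shape = c(256L, 256L))
}
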