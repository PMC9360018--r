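#' Optical configuration for the DPC microscope
#'
#' Bundles the physical parameters of the differential phase contrast (DPC)
#' system: illumination wavelength, objective and illumination numerical
#' apertures, sample-plane pixel size, and the Tikhonov regularization
#' strength used in phase reconstruction. Defaults describe a 10x/0.25
#' objective with an 8x8 LED array (18 mm square, 24 mm above the sample)
#' giving an illumination NA of 0.39, red LEDs at 624 nm, and a camera pixel
#' size of 0.54 um at the sample plane.
#'
#' The coherence parameter sigma = NA_illum / NA_obj exceeds 1, i.e. the
#' system operates in the partially coherent regime required for DPC.
#'
#' @param wavelength_um illumination wavelength in micrometres.
#' @param na_objective numerical aperture of the objective.
#' @param na_illumination numerical aperture of the LED illumination.
#' @param pixel_size_um pixel size at the sample plane, micrometres.
#' @param regularization_beta Tikhonov regularization constant (applied to
#'   transfer functions scaled to unit maximum magnitude).
#' @param illumination_axes orientations (degrees) of the two DPC axes.
#' @param led_pitch_mm spacing between adjacent LEDs in the array.
#' @param led_height_mm distance from the LED array to the sample plane.
#' @param led_grid number of LEDs along one side of the square array.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelength_um = 0.624,
                           na_objective = 0.25,
                           na_illumination = 0.39,
                           pixel_size_um = 0.54,
                           regularization_beta = 1e-3,
                           illumination_axes = c(90, 180),
                           led_pitch_mm = 18 / 8,
                           led_height_mm = 24,
                           led_grid = 8) {
  stopifnot(wavelength_um > 0, pixel_size_um > 0, regularization_beta > 0,
            na_objective > 0)
  if (na_objective > na_illumination)
    stop("DPC requires the partially coherent regime: na_illumination >= na_objective")
  structure(list(
    wavelength_um = wavelength_um,
    na_objective = na_objective,
    na_illumination = na_illumination,
    pixel_size_um = pixel_size_um,
    coherence_sigma = na_illumination / na_objective,
    regularization_beta = regularization_beta,
    illumination_axes = illumination_axes,
    led_pitch_mm = led_pitch_mm,
    led_height_mm = led_height_mm,
    led_grid = led_grid
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("DPC optical configuration\n")
  cat(sprintf("  wavelength        %.3f um\n", x$wavelength_um))
  cat(sprintf("  NA objective      %.2f\n", x$na_objective))
  cat(sprintf("  NA illumination   %.2f (sigma = %.2f)\n",
              x$na_illumination, x$coherence_sigma))
  cat(sprintf("  pixel size        %.2f um\n", x$pixel_size_um))
  cat(sprintf("  regularization    %g\n", x$regularization_beta))
  invisible(x)
}

#' Four-frame DPC acquisition
#'
#' A single DPC acquisition consists of four intensity images taken with
#' half-circle illumination from the top, bottom, left, and right halves of
#' the LED array. All four must share dimensions and be nonnegative.
#'
#' @param top,bottom,left,right numeric matrices of raw intensities.
#' @param timestamp acquisition time (hours), optional.
#' @param location_id identifier of the imaging location, optional.
#' @return An object of class `dpc_frameset`.
#' @export
dpc_frameset <- function(top, bottom, left, right,
                         timestamp = NA_real_, location_id = NA_character_) {
  frames <- list(top = top, bottom = bottom, left = left, right = right)
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1L)
    stop("all four DPC frames must have identical dimensions")
  for (nm in names(frames)) {
    if (!all(is.finite(frames[[nm]])) || any(frames[[nm]] < 0))
      stop("DPC frame '", nm, "' must be finite and nonnegative")
  }
  structure(c(frames, list(timestamp = timestamp, location_id = location_id)),
            class = "dpc_frameset")
}

#' Reconstructed phase image
#'
#' @param phase numeric matrix of phase shifts in radians.
#' @param pixel_size_um pixel size at the sample plane, micrometres.
#' @param timestamp acquisition time (hours), optional.
#' @param location_id imaging-location identifier, optional.
#' @return An object of class `phase_image`.
#' @export
phase_image <- function(phase, pixel_size_um,
                        timestamp = NA_real_, location_id = NA_character_) {
  stopifnot(is.matrix(phase), pixel_size_um > 0)
  if (!all(is.finite(phase))) stop("phase image must be finite everywhere")
  structure(list(phase = phase, pixel_size_um = pixel_size_um,
                 timestamp = timestamp, location_id = location_id),
            class = "phase_image")
}

#' LED array alignment check from an empty-sample acquisition
#'
#' With no sample in place the four half-circle illuminations should deliver
#' equal intensity; a deviation of any half from the grand mean beyond the
#' tolerance indicates a decentred array. The instrument acceptance criterion
#' used during system calibration is that each half agrees with the mean to
#' within 5%.
#'
#' @param frames a [dpc_frameset()] acquired with no sample.
#' @param tolerance maximum tolerated relative deviation from the grand mean.
#' @return A list with per-half mean intensities, relative deviations, and an
#'   `aligned` flag.
#' @export
check_led_alignment <- function(frames, tolerance = 0.05) {
  stopifnot(inherits(frames, "dpc_frameset"))
  halves <- c("top", "bottom", "left", "right")
  means <- vapply(halves, function(h) mean(frames[[h]]), numeric(1))
  if (any(means <= 0))
    stop("invalid acquisition: zero-intensity half-circle frame")
  grand <- mean(means)
  deviation <- (means - grand) / grand
  list(half_means = means,
       grand_mean = grand,
       relative_deviation = deviation,
       tolerance = tolerance,
       aligned = all(abs(deviation) <= tolerance))
}

#' Normalized DPC phase gradient from an opposing frame pair
#'
#' The DPC signal along one axis is the normalized difference of the two
#' opposing half-circle images, (I1 - I2)/(I1 + I2), which in the weak-object
#' regime is a linear function of the sample phase. Bounded in \[-1, 1\].
#'
#' @param i1,i2 intensity matrices of the opposing pair (e.g. top, bottom).
#' @param guard if TRUE, pixels where I1 + I2 = 0 are floored at machine
#'   epsilon (with a warning) instead of producing NaN.
#' @return A matrix in \[-1, 1\].
#' @export
compute_phase_gradient <- function(i1, i2, guard = TRUE) {
  if (!identical(dim(i1), dim(i2))) stop("opposing frames differ in shape")
  s <- i1 + i2
  if (any(s == 0)) {
    if (!guard) stop("zero-sum pixels in DPC pair")
    warning("zero-sum pixels floored at machine epsilon")
    s[s == 0] <- .Machine$double.eps
  }
  (i1 - i2) / s
}

# FFT frequency coordinates in cycles per micrometre, matching stats::fft
# layout (DC first, negative frequencies in the upper half).
fft_freq <- function(n, pixel_size_um) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * pixel_size_um)
}

# Direction sines (sx, sy) of the brightfield LEDs in one half of the array.
# The array is a led_grid x led_grid square of pitch led_pitch_mm centred on
# the optical axis at height led_height_mm; LEDs whose individual NA exceeds
# na_illumination are outside the illumination aperture and dropped, and only
# LEDs inside the objective pupil (NA <= na_objective) contribute to the
# weak-object transfer function.
led_half_sines <- function(config, half = c("top", "bottom", "left", "right")) {
  half <- match.arg(half)
  g <- config$led_grid
  pos <- (seq_len(g) - (g + 1) / 2) * config$led_pitch_mm
  grid <- expand.grid(x = pos, y = pos)
  r <- sqrt(grid$x^2 + grid$y^2)
  hyp <- sqrt(r^2 + config$led_height_mm^2)
  na_led <- r / hyp
  keep <- na_led <= config$na_illumination
  keep <- keep & switch(half,
    top = grid$y > 0, bottom = grid$y < 0,
    left = grid$x < 0, right = grid$x > 0)
  data.frame(sx = grid$x[keep] / hyp[keep], sy = grid$y[keep] / hyp[keep])
}

#' Weak-object phase transfer function for one DPC axis
#'
#' Computes the phase transfer function of the normalized DPC signal for a
#' half-circle LED source, as the numerical pupil/source overlap sum over the
#' discrete LED positions: for each brightfield LED at illumination frequency
#' u_s, the shifted-pupil difference P(u + u_s) - P(u - u_s) is accumulated on
#' the FFT frequency grid. The result is purely imaginary, antisymmetric
#' under frequency inversion, zero at DC, and zero beyond the partially
#' coherent cutoff. It is scaled to unit maximum magnitude so that the
#' regularization constant has a consistent meaning across image sizes.
#'
#' @param config an [optical_config()].
#' @param axis DPC axis in degrees: 90 (top/bottom pair, vertical gradient)
#'   or 180 (left/right pair, horizontal gradient).
#' @param shape integer c(rows, cols) of the target images.
#' @return A complex matrix of dimension `shape`.
#' @export
build_phase_transfer_function <- function(config, axis, shape) {
  if (!axis %in% config$illumination_axes)
    stop("unsupported DPC axis: ", axis)
  nr <- shape[1]; nc <- shape[2]
  fy <- fft_freq(nr, config$pixel_size_um)
  fx <- fft_freq(nc, config$pixel_size_um)
  FY <- matrix(fy, nr, nc)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  rho <- config$na_objective / config$wavelength_um   # pupil radius, 1/um
  leds <- led_half_sines(config, if (axis == 90) "top" else "left")
  H <- matrix(0, nr, nc)
  for (i in seq_len(nrow(leds))) {
    usx <- leds$sx[i] / config$wavelength_um
    usy <- leds$sy[i] / config$wavelength_um
    if (sqrt(usx^2 + usy^2) > rho) next   # darkfield LED: no linear contrast
    plus  <- (FX + usx)^2 + (FY + usy)^2 <= rho^2
    minus <- (FX - usx)^2 + (FY - usy)^2 <= rho^2
    H <- H + (plus - minus)
  }
  m <- max(abs(H))
  if (m == 0) stop("transfer function identically zero; check geometry")
  (1i * H) / m
}

#' Tikhonov-regularized phase reconstruction
#'
#' Inverts one or more normalized DPC gradient images through their phase
#' transfer functions by regularized least squares in the frequency domain:
#' phi = IFFT\[ sum_j conj(H_j) G_j / (sum_j |H_j|^2 + beta) \].
#'
#' @param gradients list of normalized difference images (matrices).
#' @param tfs list of matching complex transfer functions.
#' @param beta Tikhonov regularization constant (> 0).
#' @param pixel_size_um pixel size recorded on the output [phase_image()].
#' @param timestamp,location_id metadata carried to the output.
#' @return A [phase_image()].
#' @export
tikhonov_reconstruct <- function(gradients, tfs, beta = 1e-3,
                                 pixel_size_um = 0.54,
                                 timestamp = NA_real_,
                                 location_id = NA_character_) {
  if (beta <= 0) stop("beta must be positive")
  if (length(gradients) < 1 || length(gradients) != length(tfs))
    stop("need matching nonempty gradient / transfer-function lists")
  d <- dim(gradients[[1]])
  num <- matrix(0 + 0i, d[1], d[2])
  den <- matrix(beta, d[1], d[2])
  for (j in seq_along(gradients)) {
    if (!identical(dim(gradients[[j]]), d) || !identical(dim(tfs[[j]]), d))
      stop("gradient/transfer-function shape mismatch")
    num <- num + Conj(tfs[[j]]) * stats::fft(gradients[[j]])
    den <- den + Mod(tfs[[j]])^2
  }
  phi_c <- stats::fft(num / den, inverse = TRUE) / length(num)
  resid <- max(abs(Im(phi_c)))
  amp <- max(abs(Re(phi_c)), .Machine$double.eps)
  if (resid > 1e-6 * amp)
    warning(sprintf("imaginary residue %.3g exceeds 1e-6 of max amplitude", resid))
  phase_image(Re(phi_c), pixel_size_um,
              timestamp = timestamp, location_id = location_id)
}

#' Forward-simulate a four-frame DPC acquisition
#'
#' Applies the linearized weak-object forward model: each half-circle frame is
#' background * (1 + response), where the response is the real-space action of
#' the axis transfer function on the phantom phase (positive sign for the
#' top/left frames, negative for their opposites). Optional multiplicative
#' shot-like Gaussian noise is seeded for determinism. Valid for small-phase
#' phantoms (|phi| up to ~1 rad).
#'
#' @param phantom a [phase_image()] ground-truth phantom.
#' @param config an [optical_config()].
#' @param noise_level standard deviation of multiplicative intensity noise,
#'   as a fraction of the local intensity (0 disables noise).
#' @param seed integer seed for the noise draw.
#' @param background mean background intensity level.
#' @return A [dpc_frameset()].
#' @export
simulate_dpc_frames <- function(phantom, config, noise_level = 0, seed = NULL,
                                background = 1) {
  stopifnot(inherits(phantom, "phase_image"))
  d <- dim(phantom$phase)
  Hv <- build_phase_transfer_function(config, 90, d)
  Hh <- build_phase_transfer_function(config, 180, d)
  PH <- stats::fft(phantom$phase)
  sv <- Re(stats::fft(Hv * PH, inverse = TRUE)) / length(PH)
  sh <- Re(stats::fft(Hh * PH, inverse = TRUE)) / length(PH)
  frames <- list(top = background * (1 + sv), bottom = background * (1 - sv),
                 left = background * (1 + sh), right = background * (1 - sh))
  if (noise_level > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (nm in names(frames)) {
      frames[[nm]] <- frames[[nm]] *
        (1 + noise_level * matrix(stats::rnorm(prod(d)), d[1], d[2]))
    }
  }
  frames <- lapply(frames, function(f) pmax(f, 0))
  dpc_frameset(frames$top, frames$bottom, frames$left, frames$right,
               timestamp = phantom$timestamp, location_id = phantom$location_id)
}

#' Reconstruct phase from a four-frame DPC acquisition
#'
#' Convenience wrapper chaining [compute_phase_gradient()] on the two
#' opposing pairs with [build_phase_transfer_function()] and
#' [tikhonov_reconstruct()].
#'
#' @param frames a [dpc_frameset()].
#' @param config an [optical_config()].
#' @param beta Tikhonov regularization; defaults to the configured value.
#' @return A [phase_image()].
#' @export
reconstruct_phase <- function(frames, config,
                              beta = config$regularization_beta) {
  d <- dim(frames$top)
  gv <- compute_phase_gradient(frames$top, frames$bottom)
  gh <- compute_phase_gradient(frames$left, frames$right)
  Hv <- build_phase_transfer_function(config, 90, d)
  Hh <- build_phase_transfer_function(config, 180, d)
  tikhonov_reconstruct(list(gv, gh), list(Hv, Hh), beta = beta,
                       pixel_size_um = config$pixel_size_um,
                       timestamp = frames$timestamp,
                       location_id = frames$location_id)
}

#' Spherical-bead phase phantom
#'
#' Builds the phase map of spherical beads of known refractive index embedded
#' in a homogeneous medium: phi(x, y) = (2 pi / lambda) * (n_bead - n_medium)
#' * thickness(x, y), with the chord thickness 2 sqrt(r^2 - d^2) of a sphere.
#' Thickness is supersampled within each pixel so the discrete integrated
#' phase matches the analytic sphere volume closely.
#'
#' @param shape image dimensions c(rows, cols).
#' @param centers_px data.frame or matrix with columns x, y (pixel units,
#'   1-based centres).
#' @param radius_um bead radius in micrometres (scalar or per-bead vector).
#' @param n_bead,n_medium refractive indices of bead and medium.
#' @param config an [optical_config()] (wavelength and pixel size).
#' @param supersample subpixel sampling factor per axis.
#' @return A [phase_image()].
#' @export
bead_phantom <- function(shape, centers_px, radius_um, n_bead = 1.583,
                         n_medium = 1.56, config = optical_config(),
                         supersample = 8) {
  centers_px <- as.data.frame(centers_px)
  radius_um <- rep_len(radius_um, nrow(centers_px))
  p <- config$pixel_size_um
  phi <- matrix(0, shape[1], shape[2])
  ss <- supersample
  off <- (seq_len(ss) - (ss + 1) / 2) / ss   # subpixel offsets in pixels
  for (b in seq_len(nrow(centers_px))) {
    r_px <- radius_um[b] / p
    ix <- which(abs(seq_len(shape[2]) - centers_px$x[b]) <= r_px + 1)
    iy <- which(abs(seq_len(shape[1]) - centers_px$y[b]) <= r_px + 1)
    if (!length(ix) || !length(iy)) next
    thick <- matrix(0, length(iy), length(ix))
    for (oy in off) for (ox in off) {
      dy <- (iy + oy - centers_px$y[b])
      dx <- (ix + ox - centers_px$x[b])
      d2 <- outer(dy^2, dx^2, "+")
      thick <- thick + ifelse(d2 < r_px^2, 2 * sqrt(pmax(r_px^2 - d2, 0)), 0)
    }
    thick <- thick * p / ss^2   # mean chord length in um
    phi[iy, ix] <- phi[iy, ix] +
      (2 * pi / config$wavelength_um) * (n_bead - n_medium) * thick
  }
  phase_image(phi, p)
}

#' Recover bead refractive indices from a reconstructed phase image
#'
#' For each bead of known centre and radius, integrates the reconstructed
#' phase over a disk of the bead radius and converts it to a refractive index
#' via n = n_medium + (lambda / 2 pi) * sum(phi) * A_pixel / V_bead with the
#' analytic sphere volume. DPC reconstruction does not preserve the global
#' phase offset and leaves a smooth shallow depression around compact
#' objects (its low-frequency response is attenuated), so each bead's local
#' background — the median phase in an annulus between 2 and 3 bead radii —
#' is subtracted before integrating, as in aperture photometry. Beads
#' touching the image border are excluded with a warning. Given a list of
#' repeated phase images of the same field, also reports the temporal
#' coefficient of variation of the mean index.
#'
#' @param phase a [phase_image()], or a list of them (repeated acquisitions
#'   of the same field) for temporal-precision estimation.
#' @param centers_px data.frame with columns x, y (pixels).
#' @param radius_um bead radius in micrometres (scalar or per-bead).
#' @param medium_index refractive index of the embedding medium.
#' @param config an [optical_config()].
#' @param reference_index book value for the bead material, reported back for
#'   convenience (default 1.583, polystyrene at 624 nm).
#' @return A list with `per_bead_indices`, `mean_refractive_index`,
#'   `reference_index`, `medium_index`, and (for repeated frames)
#'   `temporal_cv` and `per_frame_means`.
#' @export
calibrate_with_beads <- function(phase, centers_px, radius_um,
                                 medium_index = 1.56,
                                 config = optical_config(),
                                 reference_index = 1.583) {
  if (inherits(phase, "phase_image")) {
    frames <- list(phase)
  } else {
    frames <- phase
    stopifnot(all(vapply(frames, inherits, logical(1), "phase_image")))
  }
  centers_px <- as.data.frame(centers_px)
  radius_um <- rep_len(radius_um, nrow(centers_px))
  p <- frames[[1]]$pixel_size_um
  d <- dim(frames[[1]]$phase)
  xg <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  yg <- matrix(seq_len(d[1]), d[1], d[2])

  r_px <- radius_um / p
  dist2 <- function(b) (xg - centers_px$x[b])^2 + (yg - centers_px$y[b])^2
  keep <- vapply(seq_len(nrow(centers_px)), function(b) {
    centers_px$x[b] - r_px[b] >= 1 && centers_px$x[b] + r_px[b] <= d[2] &&
      centers_px$y[b] - r_px[b] >= 1 && centers_px$y[b] + r_px[b] <= d[1]
  }, logical(1))
  if (!all(keep)) warning(sum(!keep), " bead(s) touching the image border excluded")
  if (!any(keep)) stop("no beads fully inside the image")
  if (any(radius_um <= 0)) stop("bead volume zero")

  per_frame <- lapply(frames, function(fr) {
    phi <- fr$phase
    vapply(which(keep), function(b) {
      d2 <- dist2(b)
      ann <- d2 > (2 * r_px[b])^2 & d2 <= (3 * r_px[b])^2
      local_bg <- if (any(ann)) stats::median(phi[ann]) else 0
      v_bead <- 4 / 3 * pi * radius_um[b]^3                    # um^3
      s <- sum(phi[d2 <= r_px[b]^2] - local_bg) * p^2          # rad um^2
      medium_index + (config$wavelength_um / (2 * pi)) * s / v_bead
    }, numeric(1))
  })
  frame_means <- vapply(per_frame, mean, numeric(1))
  out <- list(per_bead_indices = per_frame[[1]],
              mean_refractive_index = mean(frame_means),
              reference_index = reference_index,
              medium_index = medium_index)
  if (length(frames) > 1) {
    out$per_frame_means <- frame_means
    out$temporal_cv <- stats::sd(frame_means) / mean(frame_means)
  }
  out
}

#' Read and write DPC frames and phase maps as TIFF
#'
#' Frames follow the naming convention
#' `{location}_{timeindex}_{top|bottom|left|right}.tif` (configurable via
#' `pattern`); phase maps are written as 32-bit floating-point TIFF.
#'
#' @param dir directory containing the four frame files.
#' @param location,timeindex identifiers substituted into the pattern.
#' @param pattern file-name pattern with `{location}`, `{timeindex}`,
#'   `{half}` placeholders.
#' @return `read_dpc_frames` returns a [dpc_frameset()].
#' @export
read_dpc_frames <- function(dir, location, timeindex,
                            pattern = "{location}_{timeindex}_{half}.tif") {
  halves <- c("top", "bottom", "left", "right")
  imgs <- lapply(halves, function(h) {
    f <- gsub("{half}", h, gsub("{timeindex}", timeindex,
         gsub("{location}", location, pattern, fixed = TRUE), fixed = TRUE),
         fixed = TRUE)
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing DPC frame: ", path)
    m <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  dpc_frameset(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]],
               timestamp = NA_real_, location_id = as.character(location))
}

#' @rdname read_dpc_frames
#' @param img a [phase_image()] (for writing) .
#' @param path output/input TIFF path.
#' @details Phase values are affinely mapped to \[0, 1\] for 32-bit TIFF
#'   storage; the offset, scale, and pixel size travel in a JSON sidecar
#'   (`<path>.json`) and are restored on read.
#' @export
write_phase_tiff <- function(img, path) {
  stopifnot(inherits(img, "phase_image"))
  lo <- min(img$phase); hi <- max(img$phase)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img$phase - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(list(offset = lo, scale = scale,
                            pixel_size_um = img$pixel_size_um,
                            timestamp = img$timestamp,
                            location_id = img$location_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_dpc_frames
#' @param pixel_size_um pixel size used when no sidecar metadata is found.
#' @export
read_phase_tiff <- function(path, pixel_size_um = 0.54) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    m <- m * meta$scale + meta$offset
    return(phase_image(m, meta$pixel_size_um,
                       timestamp = if (is.null(meta$timestamp)) NA_real_
                                   else meta$timestamp,
                       location_id = if (is.null(meta$location_id))
                                       NA_character_ else meta$location_id))
  }
  phase_image(m, pixel_size_um)
}

#' Project a phantom onto the DPC passband
#'
#' DPC has no response at DC and in a small neighbourhood of it (and beyond
#' the partially coherent cutoff), so only the in-band content of a phantom
#' is recoverable. This helper zeroes all frequency components where the
#' combined two-axis response |Hv|^2 + |Hh|^2 falls below `min_response`,
#' yielding a band-limited phantom for which reconstruction round trips are
#' meaningful.
#'
#' @param img a [phase_image()].
#' @param config an [optical_config()].
#' @param min_response minimum combined squared transfer-function magnitude
#'   (transfer functions are unit-max-normalized, so this is relative).
#' @return A band-limited [phase_image()].
#' @export
bandlimit_phantom <- function(img, config, min_response = 0.05) {
  stopifnot(inherits(img, "phase_image"))
  d <- dim(img$phase)
  Hv <- build_phase_transfer_function(config, 90, d)
  Hh <- build_phase_transfer_function(config, 180, d)
  W <- (Mod(Hv)^2 + Mod(Hh)^2) >= min_response
  ph <- Re(stats::fft(stats::fft(img$phase) * W, inverse = TRUE)) / prod(d)
  phase_image(ph, img$pixel_size_um, img$timestamp, img$location_id)
}
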