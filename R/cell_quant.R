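#' Segmentation and background-correction parameters
#'
#' @param background_poly_order total degree of the 2D background polynomial
#'   fitted to non-cell pixels (default 8).
#' @param rolling_ball_radius radius in pixels of the disk structuring
#'   element used for rolling-ball background removal (default 100).
#' @param use_watershed split touching objects with an intensity watershed
#'   (used for single-cell lines; off for cluster-forming lines).
#' @param min_object_area_px minimum object area in pixels; smaller objects
#'   are discarded as debris.
#' @param edge_quantile quantile of the nonzero Sobel gradient magnitude used
#'   as the edge threshold.
#' @param refine_fraction after the morphological fill, each candidate object
#'   is trimmed to pixels above this fraction of its peak phase (half-maximum
#'   by default), making the measured area robust to the edge threshold. Set
#'   to 0 to disable.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(background_poly_order = 8,
                                rolling_ball_radius = 100,
                                use_watershed = FALSE,
                                min_object_area_px = 20,
                                edge_quantile = 0.9,
                                refine_fraction = 0.5) {
  stopifnot(background_poly_order >= 0, rolling_ball_radius > 0,
            min_object_area_px >= 0, edge_quantile > 0, edge_quantile < 1,
            refine_fraction >= 0, refine_fraction < 1)
  structure(list(background_poly_order = background_poly_order,
                 rolling_ball_radius = rolling_ball_radius,
                 use_watershed = use_watershed,
                 min_object_area_px = min_object_area_px,
                 edge_quantile = edge_quantile,
                 refine_fraction = refine_fraction),
            class = "segmentation_params")
}

sobel_magnitude <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(m, kx)
  gy <- EBImage::filter2(m, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Segment cells from a phase image
#'
#' Edges are found with a Sobel gradient-magnitude filter; morphological
#' closing and hole filling turn the edge ring into a solid mask, which is
#' then lightly opened to remove specks. Objects below the minimum area are
#' dropped. With `use_watershed`, touching objects are split along intensity
#' valleys (watershed on the masked phase), which is appropriate for
#' single-cell lines.
#'
#' @param phase a [phase_image()] (background-flat or corrected).
#' @param params a [segmentation_params()].
#' @return An integer label matrix (0 = background).
#' @export
segment_cells <- function(phase, params = segmentation_params()) {
  stopifnot(inherits(phase, "phase_image"))
  m <- phase$phase
  if (all(m == m[1])) return(matrix(0L, nrow(m), ncol(m)))
  mag <- sobel_magnitude(m)
  nz <- mag[mag > 1e-12 * max(mag)]
  if (!length(nz)) return(matrix(0L, nrow(m), ncol(m)))
  thr <- stats::quantile(nz, params$edge_quantile)
  edges <- mag > thr
  k3 <- EBImage::makeBrush(3, "box")
  mask <- EBImage::closing(edges, EBImage::makeBrush(5, "disc"))
  mask <- EBImage::fillHull(mask)
  mask <- EBImage::opening(mask, k3)
  lab <- EBImage::bwlabel(mask)
  if (params$refine_fraction > 0) {
    lab <- matrix(as.integer(lab), nrow(m), ncol(m))
    for (id in seq_len(max(lab))) {
      sel <- lab == id
      peak <- max(m[sel])
      lab[sel & m < params$refine_fraction * peak] <- 0L
    }
    lab <- EBImage::bwlabel(lab > 0)
  }
  if (params$use_watershed) {
    h <- m - min(m)
    lab <- EBImage::watershed(EBImage::Image(h * (lab > 0)), tolerance = 0.05)
    lab <- EBImage::imageData(lab)
  }
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  if (params$min_object_area_px > 0) {
    tab <- tabulate(lab[lab > 0])
    drop <- which(tab < params$min_object_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    # relabel consecutively
    u <- sort(unique(lab[lab > 0]))
    if (length(u)) lab[lab > 0] <- match(lab[lab > 0], u)
  }
  lab
}

# 2D polynomial basis of total degree <= ord on scaled [-1,1] coordinates
poly2d_basis <- function(xs, ys, ord) {
  cols <- list()
  for (i in 0:ord) for (j in 0:(ord - i)) cols[[length(cols) + 1]] <- xs^i * ys^j
  do.call(cbind, cols)
}

#' Background correction: polynomial surface plus rolling-ball removal
#'
#' Fits a 2D polynomial of total degree `background_poly_order` to the
#' non-cell (background) pixels only and subtracts it everywhere, then
#' applies rolling-ball background removal (grayscale opening with a disk
#' structuring element) and finally zeroes the median of the background
#' pixels. If too few background pixels are available to constrain the
#' polynomial, the order is reduced with a warning.
#'
#' @param phase a [phase_image()].
#' @param mask integer label matrix aligned with `phase` (0 = background); a
#'   NULL mask treats every pixel as background.
#' @param params a [segmentation_params()].
#' @param rolling_ball apply the rolling-ball step (default TRUE).
#' @return A background-corrected [phase_image()].
#' @export
correct_background <- function(phase, mask = NULL,
                               params = segmentation_params(),
                               rolling_ball = TRUE) {
  stopifnot(inherits(phase, "phase_image"))
  m <- phase$phase
  d <- dim(m)
  if (is.null(mask)) mask <- matrix(0L, d[1], d[2])
  if (!identical(dim(mask), d)) stop("mask not aligned with phase image")
  bg <- mask == 0
  xs <- matrix(seq(-1, 1, length.out = d[2]), d[1], d[2], byrow = TRUE)
  ys <- matrix(seq(-1, 1, length.out = d[1]), d[1], d[2])
  ord <- params$background_poly_order
  n_par <- function(o) (o + 1) * (o + 2) / 2
  n_bg <- sum(bg)
  while (ord > 0 && n_bg < n_par(ord)) ord <- ord - 1
  if (ord < params$background_poly_order)
    warning(sprintf("only %d background pixels; polynomial order reduced to %d",
                    n_bg, ord))
  if (n_bg >= 1) {
    B <- poly2d_basis(xs[bg], ys[bg], ord)
    fit <- stats::lm.fit(B, m[bg])
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    surf <- matrix(poly2d_basis(c(xs), c(ys), ord) %*% coefs, d[1], d[2])
    m <- m - surf
  }
  if (rolling_ball) {
    r <- min(params$rolling_ball_radius, floor(min(d) / 2) - 1)
    brush <- EBImage::makeBrush(2 * r + 1, "disc")
    lo <- min(m)
    est <- EBImage::opening(m - lo, brush) + lo
    m <- m - est
  }
  if (any(bg)) m <- m - stats::median(m[bg])
  phase_image(m, phase$pixel_size_um, phase$timestamp, phase$location_id)
}

#' Dry mass from integrated phase
#'
#' Converts integrated optical phase to dry mass through the specific
#' refractive increment alpha: mass = (lambda / 2 pi) * sum(phi) * A_pixel /
#' alpha. With the default alpha = 1.8e-4 m^3/kg (0.18 um^3/pg), phase in
#' radians and pixel area in um^2, the result is in picograms. Mass is
#' additive over disjoint regions; a negative total (debris, noise) is
#' allowed but flagged with a warning.
#'
#' @param phase a [phase_image()].
#' @param region logical/numeric matrix selecting pixels (NULL = whole
#'   image), or an integer label matrix together with `label`.
#' @param config an [optical_config()] (wavelength).
#' @param alpha_um3_pg specific refractive increment in um^3/pg.
#' @param label object label when `region` is a label matrix.
#' @return Mass in picograms.
#' @export
compute_mass <- function(phase, region = NULL, config = optical_config(),
                         alpha_um3_pg = 0.18, label = NULL) {
  stopifnot(inherits(phase, "phase_image"), alpha_um3_pg > 0)
  sel <- if (is.null(region)) rep(TRUE, length(phase$phase))
         else if (!is.null(label)) region == label
         else region != 0
  s <- sum(phase$phase[sel])
  mass <- (config$wavelength_um / (2 * pi)) * s * phase$pixel_size_um^2 /
    alpha_um3_pg
  if (mass < 0) warning("negative total mass (debris or noise region)")
  mass
}

#' Per-object observations from a labelled phase image
#'
#' @param phase a [phase_image()].
#' @param labels integer label matrix from [segment_cells()].
#' @param frame_index integer frame number.
#' @param time_h acquisition time in hours.
#' @param config an [optical_config()].
#' @param alpha_um3_pg specific refractive increment in um^3/pg.
#' @return A data.frame with one row per object: frame_index, time_h, label,
#'   x, y (centroid, pixels), area_um2, mass_pg, mean_phase.
#' @export
measure_cells <- function(phase, labels, frame_index = 1L, time_h = 0,
                          config = optical_config(), alpha_um3_pg = 0.18) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    return(data.frame(frame_index = integer(), time_h = numeric(),
                      label = integer(), x = numeric(), y = numeric(),
                      area_um2 = numeric(), mass_pg = numeric(),
                      mean_phase = numeric()))
  }
  p2 <- phase$pixel_size_um^2
  rows <- lapply(ids, function(id) {
    sel <- labels == id
    idx <- which(sel, arr.ind = TRUE)
    phi <- phase$phase[sel]
    data.frame(frame_index = frame_index, time_h = time_h, label = id,
               x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1,
               area_um2 = nrow(idx) * p2,
               mass_pg = (config$wavelength_um / (2 * pi)) * sum(phi) * p2 /
                 alpha_um3_pg,
               mean_phase = mean(phi))
  })
  do.call(rbind, rows)
}

#' Link per-frame observations into tracks
#'
#' Greedy nearest-neighbour assignment between successive frames, minimizing
#' the combined cost (dpos / position_scale)^2 + (dmass / mass_scale)^2.
#' Pairs are assigned in order of increasing cost (ties broken by lowest
#' previous then lowest current label), so linking is deterministic.
#' Unmatched current-frame objects start new tracks; tracks with no match
#' end.
#'
#' Default scales follow the data: position_scale is twice the median
#' nearest-neighbour spacing in each frame, mass_scale the median object
#' mass.
#'
#' @param observations data.frame as from [measure_cells()] covering several
#'   frames (columns frame_index, time_h, x, y, mass_pg at minimum).
#' @param position_scale length scale (pixels) for the position cost; NULL
#'   for the per-frame default.
#' @param mass_scale mass scale (pg) for the mass cost; NULL for the median
#'   object mass.
#' @param max_cost assignments with combined cost above this are not made.
#' @return The input data.frame with a `track_id` column, ordered by track
#'   and time.
#' @export
link_tracks <- function(observations, position_scale = NULL,
                        mass_scale = NULL, max_cost = Inf) {
  obs <- observations[order(observations$frame_index), , drop = FALSE]
  if (!nrow(obs)) { obs$track_id <- integer(); return(obs) }
  frames <- sort(unique(obs$frame_index))
  obs$track_id <- NA_integer_
  obs$.row <- seq_len(nrow(obs))
  next_id <- 1L
  prev <- obs[obs$frame_index == frames[1], , drop = FALSE]
  obs$track_id[prev$.row] <- seq_len(nrow(prev))
  next_id <- nrow(prev) + 1L
  prev$track_id <- seq_len(nrow(prev))
  global_mass_scale <- mass_scale
  if (is.null(global_mass_scale)) {
    global_mass_scale <- stats::median(abs(obs$mass_pg))
    if (!is.finite(global_mass_scale) || global_mass_scale == 0)
      global_mass_scale <- 1
  }
  for (fi in seq_along(frames)[-1]) {
    cur <- obs[obs$frame_index == frames[fi], , drop = FALSE]
    if (!nrow(cur)) { prev <- cur; next }
    if (!nrow(prev)) {
      obs$track_id[cur$.row] <- next_id + seq_len(nrow(cur)) - 1L
      next_id <- next_id + nrow(cur)
      cur$track_id <- obs$track_id[cur$.row]
      prev <- cur
      next
    }
    ps <- position_scale
    if (is.null(ps)) {
      pts <- cbind(cur$x, cur$y)
      if (nrow(pts) > 1) {
        dm <- as.matrix(stats::dist(pts))
        diag(dm) <- Inf
        ps <- 2 * stats::median(apply(dm, 1, min))
        if (!is.finite(ps) || ps == 0) ps <- 1
      } else ps <- 1
    }
    dp2 <- (outer(prev$x, cur$x, "-")^2 + outer(prev$y, cur$y, "-")^2) / ps^2
    dm2 <- outer(prev$mass_pg, cur$mass_pg, "-")^2 / global_mass_scale^2
    cost <- dp2 + dm2
    ord <- order(c(cost), prev$label[row(cost)], cur$label[col(cost)])
    used_prev <- logical(nrow(prev)); used_cur <- logical(nrow(cur))
    assign_cur <- rep(NA_integer_, nrow(cur))
    for (k in ord) {
      if (cost[k] > max_cost) break
      i <- row(cost)[k]; j <- col(cost)[k]
      if (used_prev[i] || used_cur[j]) next
      used_prev[i] <- TRUE; used_cur[j] <- TRUE
      assign_cur[j] <- prev$track_id[i]
    }
    new_n <- sum(is.na(assign_cur))
    assign_cur[is.na(assign_cur)] <- next_id + seq_len(new_n) - 1L
    next_id <- next_id + new_n
    obs$track_id[cur$.row] <- assign_cur
    cur$track_id <- assign_cur
    prev <- cur
  }
  obs$.row <- NULL
  obs[order(obs$track_id, obs$frame_index), , drop = FALSE]
}
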