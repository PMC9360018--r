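#' Track filtering parameters for SGR estimation
#'
#' Defaults follow the screening protocol: tracks shorter than 20 frames are
#' dropped, masses are median-filtered with a 5-frame kernel, tracks whose
#' filtered mean mass is below 110 pg are treated as debris, and records more
#' than 3 median absolute deviations from the median (in either the specific
#' growth rate k or the standard error of the estimate s_y.x) are outliers.
#'
#' @param min_frames minimum track length in frames.
#' @param median_kernel odd kernel size (frames) for the running median.
#' @param min_mean_mass_pg minimum filtered mean mass in picograms.
#' @param mad_multiplier outlier cut in (raw) median absolute deviations.
#' @return An object of class `track_filter_params`.
#' @export
track_filter_params <- function(min_frames = 20, median_kernel = 5,
                                min_mean_mass_pg = 110, mad_multiplier = 3) {
  stopifnot(min_frames > 0, median_kernel > 0, median_kernel %% 2 == 1,
            min_mean_mass_pg > 0, mad_multiplier > 0)
  structure(list(min_frames = min_frames, median_kernel = median_kernel,
                 min_mean_mass_pg = min_mean_mass_pg,
                 mad_multiplier = mad_multiplier),
            class = "track_filter_params")
}

#' Convert between specific growth rate and doubling time
#'
#' For exponential growth, SGR = ln(2) / t_doubling; the two functions are
#' mutual inverses.
#'
#' @param t_doubling_h doubling time in hours (> 0).
#' @return `sgr_from_doubling_time` returns the SGR in 1/h;
#'   `doubling_time_from_sgr` returns the doubling time in hours.
#' @export
sgr_from_doubling_time <- function(t_doubling_h) {
  if (any(t_doubling_h <= 0)) stop("doubling time must be positive")
  log(2) / t_doubling_h
}

#' @rdname sgr_from_doubling_time
#' @param sgr_h specific growth rate in 1/h (> 0).
#' @export
doubling_time_from_sgr <- function(sgr_h) {
  if (any(sgr_h <= 0)) stop("SGR must be positive to define a doubling time")
  log(2) / sgr_h
}

median_filter_series <- function(x, k) {
  if (length(x) < k) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

#' Specific growth rate of one mass-versus-time track
#'
#' Applies the track filters (minimum length, median filter, minimum mean
#' mass), time-shifts the track so its first observation is at t = 0, fits
#' ordinary least squares mass-versus-time, and reports the slope (growth
#' rate, pg/h), intercept (initial mass, pg), their ratio (SGR, 1/h), and the
#' standard error of the estimate s_y.x.
#'
#' @param time_h numeric vector of observation times (hours), increasing.
#' @param mass_pg numeric vector of masses (pg), same length.
#' @param params a [track_filter_params()].
#' @return A list with `accepted` (logical); when accepted: `growth_rate_pg_h`,
#'   `initial_mass_pg`, `sgr_h`, `see`, `n_frames`; when rejected: `reason`.
#' @export
compute_sgr <- function(time_h, mass_pg, params = track_filter_params()) {
  stopifnot(length(time_h) == length(mass_pg))
  if (is.unsorted(time_h, strictly = TRUE)) stop("track times must be strictly increasing")
  n <- length(time_h)
  if (n < params$min_frames)
    return(list(accepted = FALSE, reason = "too_few_frames", n_frames = n))
  m <- median_filter_series(mass_pg, params$median_kernel)
  if (mean(m) < params$min_mean_mass_pg)
    return(list(accepted = FALSE, reason = "low_mass", n_frames = n))
  t0 <- time_h - time_h[1]
  fit <- stats::lm.fit(cbind(1, t0), m)
  b0 <- fit$coefficients[1]; b1 <- fit$coefficients[2]
  if (!is.finite(b0) || b0 <= 0)
    return(list(accepted = FALSE, reason = "nonpositive_intercept", n_frames = n))
  see <- sqrt(sum(fit$residuals^2) / (n - 2))
  list(accepted = TRUE,
       growth_rate_pg_h = unname(b1),
       initial_mass_pg = unname(b0),
       sgr_h = unname(b1 / b0),
       see = see,
       n_frames = n)
}

#' SGR records for a table of tracks
#'
#' Applies [compute_sgr()] to each track in a long-format table and, when
#' requested, removes population outliers with [remove_outlier_records()].
#'
#' @param tracks data.frame with columns `track_id`, `time_h`, `mass_pg`
#'   (additional grouping columns such as `well` are carried through).
#' @param params a [track_filter_params()].
#' @param remove_outliers apply the 3-MAD population filter. The filter is
#'   applied within each condition (drug x concentration when present,
#'   otherwise per well, otherwise globally), since growth-rate populations
#'   are only comparable within a condition.
#' @return A data.frame with one row per track: track_id, accepted, reason,
#'   sgr_h, growth_rate_pg_h, initial_mass_pg, see, n_frames (plus carried
#'   grouping columns).
#' @export
sgr_table <- function(tracks, params = track_filter_params(),
                      remove_outliers = TRUE) {
  carry <- intersect(c("well", "location_id", "condition", "drug",
                       "concentration_uM"), names(tracks))
  recs <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$time_h), , drop = FALSE]
    r <- compute_sgr(tr$time_h, tr$mass_pg, params)
    out <- data.frame(track_id = tr$track_id[1],
                      accepted = r$accepted,
                      reason = if (r$accepted) "" else r$reason,
                      sgr_h = if (r$accepted) r$sgr_h else NA_real_,
                      growth_rate_pg_h = if (r$accepted) r$growth_rate_pg_h else NA_real_,
                      initial_mass_pg = if (r$accepted) r$initial_mass_pg else NA_real_,
                      see = if (r$accepted) r$see else NA_real_,
                      n_frames = r$n_frames)
    for (cc in carry) out[[cc]] <- tr[[cc]][1]
    out
  })
  res <- do.call(rbind, recs)
  rownames(res) <- NULL
  if (remove_outliers) {
    acc <- res[res$accepted, , drop = FALSE]
    grp <- if (all(c("drug", "concentration_uM") %in% names(acc))) {
      interaction(acc$drug, acc$concentration_uM, drop = TRUE)
    } else if ("well" %in% names(acc)) {
      factor(acc$well)
    } else factor(rep(1L, nrow(acc)))
    out_ids <- unlist(lapply(split(acc, grp), function(g) {
      if (nrow(g) < 3) return(character())
      setdiff(g$track_id, remove_outlier_records(g, params)$track_id)
    }))
    res$accepted[res$track_id %in% out_ids] <- FALSE
    res$reason[res$track_id %in% out_ids] <- "mad_outlier"
  }
  res
}

#' Remove population outliers from SGR records
#'
#' A record is an outlier when its SGR (k) or its standard error of the
#' estimate (s_y.x) deviates from the respective median by more than
#' `mad_multiplier` median absolute deviations. The MAD carries the usual
#' 1.4826 consistency factor (the Matlab/R convention, under which 3 MAD
#' corresponds to 3 sigma for normal data). The two flags are combined as a
#' union, and the rule is applied once, not iterated. With fewer than 3
#' records the input is returned unchanged with a warning. When the MAD
#' degenerates to 0 (all values at the median), identical values are
#' retained and genuinely deviating values removed; a small numerical floor
#' keeps floating-point jitter from being flagged.
#'
#' @param records data.frame with columns `sgr_h` and `see`.
#' @param params a [track_filter_params()].
#' @return The filtered data.frame.
#' @export
remove_outlier_records <- function(records, params = track_filter_params()) {
  if (nrow(records) < 3) {
    warning("fewer than 3 records; outlier filter not applied")
    return(records)
  }
  flag <- function(x) {
    med <- stats::median(x)
    eps <- 1e-9 * max(1, abs(med))
    abs(x - med) > params$mad_multiplier * stats::mad(x, center = med) + eps
  }
  out <- flag(records$sgr_h) | flag(records$see)
  records[!out, , drop = FALSE]
}

#' Time-resolved SGR from overlapping 24-hour windows
#'
#' Breaks each track into overlapping 24 h intervals centred on each imaging
#' time point. With frames every `frame_interval_min` minutes over
#' `duration_h` hours there are N = duration / interval frames (at t = 0,
#' ..., (N-1) dt); a window is kept only when fully contained in the
#' acquisition, giving N - window_frames centres (144 for a 72 h experiment
#' at 20 min spacing), which are then grouped 8 adjacent intervals per bin
#' (18 bins). Within each interval the minimum-length and minimum-mass
#' filters are reapplied, per-track SGR is computed by time-shifted
#' regression normalized by that regression's intercept, and the 3-MAD
#' goodness-of-fit rule is applied to s_y.x within the interval.
#'
#' @param tracks data.frame with columns `track_id`, `time_h`, `mass_pg`.
#' @param duration_h experiment duration in hours (>= window_h).
#' @param frame_interval_min imaging period in minutes.
#' @param window_h sliding-window width in hours (24).
#' @param intervals_per_bin adjacent intervals grouped per bin (8).
#' @param params a [track_filter_params()]; the minimum frame count is
#'   applied within each window.
#' @return A list with `interval_centers_h`, `n_intervals`, `n_bins`,
#'   `records` (data.frame: interval, center_h, bin, track_id, sgr_h, see)
#'   and `bin_summary` (data.frame: bin, center_h, n_tracks, mean_sgr_h,
#'   sd_sgr_h), plus `bin_density` (list of per-bin kernel density
#'   estimates).
#' @export
sliding_window_sgr <- function(tracks, duration_h = 72,
                               frame_interval_min = 20, window_h = 24,
                               intervals_per_bin = 8,
                               params = track_filter_params()) {
  dt <- frame_interval_min / 60
  if (duration_h < window_h) stop("experiment shorter than the sliding window")
  n_frames <- round(duration_h / dt)
  half <- round(window_h / 2 / dt)            # frames per half-window
  centers_idx <- half:(n_frames - 1 - half)   # fully contained centres
  centers_h <- centers_idx * dt
  n_int <- length(centers_idx)
  n_bins <- as.integer(n_int %/% intervals_per_bin)

  by_track <- split(tracks[order(tracks$time_h), c("time_h", "mass_pg")],
                    tracks$track_id[order(tracks$time_h)])
  recs <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    lo <- centers_h[i] - window_h / 2 - dt / 4
    hi <- centers_h[i] + window_h / 2 + dt / 4
    rows <- lapply(names(by_track), function(id) {
      tr <- by_track[[id]]
      sel <- tr$time_h >= lo & tr$time_h <= hi
      if (sum(sel) < params$min_frames) return(NULL)
      r <- compute_sgr(tr$time_h[sel], tr$mass_pg[sel], params)
      if (!r$accepted) return(NULL)
      data.frame(interval = i, center_h = centers_h[i], track_id = id,
                 sgr_h = r$sgr_h, see = r$see)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows) && nrow(rows) >= 3) {
      med <- stats::median(rows$see)
      mad_raw <- stats::median(abs(rows$see - med))
      rows <- rows[abs(rows$see - med) <= params$mad_multiplier * mad_raw, ,
                   drop = FALSE]
    }
    recs[[i]] <- rows
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(interval = integer(), center_h = numeric(),
                          track_id = character(), sgr_h = numeric(),
                          see = numeric())
  records$bin <- pmin((records$interval - 1) %/% intervals_per_bin + 1, n_bins)

  bin_summary <- NULL
  bin_density <- list()
  if (nrow(records)) {
    # each bin is summarized by the mean SGR of each cell in the bin
    per_cell <- stats::aggregate(sgr_h ~ bin + track_id, records, mean)
    bs <- lapply(split(per_cell, per_cell$bin), function(g) {
      data.frame(bin = g$bin[1],
                 center_h = mean(records$center_h[records$bin == g$bin[1]]),
                 n_tracks = nrow(g),
                 mean_sgr_h = mean(g$sgr_h),
                 sd_sgr_h = stats::sd(g$sgr_h))
    })
    bin_summary <- do.call(rbind, bs)
    rownames(bin_summary) <- NULL
    bin_density <- lapply(split(per_cell, per_cell$bin), function(g) {
      if (nrow(g) >= 2) stats::density(g$sgr_h, bw = "nrd0") else NULL
    })
  }
  list(interval_centers_h = centers_h, n_intervals = n_int, n_bins = n_bins,
       records = records, bin_summary = bin_summary, bin_density = bin_density)
}

#' Normalized total-mass curve per condition
#'
#' For each imaging location, the total image mass over time is median
#' filtered and divided by its initial value; the condition curve is the mean
#' over all locations in all replicate wells, and the spread is the standard
#' deviation across the per-well mean curves.
#'
#' @param location_mass data.frame with columns `well`, `location_id`,
#'   `time_h`, `total_mass_pg`; all locations must share the time grid.
#' @param median_kernel odd kernel for the temporal median filter.
#' @return A data.frame with columns time_h, mean_normalized_mass,
#'   sd_across_wells, n_locations.
#' @export
normalized_mass_curve <- function(location_mass, median_kernel = 5) {
  key <- interaction(location_mass$well, location_mass$location_id, drop = TRUE)
  per_loc <- lapply(split(location_mass, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    m <- median_filter_series(g$total_mass_pg, median_kernel)
    if (m[1] == 0) stop("zero initial mass at a location")
    data.frame(well = g$well[1], time_h = g$time_h, norm = m / m[1])
  })
  all_loc <- do.call(rbind, per_loc)
  times <- sort(unique(all_loc$time_h))
  mean_curve <- tapply(all_loc$norm, all_loc$time_h, mean)
  per_well <- stats::aggregate(norm ~ well + time_h, all_loc, mean)
  sd_curve <- tapply(per_well$norm, per_well$time_h, stats::sd)
  data.frame(time_h = times,
             mean_normalized_mass = as.numeric(mean_curve[as.character(times)]),
             sd_across_wells = as.numeric(sd_curve[as.character(times)]),
             n_locations = length(per_loc))
}
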