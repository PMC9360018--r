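#' Specification of a synthetic cell population
#'
#' Describes the study conditions emulated by the track generator: a 72 h
#' experiment imaged every 20 min, single-cell SGR drawn from a normal
#' distribution, lognormal initial masses, an optional dying subpopulation
#' that switches to exponential mass loss (default rate -0.217 1/h, the
#' abrupt mass-loss rate seen during cell death) at a drawn death time, and
#' multiplicative measurement noise.
#'
#' @param n_cells number of cells/clusters.
#' @param sgr_mean,sgr_sd population mean and SD of single-cell SGR (1/h).
#' @param death_fraction fraction of cells that die during the experiment.
#' @param death_time_range_h range (hours) from which death times are drawn
#'   uniformly.
#' @param death_rate_h SGR during the death phase (1/h, negative).
#' @param frame_interval_min imaging period (minutes).
#' @param duration_h experiment duration (hours).
#' @param initial_mass_meanlog,initial_mass_sdlog lognormal parameters of
#'   the initial mass (pg).
#' @param noise_cv multiplicative mass measurement noise (coefficient of
#'   variation).
#' @param growth_model within-track mass accumulation model: "linear"
#'   (default), m(t) = m0 (1 + SGR t), for which the slope/intercept SGR
#'   estimator is exact; or "exponential", m(t) = m0 exp(SGR t), under which
#'   the linear-regression estimator carries a known upward bias of order
#'   SGR * track length (see the methods vignette). The death phase is
#'   always exponential decay.
#' @param seed integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 200, sgr_mean = 0.02, sgr_sd = 0.008,
                            death_fraction = 0, death_time_range_h = c(10, 50),
                            death_rate_h = -0.217,
                            frame_interval_min = 20, duration_h = 72,
                            initial_mass_meanlog = log(350),
                            initial_mass_sdlog = 0.35,
                            noise_cv = 0.02,
                            growth_model = c("linear", "exponential"),
                            seed = 1L) {
  growth_model <- match.arg(growth_model)
  stopifnot(n_cells >= 1, death_fraction >= 0, death_fraction <= 1,
            duration_h > 0, frame_interval_min > 0, noise_cv >= 0)
  structure(as.list(environment()), class = "population_spec")
}

#' Generate synthetic mass-versus-time tracks
#'
#' Each cell accumulates mass at its drawn SGR under the configured growth
#' model (linear by default, exponential optionally); dying cells switch to
#' exponential decay at `death_rate_h` at their drawn death time.
#' Multiplicative Gaussian measurement noise is applied per observation.
#' Deterministic per seed. Frames are at t = 0, dt, ..., (N-1) dt with
#' N = duration / dt.
#'
#' @param spec a [population_spec()].
#' @param well,location_id identifiers attached to every row.
#' @return A long-format data.frame: track_id, well, location_id, frame,
#'   time_h, mass_pg, true_sgr_h, dies.
#' @export
generate_cell_tracks <- function(spec, well = "A1", location_id = "L1") {
  set.seed(spec$seed)
  dt <- spec$frame_interval_min / 60
  n_frames <- round(spec$duration_h / dt)
  t <- (seq_len(n_frames) - 1) * dt
  sgr <- stats::rnorm(spec$n_cells, spec$sgr_mean, spec$sgr_sd)
  m0 <- stats::rlnorm(spec$n_cells, spec$initial_mass_meanlog,
                      spec$initial_mass_sdlog)
  dies <- stats::runif(spec$n_cells) < spec$death_fraction
  t_death <- stats::runif(spec$n_cells, spec$death_time_range_h[1],
                          spec$death_time_range_h[2])
  grow <- function(m0i, g, tt) {
    if (spec$growth_model == "linear") m0i * (1 + g * tt)
    else m0i * exp(g * tt)
  }
  rows <- lapply(seq_len(spec$n_cells), function(i) {
    m <- grow(m0[i], sgr[i], t)
    if (dies[i]) {
      after <- t > t_death[i]
      if (any(after)) {
        m_at <- grow(m0[i], sgr[i], t_death[i])
        m[after] <- m_at * exp(spec$death_rate_h * (t[after] - t_death[i]))
      }
    }
    m <- pmax(m, 0)
    if (spec$noise_cv > 0)
      m <- m * (1 + spec$noise_cv * stats::rnorm(n_frames))
    data.frame(track_id = sprintf("%s_%s_c%04d", well, location_id, i),
               well = well, location_id = location_id,
               frame = seq_len(n_frames) - 1L, time_h = t, mass_pg = m,
               true_sgr_h = sgr[i],
               dies = dies[i])
  })
  do.call(rbind, rows)
}

#' 96-well plate layout for a 6-point dose-response screen
#'
#' Builds the standard screen layout: up to five drugs at six concentrations
#' in triplicate wells, plus triplicate solvent-control wells (DMSO and
#' optionally ethanol), with a fixed number of imaging locations per well.
#'
#' @param drugs character vector of drug names (max 5).
#' @param concentrations_uM six concentrations shared by all drugs, or a
#'   named list per drug.
#' @param solvents solvent controls to include.
#' @param n_replicates wells per condition.
#' @param locations_per_well imaging locations per well (9).
#' @param cell_line label carried through.
#' @return A data.frame of class `plate_layout`: well, drug,
#'   concentration_uM (NA for controls), solvent, cell_line, replicate.
#' @export
plate_layout <- function(drugs = paste0("drug", 1:5),
                         concentrations_uM = c(0.0064, 0.032, 0.16, 0.8, 4, 20),
                         solvents = c("DMSO", "ethanol"),
                         n_replicates = 3, locations_per_well = 9,
                         cell_line = "cellline") {
  if (length(drugs) > 5) stop("layout supports at most five drugs")
  if (!is.list(concentrations_uM))
    concentrations_uM <- stats::setNames(
      rep(list(concentrations_uM), length(drugs)), drugs)
  rows <- list()
  wells <- outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)
  wi <- 1L
  for (d in drugs) for (conc in concentrations_uM[[d]]) for (r in seq_len(n_replicates)) {
    rows[[length(rows) + 1]] <- data.frame(
      well = wells[wi], drug = d, concentration_uM = conc,
      solvent = "DMSO", cell_line = cell_line, replicate = r)
    wi <- wi + 1L
  }
  for (s in solvents) for (r in seq_len(n_replicates)) {
    rows[[length(rows) + 1]] <- data.frame(
      well = wells[wi], drug = paste0(s, "_control"),
      concentration_uM = NA_real_, solvent = s, cell_line = cell_line,
      replicate = r)
    wi <- wi + 1L
  }
  out <- do.call(rbind, rows)
  attr(out, "locations_per_well") <- locations_per_well
  class(out) <- c("plate_layout", class(out))
  out
}

#' Enumerate imaging locations of a plate
#'
#' @param layout a [plate_layout()]; with the default 96-well, 9-location
#'   design this enumerates 864 locations, 27 per triplicate condition.
#' @return A data.frame with one row per (well, location).
#' @export
enumerate_locations <- function(layout) {
  lpw <- attr(layout, "locations_per_well")
  out <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    data.frame(well = layout$well[i], drug = layout$drug[i],
               concentration_uM = layout$concentration_uM[i],
               replicate = layout$replicate[i],
               location_id = sprintf("%s_loc%d", layout$well[i],
                                     seq_len(lpw)))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write a plate layout as YAML
#'
#' @param layout a [plate_layout()].
#' @param path YAML file path.
#' @export
write_plate_layout <- function(layout, path) {
  wells <- lapply(seq_len(nrow(layout)), function(i) {
    list(drug = layout$drug[i],
         concentration_uM = if (is.na(layout$concentration_uM[i])) NULL
                            else layout$concentration_uM[i],
         solvent = layout$solvent[i], cell_line = layout$cell_line[i],
         replicate = layout$replicate[i])
  })
  names(wells) <- layout$well
  yaml::write_yaml(list(locations_per_well = attr(layout, "locations_per_well"),
                        wells = wells), path)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(names(y$wells), function(w) {
    e <- y$wells[[w]]
    data.frame(well = w, drug = e$drug,
               concentration_uM = if (is.null(e$concentration_uM)) NA_real_
                                  else e$concentration_uM,
               solvent = e$solvent, cell_line = e$cell_line,
               replicate = e$replicate)
  })
  out <- do.call(rbind, rows)
  attr(out, "locations_per_well") <- y$locations_per_well
  class(out) <- c("plate_layout", class(out))
  out
}

#' Serial-dilution concentrations from a stock
#'
#' Documents the screen's dilution arithmetic: a stock is aliquoted to twice
#' the top assay concentration and serially diluted 1:1 with drugged media,
#' then halved again when added to cells.
#'
#' @param top_uM highest final assay concentration.
#' @param n_points number of dose points.
#' @return Final assay concentrations, highest first.
#' @export
serial_dilution <- function(top_uM = 20, n_points = 6) {
  top_uM / 2^(seq_len(n_points) - 1)
}

#' Generate dose-response-structured tracks
#'
#' Per-condition mean SGR follows a ground-truth Hill curve; single-cell SGR
#' scatters around it with a (optionally concentration-dependent) SD.
#' Enables end-to-end EC50 / DoR / ToR recovery tests against known truth.
#'
#' @param hill list with E0, Emax, EC50_uM, HS (truth).
#' @param layout a [plate_layout()] (only wells of `drug` are simulated,
#'   plus the solvent controls).
#' @param drug drug name within the layout.
#' @param n_cells_per_location cells per imaging location.
#' @param sgr_sd per-cell SGR standard deviation (1/h); scalar or function
#'   of concentration.
#' @param noise_cv mass measurement noise.
#' @param seed integer seed.
#' @param locations_per_well imaging locations simulated per well (defaults
#'   to the layout's).
#' @param duration_h,frame_interval_min acquisition grid.
#' @return A long-format tracks data.frame with columns as in
#'   [generate_cell_tracks()] plus drug and concentration_uM.
#' @export
generate_dose_response_tracks <- function(hill, layout, drug,
                                          n_cells_per_location = 15,
                                          sgr_sd = 0.008, noise_cv = 0.02,
                                          seed = 1L,
                                          locations_per_well = NULL,
                                          duration_h = 72,
                                          frame_interval_min = 20) {
  if (is.null(locations_per_well))
    locations_per_well <- attr(layout, "locations_per_well")
  sel <- layout[layout$drug == drug | is.na(layout$concentration_uM), ,
                drop = FALSE]
  sd_fun <- if (is.function(sgr_sd)) sgr_sd else function(conc) sgr_sd
  out <- list()
  for (i in seq_len(nrow(sel))) {
    conc <- sel$concentration_uM[i]
    mu <- if (is.na(conc)) hill$E0
          else hill_curve(conc, hill$E0, hill$Emax, hill$EC50_uM, hill$HS)
    for (loc in seq_len(locations_per_well)) {
      spec <- population_spec(
        n_cells = n_cells_per_location, sgr_mean = mu,
        sgr_sd = sd_fun(conc), noise_cv = noise_cv,
        duration_h = duration_h, frame_interval_min = frame_interval_min,
        seed = (seed + 131L * i + 7L * loc) %% .Machine$integer.max)
      tr <- generate_cell_tracks(spec, well = sel$well[i],
                                 location_id = sprintf("%s_loc%d",
                                                       sel$well[i], loc))
      tr$drug <- sel$drug[i]
      tr$concentration_uM <- conc
      out[[length(out) + 1]] <- tr
    }
  }
  do.call(rbind, out)
}
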