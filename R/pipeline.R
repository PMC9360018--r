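#' Run the track-to-parameters analysis pipeline
#'
#' Entry point at the tracks stage: takes a long-format track table (as
#' produced by the imaging stages or by the synthetic generators) plus a
#' plate layout, and computes, per drug: per-track SGR records with full
#' filter bookkeeping, the condition-averaged dose-response Hill fit with
#' F-test response call and depth of response, the heterogeneity (SD) dose
#' response, Hellinger-distance dynamics against the solvent control with
#' the control-derived threshold and time of response per concentration,
#' and the SD at EC50.
#'
#' Condition averages are means over per-location mean SGRs (the 27
#' locations of a triplicate condition), with SEM across locations.
#'
#' @param tracks data.frame with columns track_id, well, location_id,
#'   time_h, mass_pg (drug/concentration_uM merged from the layout when
#'   absent).
#' @param layout a [plate_layout()] covering the wells present.
#' @param params a [track_filter_params()].
#' @param alpha F-test significance level for the response call.
#' @param duration_h,frame_interval_min acquisition grid for the temporal
#'   analysis.
#' @param temporal compute the sliding-window / Hellinger / ToR stage
#'   (slower); otherwise EC50/DoR/SD only.
#' @param out_dir optional directory to write per-stage CSV outputs.
#' @return A list of class `qpi_results`: sgr_records, filter_counts,
#'   dose_response (per drug), tor (per drug x concentration), and
#'   heterogeneity.
#' @export
run_pipeline <- function(tracks, layout, params = track_filter_params(),
                         alpha = 0.01, duration_h = 72,
                         frame_interval_min = 20, temporal = TRUE,
                         out_dir = NULL) {
  need <- c("track_id", "well", "time_h", "mass_pg")
  if (!all(need %in% names(tracks)))
    stop("tracks table missing columns: ",
         paste(setdiff(need, names(tracks)), collapse = ", "))
  if (!all(c("drug", "concentration_uM") %in% names(tracks))) {
    tracks <- merge(tracks,
                    layout[, c("well", "drug", "concentration_uM")],
                    by = "well", sort = FALSE)
  }

  recs <- sgr_table(tracks, params)
  filter_counts <- c(table(factor(ifelse(recs$accepted, "accepted",
                                         recs$reason))))

  acc <- recs[recs$accepted, , drop = FALSE]
  control_drugs <- unique(layout$drug[is.na(layout$concentration_uM)])
  drugs <- setdiff(unique(acc$drug), control_drugs)

  per_loc_mean <- function(df) {
    g <- stats::aggregate(sgr_h ~ location_id, df, mean)
    g$sgr_h
  }

  dose_response <- list()
  heterogeneity <- list()
  for (d in drugs) {
    dd <- acc[acc$drug == d, , drop = FALSE]
    ctrl <- acc[acc$drug %in% control_drugs, , drop = FALSE]
    conds <- sort(unique(dd$concentration_uM))
    mk_row <- function(df) {
      lm <- per_loc_mean(df)
      c(mean = mean(lm), sem = stats::sd(lm) / sqrt(length(lm)),
        sd_cells = stats::sd(df$sgr_h), n = nrow(df))
    }
    rows <- rbind(mk_row(ctrl), t(vapply(conds, function(cc)
      mk_row(dd[dd$concentration_uM == cc, ]), numeric(4))))
    drd <- dose_response_data(c(NA, conds), rows[, "mean"],
                              sem = rows[, "sem"], n = rows[, "n"])
    hf <- fit_hill(drd)
    call <- f_test_response(drd, hf, alpha = alpha)
    sd_drd <- dose_response_data(c(NA, conds), rows[, "sd_cells"])
    sd_fit <- tryCatch(fit_heterogeneity_ec50(sd_drd), error = function(e) NULL)
    sd_ec <- sd_at_ec50(
      data.frame(concentration_uM = dd$concentration_uM, sgr_h = dd$sgr_h),
      if (call$responded) hf$EC50_uM else NA_real_)
    dose_response[[d]] <- list(drug = d, data = drd, hill = hf,
                               call = call, sd_fit = sd_fit)
    heterogeneity[[d]] <- list(drug = d, sd_at_ec50 = sd_ec,
                               sd_dose_response = sd_drd)
  }

  tor <- NULL
  if (temporal && length(control_drugs) >= 1) {
    tor <- run_tor_stage(tracks, recs, control_drugs, drugs, dose_response,
                         params, duration_h, frame_interval_min)
  }

  res <- structure(list(sgr_records = recs, filter_counts = filter_counts,
                        dose_response = dose_response, tor = tor,
                        heterogeneity = heterogeneity),
                   class = "qpi_results")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

# Hellinger/ToR stage: sliding-window SGR distributions per condition vs the
# first solvent control, thresholded by the control-vs-control distance.
run_tor_stage <- function(tracks, recs, control_drugs, drugs, dose_response,
                          params, duration_h, frame_interval_min) {
  win <- function(sub) sliding_window_sgr(sub, duration_h, frame_interval_min,
                                          params = params)
  ctrl_wells <- split(unique(tracks$well[tracks$drug %in% control_drugs]),
                      tracks$drug[match(
                        unique(tracks$well[tracks$drug %in% control_drugs]),
                        tracks$well)])
  ctrl_names <- names(ctrl_wells)
  ref <- win(tracks[tracks$drug == ctrl_names[1], ])
  bins_of <- function(w) {
    lapply(seq_len(w$n_bins), function(b) {
      pc <- w$records[w$records$bin == b, ]
      tapply(pc$sgr_h, pc$track_id, mean)
    })
  }
  bin_centers <- vapply(seq_len(ref$n_bins), function(b)
    mean(ref$interval_centers_h[unique(ref$records$interval[
      ref$records$bin == b])]), numeric(1))
  ref_bins <- bins_of(ref)

  threshold <- NA_real_
  if (length(ctrl_names) >= 2) {
    other <- bins_of(win(tracks[tracks$drug == ctrl_names[2], ]))
    hs <- hellinger_series(other, ref_bins, bin_centers,
                           label = "control_vs_control")
    threshold <- hellinger_threshold(hs)
  }

  rows <- list()
  for (d in drugs) {
    conds <- sort(unique(tracks$concentration_uM[tracks$drug == d]))
    conds <- conds[!is.na(conds)]
    for (cc in conds) {
      w <- win(tracks[tracks$drug == d & tracks$concentration_uM == cc, ])
      hs <- hellinger_series(bins_of(w), ref_bins, bin_centers,
                             label = sprintf("%s_%g", d, cc))
      fit <- fit_tor_model(hs)
      tr <- if (is.na(threshold)) list(status = "no_threshold",
                                       tor_h = NA_real_)
            else compute_tor(fit, threshold, duration_h)
      rows[[length(rows) + 1]] <- data.frame(
        drug = d, concentration_uM = cc, a = fit$a, b = fit$b, c = fit$c,
        threshold = threshold, tor_h = tr$tor_h, status = tr$status)
    }
  }
  tor_tab <- do.call(rbind, rows)
  tor_at <- lapply(drugs, function(d) {
    hf <- dose_response[[d]]$hill
    if (!dose_response[[d]]$call$responded)
      return(data.frame(drug = d, concentration_uM = NA_real_,
                        tor_h = NA_real_))
    ta <- tor_at_ec50(tor_tab[tor_tab$drug == d, ], hf$EC50_uM)
    data.frame(drug = d, concentration_uM = ta$concentration_uM,
               tor_h = ta$tor_h)
  })
  list(table = tor_tab, threshold = threshold,
       tor_at_ec50 = do.call(rbind, tor_at))
}

#' Write pipeline results as CSV files
#'
#' @param res a `qpi_results` object from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$sgr_records, file.path(out_dir, "sgr.csv"),
                   row.names = FALSE)
  dr <- do.call(rbind, lapply(res$dose_response, function(e)
    data.frame(drug = e$drug, E0 = e$hill$E0, Emax = e$hill$Emax,
               EC50_uM = e$hill$EC50_uM, HS = e$hill$HS,
               p_value = e$call$p_value, responded = e$call$responded,
               DoR = e$call$dor, cytotoxic = e$call$cytotoxic)))
  utils::write.csv(dr, file.path(out_dir, "dose_response.csv"),
                   row.names = FALSE)
  if (!is.null(res$tor))
    utils::write.csv(res$tor$table, file.path(out_dir, "tor.csv"),
                     row.names = FALSE)
  counts <- data.frame(reason = names(res$filter_counts),
                       n = as.integer(res$filter_counts))
  utils::write.csv(counts, file.path(out_dir, "filter_counts.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.qpi_results <- function(x, ...) {
  cat("QPI screening results\n")
  cat("  tracks: ", sum(x$filter_counts), " (",
      paste(sprintf("%s=%d", names(x$filter_counts), x$filter_counts),
            collapse = ", "), ")\n", sep = "")
  for (e in x$dose_response) {
    cat(sprintf("  %s: EC50 = %.3g uM, DoR = %.3g, responded = %s\n",
                e$drug, e$hill$EC50_uM,
                if (is.na(e$call$dor)) NA else e$call$dor,
                e$call$responded))
  }
  invisible(x)
}
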