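#' Standard deviation of response at the EC50
#'
#' Heterogeneity measure: the standard deviation of single-cell SGR at the
#' tested concentration nearest the EC50 in log-concentration distance.
#'
#' @param sgr_by_condition data.frame with columns `concentration_uM` and
#'   `sgr_h` (one row per accepted cell record).
#' @param ec50_uM the fitted EC50; when NA (no response call) the control /
#'   lowest concentration is used.
#' @return A list with `concentration_uM` (condition selected) and `sd_h`.
#' @export
sd_at_ec50 <- function(sgr_by_condition, ec50_uM) {
  conc <- sort(unique(sgr_by_condition$concentration_uM))
  if (!length(conc)) stop("no conditions supplied")
  target <- if (is.finite(ec50_uM)) {
    conc[which.min(abs(log10(conc) - log10(ec50_uM)))]
  } else conc[1]
  vals <- sgr_by_condition$sgr_h[sgr_by_condition$concentration_uM == target]
  list(concentration_uM = target, sd_h = stats::sd(vals))
}

#' Design of the in-silico resistant-cell mixing analysis
#'
#' @param mixing_ratios fractions of resistant (control) cells mixed into
#'   the treated population.
#' @param threshold_grid SGR thresholds (1/h) at which resistance is called.
#' @param n_repeats seeded repeats per ratio.
#' @param seed base seed.
#' @return An object of class `mixing_design`.
#' @export
mixing_design <- function(mixing_ratios = c(0.5, 0.25, 0.1, 0.05, 0.02,
                                            0.01, 0.001, 1e-4),
                          threshold_grid = seq(-0.1, 0.15, by = 0.005),
                          n_repeats = 100, seed = 1L) {
  stopifnot(all(mixing_ratios > 0 & mixing_ratios < 1),
            !is.unsorted(threshold_grid), n_repeats >= 1)
  structure(list(mixing_ratios = mixing_ratios,
                 threshold_grid = threshold_grid,
                 n_repeats = n_repeats, seed = seed),
            class = "mixing_design")
}

#' Simulate a resistant/sensitive cell mixture
#'
#' Pools all treated cells (negatives) with control cells sampled into the
#' pool as positives ("resistant") so that positives / total = `ratio`. The
#' number of controls added is round(ratio * n_treated / (1 - ratio)), at
#' least 1. Controls are sampled without replacement when the pool allows,
#' otherwise with replacement and a warning. Deterministic per seed.
#'
#' @param control_sgr numeric SGR values of the control (resistant) pool.
#' @param treated_sgr numeric SGR values of the treated population.
#' @param ratio target fraction of resistant cells in the pool, in (0, 1).
#' @param seed integer seed.
#' @return A data.frame with columns `sgr_h` and `resistant` (logical).
#' @export
simulate_mixture <- function(control_sgr, treated_sgr, ratio, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  if (!length(control_sgr) || !length(treated_sgr)) stop("empty pools")
  n_pos <- max(1L, round(ratio * length(treated_sgr) / (1 - ratio)))
  set.seed(seed)
  if (n_pos > length(control_sgr)) {
    warning("control pool smaller than requested; sampling with replacement")
    picked <- sample(control_sgr, n_pos, replace = TRUE)
  } else {
    picked <- sample(control_sgr, n_pos, replace = FALSE)
  }
  data.frame(sgr_h = c(treated_sgr, picked),
             resistant = c(rep(FALSE, length(treated_sgr)),
                           rep(TRUE, n_pos)))
}

#' Precision-recall curve for resistant-cell detection
#'
#' At each threshold theta, cells with SGR strictly above theta are
#' predicted resistant; precision = TP / (TP + FP) and recall =
#' TP / (TP + FN). When a threshold yields no predictions, precision is 1
#' by convention (no false positives). The area under the curve is the
#' trapezoid over recall after sorting, the no-skill baseline equals the
#' positive prevalence, and the normalized AUPRC is
#' (AUPRC - prevalence) / (1 - prevalence), mapping a no-skill classifier
#' to 0 and a perfect one to 1.
#'
#' @param pool data.frame from [simulate_mixture()] (columns `sgr_h`,
#'   `resistant`).
#' @param threshold_grid SGR thresholds (1/h).
#' @return A list of class `pr_result`: thresholds, precision, recall,
#'   auprc, no_skill, normalized_auprc.
#' @export
precision_recall_curve <- function(pool,
                                   threshold_grid = seq(-0.1, 0.15, 0.005)) {
  y <- pool$resistant
  if (all(y) || !any(y)) stop("pool contains a single class")
  n_pos <- sum(y)
  prevalence <- n_pos / length(y)
  prec <- rec <- numeric(length(threshold_grid))
  for (i in seq_along(threshold_grid)) {
    pred <- pool$sgr_h > threshold_grid[i]
    tp <- sum(pred & y)
    prec[i] <- if (any(pred)) tp / sum(pred) else 1
    rec[i] <- tp / n_pos
  }
  # integrate along the threshold sweep (recall non-decreasing as the
  # threshold drops), anchoring the high-threshold end at zero recall
  ord <- order(threshold_grid, decreasing = TRUE)
  r <- rec[ord]; p <- prec[ord]
  if (r[1] > 0) { r <- c(0, r); p <- c(p[1], p) }
  auprc <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  structure(list(thresholds = threshold_grid, precision = prec,
                 recall = rec, auprc = auprc, no_skill = prevalence,
                 normalized_auprc = (auprc - prevalence) / (1 - prevalence)),
            class = "pr_result")
}

#' Repeated in-silico mixing with median AUPRC per ratio
#'
#' For each mixing ratio, repeats the seeded mixture `n_repeats` times,
#' scores each repeat with [precision_recall_curve()], and reports the
#' median normalized AUPRC together with the precision/recall curve of the
#' median-AUPRC repeat.
#'
#' @param control_sgr,treated_sgr SGR pools as in [simulate_mixture()].
#' @param design a [mixing_design()].
#' @return A list with `per_ratio` (data.frame: ratio, median_auprc,
#'   median_normalized_auprc), `repeats` (data.frame of every repeat), and
#'   `median_curves` (list of `pr_result` for the median repeat per ratio).
#' @export
replicate_mixing <- function(control_sgr, treated_sgr,
                             design = mixing_design()) {
  reps <- list(); curves <- list()
  for (ratio in design$mixing_ratios) {
    rs <- lapply(seq_len(design$n_repeats), function(r) {
      seed_r <- (design$seed + 7919L * r + round(1e6 * ratio)) %% .Machine$integer.max
      pool <- simulate_mixture(control_sgr, treated_sgr, ratio, seed = seed_r)
      pr <- precision_recall_curve(pool, design$threshold_grid)
      list(pr = pr,
           row = data.frame(ratio = ratio, repeat_index = r,
                            auprc = pr$auprc,
                            normalized_auprc = pr$normalized_auprc))
    })
    tab <- do.call(rbind, lapply(rs, `[[`, "row"))
    med_idx <- order(tab$auprc)[ceiling(nrow(tab) / 2)]
    tab$is_median <- seq_len(nrow(tab)) == med_idx
    reps[[length(reps) + 1]] <- tab
    curves[[as.character(ratio)]] <- rs[[med_idx]]$pr
  }
  repeats <- do.call(rbind, reps)
  per_ratio <- do.call(rbind, lapply(split(repeats, repeats$ratio), function(g)
    data.frame(ratio = g$ratio[1],
               median_auprc = stats::median(g$auprc),
               median_normalized_auprc = stats::median(g$normalized_auprc))))
  per_ratio <- per_ratio[order(-per_ratio$ratio), ]
  rownames(per_ratio) <- NULL
  list(per_ratio = per_ratio, repeats = repeats, median_curves = curves)
}
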