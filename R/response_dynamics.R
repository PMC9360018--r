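#' Discretized SGR distribution
#'
#' Builds a normalized histogram of single-cell SGR values over fixed bins
#' of width `bin_width` (default 1e-4 1/h) spanning `range` (default
#' \[-0.3, 0.3\] 1/h, wide enough to cover death rates near -0.22 1/h).
#' Values outside the range are clipped into the edge bins with a warning.
#'
#' @param sgr_values numeric vector of SGR values (1/h).
#' @param bin_width histogram bin width (1/h).
#' @param range length-2 numeric range covered by the bins.
#' @return An object of class `sgr_distribution`: list with `p`
#'   (probabilities summing to 1), `breaks`, `mids`, `n`.
#' @export
discretize_sgr_distribution <- function(sgr_values, bin_width = 1e-4,
                                        range = c(-0.3, 0.3)) {
  stopifnot(bin_width > 0, length(range) == 2, range[2] > range[1])
  if (!length(sgr_values)) stop("empty SGR sample")
  if (any(sgr_values < range[1] | sgr_values > range[2])) {
    warning("SGR values outside the histogram range clipped into edge bins")
    sgr_values <- pmin(pmax(sgr_values, range[1]), range[2])
  }
  nb <- ceiling((range[2] - range[1]) / bin_width)
  breaks <- range[1] + bin_width * 0:nb
  idx <- pmin(pmax(ceiling((sgr_values - range[1]) / bin_width), 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  sgr_distribution(counts / sum(counts), breaks, n = length(sgr_values))
}

#' @rdname discretize_sgr_distribution
#' @param p bin probabilities (will be checked to sum to 1).
#' @param breaks bin edges, length(p) + 1.
#' @param n sample size behind the distribution (optional).
#' @export
sgr_distribution <- function(p, breaks, n = NA_integer_) {
  stopifnot(length(breaks) == length(p) + 1, all(p >= 0))
  if (abs(sum(p) - 1) > 1e-12) stop("probabilities must sum to 1")
  structure(list(p = as.numeric(p), breaks = as.numeric(breaks),
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 n = n),
            class = "sgr_distribution")
}

#' Hellinger distance between two discretized distributions
#'
#' H(S, T) = sqrt( 1/2 * sum_i (sqrt(s_i) - sqrt(t_i))^2 ), symmetric and
#' bounded in \[0, 1\]; 0 for identical distributions, 1 for disjoint
#' support. Both distributions must share the same binning.
#'
#' @param S,T [sgr_distribution()] objects on identical bins.
#' @return The Hellinger distance (dimensionless).
#' @export
hellinger_distance <- function(S, T) {
  stopifnot(inherits(S, "sgr_distribution"), inherits(T, "sgr_distribution"))
  if (length(S$p) != length(T$p) ||
      max(abs(S$breaks - T$breaks)) > 1e-12)
    stop("distributions must share identical binning")
  h2 <- 0.5 * sum((sqrt(S$p) - sqrt(T$p))^2)
  sqrt(min(max(h2, 0), 1))
}

#' Hellinger distance series between two populations over time
#'
#' @param sgr_a,sgr_b lists of numeric SGR vectors, one per time bin (same
#'   length and time grid).
#' @param times_h numeric vector of bin centres (hours).
#' @param bin_width,range histogram parameters passed to
#'   [discretize_sgr_distribution()].
#' @param label comparison label carried on the result.
#' @return A data.frame of class `hellinger_series` with columns `time_h`,
#'   `distance`.
#' @export
hellinger_series <- function(sgr_a, sgr_b, times_h, bin_width = 1e-4,
                             range = c(-0.3, 0.3), label = "") {
  stopifnot(length(sgr_a) == length(sgr_b), length(sgr_a) == length(times_h))
  d <- vapply(seq_along(times_h), function(i) {
    hellinger_distance(
      discretize_sgr_distribution(sgr_a[[i]], bin_width, range),
      discretize_sgr_distribution(sgr_b[[i]], bin_width, range))
  }, numeric(1))
  out <- data.frame(time_h = times_h, distance = d)
  attr(out, "label") <- label
  class(out) <- c("hellinger_series", class(out))
  out
}

#' Response threshold from the control-versus-control distance
#'
#' The time-of-response threshold H* is the maximum over time of the
#' Hellinger distance between the solvent control and the untreated control.
#'
#' @param solvent_vs_untreated a [hellinger_series()] (or data.frame with a
#'   `distance` column) comparing the two control populations.
#' @return The threshold H*.
#' @export
hellinger_threshold <- function(solvent_vs_untreated) {
  if (is.null(solvent_vs_untreated$distance) || !nrow(solvent_vs_untreated))
    stop("missing control comparison series")
  max(solvent_vs_untreated$distance)
}

#' Fit the saturating-exponential time-of-response model
#'
#' Fits H(t) = a - b * exp(c t) to a Hellinger-distance series by nonlinear
#' least squares (initial guesses a = max(H), b = a - H(1), c = -0.05 1/h).
#' For saturating responses b > 0 and c < 0 with plateau a. A constant
#' series yields the degenerate fit (a = mean, b = 0) with `degenerate =
#' TRUE`.
#'
#' @param series a [hellinger_series()] (columns `time_h`, `distance`).
#' @return A list of class `tor_fit`: a, b, c, rss, degenerate, converged.
#' @export
fit_tor_model <- function(series) {
  t <- series$time_h; H <- series$distance
  if (length(t) < 4) stop("need at least 4 time points for the ToR model")
  if (stats::sd(H) < 1e-12) {
    return(structure(list(a = mean(H), b = 0, c = NA_real_, rss = 0,
                          degenerate = TRUE, converged = TRUE),
                     class = "tor_fit"))
  }
  p0 <- c(a = max(H), b = max(H) - H[1], c = -0.05)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0,
                       fn = function(p) H - (p[1] - p[2] * exp(p[3] * t)),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          rss = NA_real_, degenerate = FALSE,
                          converged = FALSE),
                     class = "tor_fit"))
  }
  p <- fit$par
  structure(list(a = unname(p[1]), b = unname(p[2]), c = unname(p[3]),
                 rss = sum(fit$fvec^2), degenerate = FALSE, converged = TRUE),
            class = "tor_fit")
}

#' Time of response by analytic inversion of the saturation model
#'
#' Inverts H(t) = a - b exp(c t) at the threshold H*: t = (1/c) *
#' ln((a - H*) / b). Returns "no response" when the threshold is never
#' crossed within the experiment: plateau at or below the threshold
#' (a <= H*), b <= 0, a failed fit, or an inverted time outside
#' (0, duration\].
#'
#' @param fit a [fit_tor_model()] result.
#' @param threshold the control-derived threshold H*.
#' @param duration_h experiment duration (hours).
#' @return A list with `status` ("response" or "no_response") and `tor_h`
#'   (hours, NA when no response).
#' @export
compute_tor <- function(fit, threshold, duration_h = 72) {
  no <- list(status = "no_response", tor_h = NA_real_)
  if (!isTRUE(fit$converged) || isTRUE(fit$degenerate)) return(no)
  if (!is.finite(fit$c) || fit$b <= 0 || fit$a <= threshold) return(no)
  ratio <- (fit$a - threshold) / fit$b
  if (ratio <= 0) return(no)
  t <- log(ratio) / fit$c
  if (!is.finite(t) || t < 0 || t > duration_h) return(no)
  list(status = "response", tor_h = t)
}

#' ToR at the tested concentration just above the EC50
#'
#' The concentration just below the EC50 often elicits no response, so the
#' ToR at the smallest tested concentration strictly above the EC50 is used
#' as the nearest approximation of the ToR at the EC50 itself. An EC50 above
#' the highest tested concentration leaves the value undefined.
#'
#' @param tor_by_concentration data.frame with columns `concentration_uM`
#'   and `tor_h`.
#' @param ec50_uM the fitted EC50.
#' @return A list with `concentration_uM` and `tor_h` (both NA when
#'   undefined).
#' @export
tor_at_ec50 <- function(tor_by_concentration, ec50_uM) {
  above <- tor_by_concentration$concentration_uM >
    ec50_uM * (1 + 1e-12)
  if (!any(above)) {
    warning("EC50 above the highest tested concentration; ToR at EC50 undefined")
    return(list(concentration_uM = NA_real_, tor_h = NA_real_))
  }
  sel <- which(above)[which.min(tor_by_concentration$concentration_uM[above])]
  list(concentration_uM = tor_by_concentration$concentration_uM[sel],
       tor_h = tor_by_concentration$tor_h[sel])
}
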