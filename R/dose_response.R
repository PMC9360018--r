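#' Assemble a dose-response table from per-condition responses
#'
#' Maps the solvent-control condition to a pseudo-concentration (lowest
#' tested concentration / 100) so all points sit on a log axis, and checks
#' the design supports 4-parameter fitting.
#'
#' @param concentration_uM concentrations in micromolar; use NA (or 0) for
#'   the solvent control.
#' @param response mean response per condition (e.g. mean SGR in 1/h, or the
#'   per-condition SD for heterogeneity fits).
#' @param sem standard error per condition (optional).
#' @param n number of locations/cells per condition (optional).
#' @return A data.frame of class `dose_response_data` with strictly positive
#'   concentrations.
#' @export
dose_response_data <- function(concentration_uM, response, sem = NA_real_,
                               n = NA_integer_) {
  conc <- concentration_uM
  tested <- conc[!is.na(conc) & conc > 0]
  if (length(tested) < 1) stop("no positive tested concentrations")
  pseudo <- min(tested) / 100
  conc[is.na(conc) | conc == 0] <- pseudo
  d <- data.frame(concentration_uM = conc, response = response,
                  sem = sem, n = n)
  if (length(unique(d$concentration_uM)) < 5)
    stop("need >= 5 distinct concentrations for 4-parameter fitting")
  class(d) <- c("dose_response_data", class(d))
  d
}

hill_curve <- function(C, E0, Emax, EC50, HS) {
  Emax + (E0 - Emax) / (1 + (C / EC50)^HS)
}

#' Four-parameter Hill (logistic) dose-response fit
#'
#' Fits response = Emax + (E0 - Emax) / (1 + (C / EC50)^HS) by least squares
#' in log10-concentration space, with a multi-start over EC50 initial
#' guesses spanning the tested range. E0 is the low-concentration asymptote,
#' Emax the high-concentration asymptote, EC50 the inflection point, HS the
#' Hill slope. HS is bounded to \[0.1, 10\] and EC50 to \[min conc / 100,
#' max conc * 100\] for stability.
#'
#' @param data a [dose_response_data()] (or a data.frame with columns
#'   `concentration_uM` and `response`).
#' @return An object of class `hill_fit`: list with E0, Emax, EC50_uM, HS,
#'   rss, dof, fitted, data.
#' @export
fit_hill <- function(data) {
  C <- data$concentration_uM
  y <- data$response
  n <- length(y)
  if (n < 5) stop("need at least 5 points for a 4-parameter fit")
  lC <- log10(C)
  lo_ec <- log10(min(C) / 100); hi_ec <- log10(max(C) * 100)
  model <- function(p, lc) {
    hill_curve(10^lc, p[1], p[2], 10^p[3], p[4])
  }
  starts <- expand.grid(
    lec = seq(min(lC), max(lC), length.out = 7),
    hs = c(0.5, 1, 2))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- c(E0 = y[which.min(lC)], Emax = y[which.max(lC)],
            lEC50 = starts$lec[k], HS = starts$hs[k])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) y - model(p, lC),
        lower = c(-Inf, -Inf, lo_ec, 0.1),
        upper = c(Inf, Inf, hi_ec, 10),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Hill fit failed to converge from all starts")
  p <- best$fit$par
  structure(list(E0 = unname(p[1]), Emax = unname(p[2]),
                 EC50_uM = unname(10^p[3]), HS = unname(p[4]),
                 rss = best$rss, dof = n - 4,
                 fitted = model(p, lC), data = data),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: E0 = %.4g, Emax = %.4g, EC50 = %.4g uM, HS = %.3g (rss %.3g, dof %d)\n",
              x$E0, x$Emax, x$EC50_uM, x$HS, x$rss, x$dof))
  invisible(x)
}

#' F-test response call: Hill fit versus flat line
#'
#' Compares the residual variance of the 4-parameter Hill fit against a
#' flat-line (fitted constant) null model with an F-test:
#' F = ((RSS_flat - RSS_hill) / 3) / (RSS_hill / (n - 4)), p from the F
#' distribution with (3, n - 4) degrees of freedom. A condition responds
#' when p < alpha (0.01).
#'
#' @param data the fitted [dose_response_data()].
#' @param hill a [hill_fit()] on the same data.
#' @param alpha significance level of the response call.
#' @return A list of class `response_call`: responded, f_statistic, p_value,
#'   flat_fit_level, and (when responded) dor and cytotoxic via
#'   [compute_dor()].
#' @export
f_test_response <- function(data, hill, alpha = 0.01) {
  y <- data$response
  n <- length(y)
  flat <- mean(y)
  rss_flat <- sum((y - flat)^2)
  rss_hill <- hill$rss
  df1 <- (n - 1) - (n - 4)     # 3
  df2 <- n - 4
  if (rss_hill <= .Machine$double.eps * rss_flat) {
    f_stat <- Inf; p <- 0
  } else {
    f_stat <- ((rss_flat - rss_hill) / df1) / (rss_hill / df2)
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  out <- list(responded = p < alpha, f_statistic = f_stat, p_value = p,
              flat_fit_level = flat, alpha = alpha,
              dor = NA_real_, cytotoxic = NA)
  if (out$responded) {
    dr <- compute_dor(hill)
    out$dor <- dr$dor
    out$cytotoxic <- dr$cytotoxic
  }
  class(out) <- "response_call"
  out
}

#' Depth of response from a Hill fit
#'
#' DoR = (E0 - Emax) / E0, the drop between the low- and high-concentration
#' asymptotes normalized by the low-concentration asymptote. DoR <= 1 is a
#' cytostatic response (growth slowed); DoR > 1 (equivalently Emax < 0) is
#' cytotoxic (net mass loss).
#'
#' @param hill a [hill_fit()].
#' @return A list with `dor` and `cytotoxic`.
#' @export
compute_dor <- function(hill) {
  if (hill$E0 == 0) stop("DoR undefined: E0 = 0")
  dor <- (hill$E0 - hill$Emax) / hill$E0
  list(dor = dor, cytotoxic = dor > 1)
}

#' Hill fit to per-condition SGR standard deviations
#'
#' The heterogeneity dose response: identical machinery as [fit_hill()]
#' applied to the standard deviation of single-cell SGR per condition,
#' yielding an EC50 for heterogeneity.
#'
#' @param sd_data a [dose_response_data()] whose `response` column holds the
#'   per-condition SGR standard deviation (1/h).
#' @return A `hill_fit`.
#' @export
fit_heterogeneity_ec50 <- function(sd_data) {
  fit_hill(sd_data)
}
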