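#' Pearson correlation with significance test
#'
#' Standard product-moment correlation between paired measurements (e.g.
#' log10 EC50 by imaging vs an endpoint assay), with the two-sided p-value
#' from the t-transform on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors (n >= 3, finite, nonzero variance).
#' @return A list with `r`, `p_value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  check_pairs(x, y)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

check_pairs <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  invisible(TRUE)
}

#' Lin's concordance correlation coefficient
#'
#' ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2), measuring
#' agreement with the identity line: it penalizes both scatter and
#' systematic location/scale shifts, so |ccc| <= |r| always.
#'
#' @param x,y paired numeric vectors.
#' @return The concordance coefficient in \[-1, 1\].
#' @export
lins_concordance <- function(x, y) {
  check_pairs(x, y)
  2 * stats::cov(x, y) /
    (stats::var(x) + stats::var(y) + (mean(x) - mean(y))^2)
}

#' Percentile bootstrap confidence interval for a paired statistic
#'
#' Resamples the pairs with replacement `n_boot` times and reports the
#' middle 95% (2.5th and 97.5th percentiles) of the statistic. Resamples on
#' which the statistic is undefined (e.g. zero variance) are skipped and
#' counted. Deterministic per seed.
#'
#' @param x,y paired numeric vectors.
#' @param statistic function of (x, y) returning a scalar (default
#'   [lins_concordance()]).
#' @param n_boot number of bootstrap resamples (>= 100; 10000 default).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return A list with `low`, `high`, `n_boot`, `n_degenerate`.
#' @export
bootstrap_ci <- function(x, y, statistic = lins_concordance, n_boot = 10000,
                         seed = 1L, conf = 0.95) {
  check_pairs(x, y)
  if (n_boot < 100) stop("n_boot must be at least 100")
  set.seed(seed)
  n <- length(x)
  vals <- numeric(n_boot)
  degen <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(statistic(x[idx], y[idx]), error = function(e) NA_real_)
    if (is.na(v)) degen <- degen + 1L
    vals[b] <- v
  }
  vals <- vals[!is.na(vals)]
  q <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  list(low = q[1], high = q[2], n_boot = n_boot, n_degenerate = degen)
}

#' Response/no-response confusion matrix between two assays
#'
#' Cross-tabulates the binary response calls of two assays over the same
#' cell-line/drug pairs and reports the agreement fraction (diagonal /
#' total).
#'
#' @param calls_a,calls_b logical vectors (TRUE = response), aligned by
#'   pair; or named vectors sharing names.
#' @return A list with `table` (2x2 matrix), `agreement`, `n`.
#' @export
response_confusion_matrix <- function(calls_a, calls_b) {
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    if (!setequal(names(calls_a), names(calls_b)))
      stop("call vectors cover different pairs")
    calls_b <- calls_b[names(calls_a)]
  }
  if (length(calls_a) != length(calls_b)) stop("call vectors differ in length")
  lv <- c(TRUE, FALSE)
  tab <- table(factor(calls_a, levels = lv, labels = c("response", "none")),
               factor(calls_b, levels = lv, labels = c("response", "none")))
  list(table = unclass(tab),
       agreement = sum(diag(tab)) / sum(tab),
       n = sum(tab))
}

#' Concordance summary between two assays
#'
#' Combines [pearson_with_p()], [lins_concordance()] with its bootstrap CI,
#' and the response [response_confusion_matrix()] in one report. EC50
#' concordance is computed on log10 concentrations and restricted to pairs
#' responding in both assays; the confusion matrix uses all pairs.
#'
#' @param ec50_a,ec50_b EC50 values (uM) per pair; NA = no response.
#' @param responded_a,responded_b logical response calls per pair.
#' @param n_boot,seed bootstrap settings.
#' @return A list with `pearson`, `ccc`, `ccc_ci`, `confusion`.
#' @export
concordance_report <- function(ec50_a, ec50_b, responded_a, responded_b,
                               n_boot = 10000, seed = 1L) {
  both <- responded_a & responded_b & is.finite(ec50_a) & is.finite(ec50_b)
  x <- log10(ec50_a[both]); y <- log10(ec50_b[both])
  list(pearson = pearson_with_p(x, y),
       ccc = lins_concordance(x, y),
       ccc_ci = bootstrap_ci(x, y, lins_concordance, n_boot, seed),
       confusion = response_confusion_matrix(responded_a, responded_b))
}
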