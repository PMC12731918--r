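#' Paired measurements from two methods
#'
#' @param ids scan identifiers.
#' @param method_a,method_b numeric vectors of equal length `n >= 2`
#'   (conventionally manual and predicted).
#' @param variable_name name of the measured variable.
#' @return An object of class `paired_series`.
#' @export
paired_series <- function(ids, method_a, method_b, variable_name = "") {
  method_a <- as.numeric(method_a); method_b <- as.numeric(method_b)
  n <- length(method_a)
  if (length(method_b) != n || length(ids) != n) {
    stop("paired_series: ids, method_a, method_b must have equal length")
  }
  if (n < 2L) stop("insufficient-data error: need n >= 2 pairs")
  if (!all(is.finite(method_a)) || !all(is.finite(method_b))) {
    stop("paired_series: values must be finite")
  }
  structure(list(ids = as.character(ids), method_a = method_a,
                 method_b = method_b, variable_name = variable_name),
            class = "paired_series")
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as `method_b - method_a` (prediction minus manual).
#' Bias is the mean difference, its spread the sample (n-1) standard
#' deviation, and the 95% limits of agreement are `bias +/- 1.96 * SD`
#' (fixed normal multiplier, not a t quantile).
#'
#' @param pairs a [paired_series()].
#' @param loa_multiplier limits-of-agreement multiplier (default 1.96).
#' @return A list of class `bland_altman_result` with `mean_bias`,
#'   `sd_bias`, `loa_lower`, `loa_upper`, `n`, plus `means`/`differences`
#'   for plotting.
#' @export
bland_altman <- function(pairs, loa_multiplier = 1.96) {
  stopifnot(inherits(pairs, "paired_series"))
  d <- pairs$method_b - pairs$method_a
  n <- length(d)
  mean_bias <- mean(d)
  sd_bias <- stats::sd(d)
  structure(list(
    mean_bias = mean_bias, sd_bias = sd_bias,
    loa_lower = mean_bias - loa_multiplier * sd_bias,
    loa_upper = mean_bias + loa_multiplier * sd_bias,
    n = n,
    means = (pairs$method_a + pairs$method_b) / 2,
    differences = d,
    variable_name = pairs$variable_name
  ), class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman%s: bias %.4g +/- %.4g (n = %d), 95%% LOA (%.4g, %.4g)\n",
              if (nzchar(x$variable_name)) paste0(" [", x$variable_name, "]") else "",
              x$mean_bias, x$sd_bias, x$n, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Intraclass correlation ICC(2,1): absolute agreement, single measurement
#'
#' Two-way random-effects model with subjects and raters (methods) as random
#' factors, computed from the ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` subjects, `k = 2` raters, `MS_R` the between-subject, `MS_C` the
#' between-rater and `MS_E` the residual mean square. Absolute agreement is
#' the appropriate form for method-interchangeability claims (a consistent
#' systematic offset between methods lowers it).
#'
#' @param pairs a [paired_series()] (`n >= 2` required, `n >= 3`
#'   recommended).
#' @return Scalar ICC in `(-1, 1]`, or `NA` (undefined sentinel) when the
#'   total variance is zero.
#' @export
icc_absolute_agreement <- function(pairs) {
  stopifnot(inherits(pairs, "paired_series"))
  y <- cbind(pairs$method_a, pairs$method_b)
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot <= 0) return(NA_real_)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences receive
#' mid-ranks. The statistic `W` is the negative-rank sum. For `n <= 12`
#' non-zero differences the two-sided p-value is exact, from full
#' enumeration of all `2^n` sign assignments of the observed ranks (valid
#' under ties as well); above that, a normal approximation with tie
#' correction is used.
#'
#' @param pairs a [paired_series()]; differences are
#'   `method_b - method_a`.
#' @param exact_max largest `n` for the exact enumeration branch.
#' @return List with `statistic` (W, negative-rank sum), `p_value`
#'   (two-sided), `n` (non-zero pairs) and `method` (`"exact"` or
#'   `"normal"`).
#' @export
wilcoxon_signed_rank <- function(pairs, exact_max = 12L) {
  stopifnot(inherits(pairs, "paired_series"))
  d <- pairs$method_b - pairs$method_a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("wilcoxon_signed_rank: all differences zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  w_neg <- sum(r[d < 0])
  if (n <= exact_max) {
    # null distribution of the negative-rank sum over all sign assignments
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    obs <- c(w_neg, sum(r) - w_neg)
    p <- 2 * min(mean(sums <= min(obs)), 1)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4  # equals n(n+1)(2n+1)/24 minus the tie correction
    # continuity-corrected two-sided normal approximation
    z <- (abs(w_neg - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal"
  }
  list(statistic = w_neg, p_value = min(p, 1), n = n, method = method)
}

#' Agreement report over paired depot measurements
#'
#' Runs ICC(2,1), Bland-Altman and the Wilcoxon signed-rank test for each
#' shared measurement variable of two per-scan measurement tables (e.g.
#' manual vs model-derived), keyed by `scan_id`.
#'
#' @param manual,predicted data.frames with a `scan_id` column and numeric
#'   measurement columns (as written by [run_quantify()]).
#' @param variables variables to compare; defaults to the standard five
#'   depot measures present in both tables.
#' @param loa_multiplier passed to [bland_altman()].
#' @return A data.frame with one row per variable: `variable`, `n`, `icc`,
#'   `mean_bias`, `sd_bias`, `loa_lower`, `loa_upper`, `wilcoxon_p`.
#' @export
agreement_report <- function(manual, predicted, variables = NULL,
                             loa_multiplier = 1.96) {
  std <- c("sat_volume_cm3", "vat_volume_cm3", "vat_sat_ratio",
           "sat_suv_mean", "vat_suv_mean")
  if (is.null(variables)) {
    variables <- intersect(std, intersect(names(manual), names(predicted)))
  }
  ids <- intersect(manual$scan_id, predicted$scan_id)
  if (length(ids) < 2L) {
    stop("insufficient-data error: need >= 2 shared scan_ids")
  }
  m <- manual[match(ids, manual$scan_id), , drop = FALSE]
  p <- predicted[match(ids, predicted$scan_id), , drop = FALSE]
  rows <- lapply(variables, function(v) {
    ok <- is.finite(m[[v]]) & is.finite(p[[v]])
    if (sum(ok) < 2L) {
      return(data.frame(variable = v, n = sum(ok), icc = NA_real_,
                        mean_bias = NA_real_, sd_bias = NA_real_,
                        loa_lower = NA_real_, loa_upper = NA_real_,
                        wilcoxon_p = NA_real_))
    }
    ps <- paired_series(ids[ok], m[[v]][ok], p[[v]][ok], v)
    ba <- bland_altman(ps, loa_multiplier)
    wx <- suppressWarnings(wilcoxon_signed_rank(ps))
    data.frame(variable = v, n = ba$n, icc = icc_absolute_agreement(ps),
               mean_bias = ba$mean_bias, sd_bias = ba$sd_bias,
               loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
               wilcoxon_p = wx$p_value)
  })
  do.call(rbind, rows)
}
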