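#' Round half away from zero
#'
#' Display rounding used by the report printers: 2 decimal places by default,
#' ties away from zero (so 0.125 prints as 0.13 and -0.125 as -0.13),
#' matching the convention of most statistics software tables rather than
#' R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Bland-Altman agreement between two paired measurement methods
#'
#' Given paired measurements of the same quantity by methods A and B,
#' computes the classical agreement summary on the differences `d = A - B`:
#'
#' * `bias` = mean(d); `sd_diff` = sample SD of d (1/(n-1));
#' * limits of agreement `LOA = bias +/- loa_mult * sd_diff`
#'   (`loa_mult = 1.96` for 95% limits);
#' * 95% CI of the bias: `bias +/- t(0.975, n-1) * sd_diff / sqrt(n)`;
#' * 95% CI of each limit via the large-sample LOA standard error
#'   `sd_diff * sqrt(3/n)` (normal approximation);
#' * a two-tailed one-sample t-test of mean difference zero, with the
#'   Wilcoxon signed-rank test as a nonparametric cross-check.
#'
#' Zero-variance differences are flagged degenerate: the limits collapse to
#' the bias and the test p-values are undefined.
#'
#' @param a,b Numeric vectors of paired measurements (same length, n >= 2).
#' @param loa_mult Limits-of-agreement multiplier (default 1.96).
#' @param conf Confidence level for the bias CI (default 0.95).
#' @return An object of class `bland_altman` with fields `n`, `mean_a`,
#'   `mean_b`, `bias`, `sd_diff`, `loa` (length 2), `ci_bias`, `ci_loa_lower`,
#'   `ci_loa_upper`, `t`, `df`, `p`, `wilcoxon_p`, `degenerate`.
#' @export
bland_altman <- function(a, b, loa_mult = 1.96, conf = 0.95) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) stop("Bland-Altman needs at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  degenerate <- sd_diff == 0
  loa <- bias + c(-1, 1) * loa_mult * sd_diff
  alpha <- 1 - conf
  tq <- stats::qt(1 - alpha / 2, n - 1)
  ci_bias <- bias + c(-1, 1) * tq * sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(3 / n)
  tst <- one_sample_test(d)
  wp <- if (degenerate) NA_real_ else
    suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value)
  structure(list(
    n = n, mean_a = mean(a), mean_b = mean(b),
    bias = bias, sd_diff = sd_diff, loa = loa,
    ci_bias = ci_bias,
    ci_loa_lower = loa[1] + c(-1, 1) * stats::qnorm(1 - alpha / 2) * se_loa,
    ci_loa_upper = loa[2] + c(-1, 1) * stats::qnorm(1 - alpha / 2) * se_loa,
    t = tst$t, df = tst$df, p = tst$p, wilcoxon_p = wp,
    loa_mult = loa_mult, degenerate = degenerate,
    mean_pair = (a + b) / 2, d = d), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 2, ...) {
  r <- function(v) format(round_half_away(v, digits), nsmall = digits)
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias %s +/- %s mm (95%% CI %s to %s)\n",
              r(x$bias), r(x$sd_diff), r(x$ci_bias[1]), r(x$ci_bias[2])))
  cat(sprintf("  LOA %s to %s mm\n", r(x$loa[1]), r(x$loa[2])))
  if (x$degenerate) {
    cat("  degenerate: zero variance of differences; tests undefined\n")
  } else {
    cat(sprintf("  one-sample t = %.3f (df %d), p = %.3g; Wilcoxon p = %.3g\n",
                x$t, x$df, x$p, x$wilcoxon_p))
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' Mean of the paired measurements on x, difference on y; solid line at the
#' bias, dashed lines at the limits of agreement, shaded bands for the 95%
#' confidence intervals of bias and limits.
#'
#' @param x A [bland_altman()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  ylim <- range(c(x$d, x$ci_loa_lower, x$ci_loa_upper))
  graphics::plot(x$mean_pair, x$d, xlab = "mean of methods (mm)",
                 ylab = "difference A - B (mm)", ylim = ylim, ...)
  band <- function(ci, col) graphics::rect(graphics::par("usr")[1], ci[1],
                                           graphics::par("usr")[2], ci[2],
                                           col = col, border = NA)
  shade <- grDevices::adjustcolor("steelblue", alpha.f = 0.2)
  band(x$ci_bias, shade); band(x$ci_loa_lower, shade); band(x$ci_loa_upper, shade)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = x$loa, lty = 2)
  graphics::points(x$mean_pair, x$d)
  invisible(x)
}

#' One-sample location test of paired differences
#'
#' Two-tailed one-sample t-test of `mean(diffs) = mu`, used to attach a
#' significance value to the absolute agreement between methods. A
#' zero-variance sample is flagged degenerate (p undefined).
#'
#' @param diffs Numeric vector, n >= 2.
#' @param mu Hypothesised mean (default 0).
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
one_sample_test <- function(diffs, mu = 0) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 2L) stop("one-sample test needs at least 2 observations")
  if (stats::sd(diffs) == 0)
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, degenerate = TRUE))
  tt <- stats::t.test(diffs, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Normality screens for method differences
#'
#' Runs the two screens customary before a Bland-Altman analysis: the
#' D'Agostino-Pearson omnibus K2 test (combining skewness and kurtosis) and
#' the Shapiro-Wilk test. The omnibus test requires n >= 8; smaller samples
#' are flagged and skipped.
#'
#' @param diffs Numeric vector.
#' @return List with `dagostino_p`, `shapiro_p`, `skipped` (logical; `TRUE`
#'   when n < 8 and no p-values are produced).
#' @export
normality_screen <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 8L)
    return(list(dagostino_p = NA_real_, shapiro_p = NA_real_, skipped = TRUE))
  list(dagostino_p = dagostino_pearson(diffs)$p,
       shapiro_p = stats::shapiro.test(diffs)$p.value,
       skipped = FALSE)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K2 omnibus statistic combines the normalised sample skewness
#' (D'Agostino's Z of sqrt(b1)) and kurtosis (Anscombe-Glynn's Z of b2);
#' under normality K2 = Z1^2 + Z2^2 is chi-squared with 2 df. Requires
#' n >= 8 for the kurtosis normalisation to be valid.
#'
#' @param x Numeric vector, n >= 8.
#' @return List with `k2` (statistic), `p`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample")
  b1 <- mean((x - m)^3) / m2^1.5   # sample skewness g1
  b2 <- mean((x - m)^4) / m2^2     # sample kurtosis b2

  # skewness: D'Agostino (1970) transformation to normality
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983) transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Within-method repeatability from repeated trials
#'
#' Repeatability (precision) of one method from paired repeats of the same
#' trial: with `d_j` the difference between the two repeats of subject `j`
#' (j = 1..m), the within-subject SD is `sqrt(sum(d_j^2) / (2 m))` and the
#' 95% repeatability coefficient is `CR = 1.96 * sqrt(2) * SD` — the bound
#' expected to cover 95% of differences between two repeats.
#'
#' @param values Numeric measurements (e.g. sway RMS, mm).
#' @param subject Subject/trial grouping; the first two repeats per group are
#'   paired.
#' @param repeat_idx Optional repeat index used to order within group.
#' @return List with `sd` (within-subject SD), `cr` (95% repeatability
#'   coefficient), `m` (number of pairs).
#' @export
repeatability <- function(values, subject, repeat_idx = NULL) {
  if (!is.null(repeat_idx)) {
    o <- order(subject, repeat_idx)
    values <- values[o]; subject <- subject[o]
  }
  sp <- split(values, subject)
  sp <- sp[vapply(sp, length, 1L) >= 2L]
  if (!length(sp))
    stop("repeatability needs at least one subject with 2 repeats")
  d <- vapply(sp, function(v) v[2] - v[1], 1.0)
  m <- length(d)
  sd_w <- sqrt(sum(d^2) / (2 * m))
  list(sd = sd_w, cr = 1.96 * sqrt(2) * sd_w, m = m)
}

#' Repeatability coefficient from a within-subject SD
#'
#' `CR = 1.96 * sqrt(2) * SD`: two repeats of the same measurement are
#' expected to differ by less than CR in 95% of cases.
#'
#' @param sd Within-subject standard deviation (same units as the measure).
#' @return 95% repeatability coefficient.
#' @export
repeatability_coefficient <- function(sd) 1.96 * sqrt(2) * sd

check_long_data <- function(data) {
  need <- c("subject", "condition", "repeat_idx", "method", "sway_rms_mm")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("long-format sway data must have columns: ",
         paste(need, collapse = ", "), " (missing: ",
         paste(miss, collapse = ", "), ")")
  data
}

#' Per-condition method-agreement report
#'
#' The full analysis surface for a paired sway study in long format: for each
#' condition, pairs the two methods' sway values by subject and repeat and
#' computes the [bland_altman()] summary, the one-sample and Wilcoxon tests,
#' and the normality screens of the differences. All records enter the
#' analysis without averaging over repeats unless `average_repeats = TRUE`
#' (which first averages the repeats of each subject x condition x method).
#'
#' @param data Data frame with columns `subject`, `condition`, `repeat_idx`,
#'   `method`, `sway_rms_mm` (long format, one row per trial per method).
#' @param method_a,method_b The two method tags to compare; differences are
#'   `method_a - method_b`.
#' @param average_repeats Average repeated measures before pairing.
#' @return An object of class `agreement_report`: list of per-condition
#'   `bland_altman` objects plus a summary data frame `$table` with columns
#'   `condition`, `n`, `mean_a`, `mean_b`, `bias`, `sd_diff`, `ci_bias_lo`,
#'   `ci_bias_hi`, `loa_lo`, `loa_hi`, `p_t`, `p_wilcoxon`, `p_dagostino`,
#'   `p_shapiro`.
#' @export
agreement_report <- function(data, method_a = "pendulum",
                             method_b = "three_joint",
                             average_repeats = FALSE) {
  data <- check_long_data(data)
  if (average_repeats) {
    agg <- stats::aggregate(sway_rms_mm ~ subject + condition + method,
                            data = data, FUN = mean)
    agg$repeat_idx <- 1L
    data <- agg
  }
  conds <- sort(unique(data$condition))
  fits <- list(); rows <- list()
  for (cc in conds) {
    dc <- data[data$condition == cc, ]
    a <- dc[dc$method == method_a, ]
    b <- dc[dc$method == method_b, ]
    key <- function(x) paste(x$subject, x$repeat_idx, sep = "\r")
    ka <- key(a); kb <- key(b)
    common <- intersect(ka, kb)
    orphans <- c(setdiff(ka, kb), setdiff(kb, ka))
    if (length(orphans))
      stop("unpaired records in condition ", cc, ": ",
           paste(utils::head(gsub("\r", "/", orphans), 5L), collapse = ", "))
    av <- a$sway_rms_mm[match(common, ka)]
    bv <- b$sway_rms_mm[match(common, kb)]
    fit <- bland_altman(av, bv)
    ns <- normality_screen(fit$d)
    fits[[cc]] <- fit
    rows[[cc]] <- data.frame(
      condition = cc, n = fit$n, mean_a = fit$mean_a, mean_b = fit$mean_b,
      bias = fit$bias, sd_diff = fit$sd_diff,
      ci_bias_lo = fit$ci_bias[1], ci_bias_hi = fit$ci_bias[2],
      loa_lo = fit$loa[1], loa_hi = fit$loa[2],
      p_t = fit$p, p_wilcoxon = fit$wilcoxon_p,
      p_dagostino = ns$dagostino_p, p_shapiro = ns$shapiro_p)
  }
  structure(list(fits = fits, table = do.call(rbind, rows),
                 method_a = method_a, method_b = method_b,
                 average_repeats = average_repeats),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 2, ...) {
  cat(sprintf("Method agreement: %s - %s%s\n", x$method_a, x$method_b,
              if (x$average_repeats) " (repeats averaged)" else ""))
  tb <- x$table
  num <- vapply(tb, is.numeric, TRUE)
  tb[num] <- lapply(tb[num], function(v)
    ifelse(abs(v) < 1e-3 & v != 0, signif(v, 3), round_half_away(v, digits)))
  print.data.frame(tb, row.names = FALSE)
  invisible(x)
}

#' Per-condition, per-method repeatability report
#'
#' Within-subject SD and 95% repeatability coefficient for each condition and
#' method, from the paired repeats in a long-format sway dataset.
#'
#' @inheritParams agreement_report
#' @return An object of class `repeatability_report`: data frame with columns
#'   `condition`, `method`, `m` (pairs), `sd`, `cr`.
#' @export
repeatability_report <- function(data) {
  data <- check_long_data(data)
  combos <- unique(data[c("condition", "method")])
  combos <- combos[order(combos$condition, combos$method), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    dc <- data[data$condition == combos$condition[i] &
                 data$method == combos$method[i], ]
    r <- repeatability(dc$sway_rms_mm, dc$subject, dc$repeat_idx)
    data.frame(condition = combos$condition[i], method = combos$method[i],
               m = r$m, sd = r$sd, cr = r$cr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("repeatability_report", "data.frame")
  out
}

#' @export
print.repeatability_report <- function(x, digits = 2, ...) {
  tb <- as.data.frame(x)
  tb$sd <- round_half_away(tb$sd, digits)
  tb$cr <- round_half_away(tb$cr, digits)
  cat("Within-method repeatability (SD, 95% CR)\n")
  print.data.frame(tb, row.names = FALSE)
  invisible(x)
}
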