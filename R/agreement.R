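# Method-agreement statistics: non-parametric Bland-Altman summaries,
# ICC(2,1) with Shrout-Fleiss confidence interval, exact/approximate
# rank tests, Brown-Forsythe Levene, Spearman correlation.

#' Non-parametric Bland-Altman summary
#'
#' Differences are oriented reference minus test method. Returns the median
#' difference, the interquartile range, and non-parametric limits of
#' agreement: the empirical 2.5% and 97.5% quantiles of the differences
#' (linear-interpolation quantiles, type 7).
#'
#' @param reference,efos Paired numeric vectors (reference method first).
#' @return A list of class `bland_altman` with `median_diff`, `iqr`
#'   (named Q1/Q3), `loa` (named 2.5%/97.5%), `n` and the differences `d`.
#' @examples
#' bland_altman(c(10, 12, 14, 18), c(11, 11, 12, 14))
#' @export
bland_altman <- function(reference, efos) {
  if (length(reference) != length(efos))
    fv_stop("agreement", "invalid-params", "paired vectors differ in length")
  d <- reference - efos
  d <- d[is.finite(d)]
  if (length(d) < 3L)
    fv_stop("agreement", "insufficient-data", "need at least 3 pairs")
  structure(list(
    median_diff = stats::median(d),
    iqr = stats::quantile(d, c(0.25, 0.75), names = TRUE),
    loa = stats::quantile(d, c(0.025, 0.975), names = TRUE),
    n = length(d), d = d
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Difference (reference - test), n = %d\n", x$n))
  cat(sprintf("  median %.3g (IQR %.3g; %.3g)\n",
              x$median_diff, x$iqr[1], x$iqr[2]))
  cat(sprintf("  non-parametric limits of agreement: (%.3g, %.3g)\n",
              x$loa[1], x$loa[2]))
  invisible(x)
}

# Two-way mean squares for an n x k ratings matrix.
icc_mean_squares <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- max(sst - ssr - ssc, 0)   # guard fp cancellation for exact agreement
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation ICC(2,1), absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the subjects-by-methods mean-squares decomposition, with the 95%
#' Shrout-Fleiss F-based confidence interval. This is the clinically
#' relevant reliability index for two fixed devices measuring the same
#' subjects.
#'
#' @param reference,efos Paired numeric vectors (one value per subject), or
#'   `reference` may be an `n x k` ratings matrix with `efos` omitted.
#' @param conf_level Confidence level for the interval.
#' @return A list of class `icc_estimate` with `estimate`, `ci_lo`,
#'   `ci_hi`, the mean squares and dimensions.
#' @examples
#' icc(c(9, 6, 8, 7, 10), c(10, 5, 9, 7, 11))
#' @export
icc <- function(reference, efos = NULL, conf_level = 0.95) {
  ratings <- if (is.null(efos)) as.matrix(reference)
             else cbind(reference, efos)
  if (ncol(ratings) < 2L)
    fv_stop("agreement", "invalid-params", "need at least 2 methods")
  ratings <- ratings[stats::complete.cases(ratings), , drop = FALSE]
  if (nrow(ratings) < 2L)
    fv_stop("agreement", "insufficient-data", "need at least 2 subjects")
  ms <- icc_mean_squares(ratings)
  n <- ms$n; k <- ms$k
  if (isTRUE(all.equal(stats::var(rowMeans(ratings)), 0,
                       tolerance = 1e-12))) {
    fv_warn("agreement", "zero-between-subject-variance",
            "no between-subject variance; ICC reported as 0")
    est <- 0
  } else {
    est <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  }
  alpha <- 1 - conf_level
  if (ms$mse <= 1e-12 * max(ms$msr, 1) && est >= 1 - 1e-9) {
    ci <- c(1, 1)          # degenerate: methods agree exactly
  } else {
    fj <- ms$msc / ms$mse
    vn <- (k - 1) * (n - 1) *
      (k * est * fj + n * (1 + (k - 1) * est) - k * est)^2
    vd <- (n - 1) * k^2 * est^2 * fj^2 +
      (n * (1 + (k - 1) * est) - k * est)^2
    v <- vn / vd
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - f_u * ms$mse) /
      (f_u * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (f_l * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_l * ms$msr)
    ci <- c(lo, hi)
    ci[!is.finite(ci)] <- NA_real_
  }
  structure(list(estimate = est, ci_lo = ci[1], ci_hi = ci[2],
                 msr = ms$msr, msc = ms$msc, mse = ms$mse,
                 n = n, k = k, conf_level = conf_level),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement: %.3f (%.0f%% CI %.3f; %.3f), n = %d\n",
              x$estimate, 100 * x$conf_level, x$ci_lo, x$ci_hi, x$n))
  invisible(x)
}

# Exact null distribution of twice the positive-rank sum, as counts over
# 0..sum(2*ranks), by subset-sum convolution. Mid-ranks doubled so tied
# ranks stay on an integer lattice.
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (w in ranks2) {
    if (w > 0L) f[(w + 1L):(total + 1L)] <-
        f[(w + 1L):(total + 1L)] + f[1L:(total + 1L - w)]
  }
  f
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided. Zero differences are dropped; absolute differences are
#' mid-ranked so ties are handled in both modes. For 20 or fewer non-zero
#' differences the p-value is exact, by enumeration of the sign-assignment
#' distribution (subset-sum convolution over the doubled mid-ranks);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x Numeric vector: either the paired differences (if `y` is
#'   `NULL`) or the first member of each pair.
#' @param y Optional second member of each pair.
#' @param exact_max Largest number of non-zero differences for which the
#'   exact distribution is enumerated.
#' @return A list of class `fv_test` with `statistic` (positive-rank sum
#'   `V`), `p.value`, `n` (non-zero differences) and `method`.
#' @examples
#' wilcoxon_paired(c(2, 3, 1, 4, 5))   # all positive, n = 5: p = 0.0625
#' @export
wilcoxon_paired <- function(x, y = NULL, exact_max = 20L) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    fv_warn("agreement", "all-zero-differences", "p = 1 reported")
    return(structure(list(statistic = NA_real_, p.value = 1, n = 0L,
                          method = "degenerate"), class = "fv_test"))
  }
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (n <= exact_max) {
    cnt <- signed_rank_counts(as.integer(round(2 * r)))
    tot <- sum(cnt)
    iv <- as.integer(round(2 * v))
    p_ge <- sum(cnt[(iv + 1L):length(cnt)]) / tot
    p_le <- sum(cnt[1L:(iv + 1L)]) / tot
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(statistic = v, p.value = p, n = n, method = method),
            class = "fv_test")
}

#' Mann-Whitney U test
#'
#' Two-sided, on mid-ranks. Exact by enumeration of all group-label
#' assignments when the pooled sample size is at most `exact_max`
#' (default 12); otherwise a normal approximation with tie correction and
#' continuity correction.
#'
#' @param group_a,group_b Numeric vectors, each non-empty (>= 2 values for
#'   a meaningful test).
#' @param exact_max Largest pooled size for exact enumeration.
#' @return A list of class `fv_test` with `statistic` (U for `group_a`),
#'   `p.value` and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12))   # exact p = 0.1
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 12L) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  m <- length(a); n <- length(b)
  if (m < 2L || n < 2L)
    fv_stop("agreement", "insufficient-data",
            "each group needs at least 2 values")
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= exact_max) {
    sets <- utils::combn(m + n, m)
    us <- colSums(matrix(rk[sets], nrow = m)) - m * (m + 1) / 2
    p_le <- mean(us <= u + 1e-9)
    p_ge <- mean(us >= u - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- m + n
    mu <- m * n / 2
    ties <- table(rk)
    sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(statistic = u, p.value = p, n = c(m, n), method = method),
            class = "fv_test")
}

#' Levene's test (Brown-Forsythe variant)
#'
#' One-way F test on absolute deviations from the group medians; the
#' median-centred variant is robust to non-normality. Two-sided p from the
#' F(k-1, N-k) reference distribution.
#'
#' @param group_a,group_b Numeric vectors, each with at least 3 values.
#' @return A list of class `fv_test` with `statistic` (F), `df`, `p.value`.
#' @export
levene <- function(group_a, group_b) {
  groups <- list(group_a[is.finite(group_a)], group_b[is.finite(group_b)])
  if (any(lengths(groups) < 3L))
    fv_stop("agreement", "insufficient-data",
            "each group needs at least 3 values")
  z <- lapply(groups, function(g) abs(g - stats::median(g)))
  zz <- unlist(z)
  if (all(zz == 0)) {
    fv_warn("agreement", "undefined-statistic",
            "all values identical within groups; p = 1 reported")
    return(structure(list(statistic = NA_real_, df = c(NA, NA), p.value = 1,
                          method = "degenerate"), class = "fv_test"))
  }
  k <- length(z); N <- length(zz)
  gm <- mean(zz)
  ssb <- sum(lengths(z) * (vapply(z, mean, numeric(1)) - gm)^2)
  ssw <- sum(unlist(lapply(z, function(g) (g - mean(g))^2)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  structure(list(statistic = f, df = c(k - 1, N - k), p.value = p,
                 method = "Brown-Forsythe"), class = "fv_test")
}

#' Spearman rank correlation with confidence interval
#'
#' Pearson correlation of mid-ranks; 95% confidence interval by the Fisher
#' z transform with variance `1.06 / (n - 3)`; two-sided p-value by the t
#' approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, neither constant.
#' @param conf_level Confidence level.
#' @return A list of class `spearman_estimate` with `rho`, `ci_lo`,
#'   `ci_hi`, `p.value`, `n`.
#' @export
spearman <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L)
    fv_stop("agreement", "insufficient-data", "need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    fv_stop("agreement", "constant-input",
            "rank correlation undefined for constant input")
  rho <- stats::cor(rank(x), rank(y))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  rho_c <- min(max(rho, -1 + 1e-15), 1 - 1e-15)
  zse <- sqrt(1.06 / (n - 3))
  ci <- tanh(atanh(rho_c) + c(-1, 1) * zq * zse)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, ci_lo = ci[1], ci_hi = ci[2], p.value = p,
                 n = n, conf_level = conf_level),
            class = "spearman_estimate")
}

#' @export
print.spearman_estimate <- function(x, ...) {
  cat(sprintf("Spearman's rho: %.3f (%.0f%% CI %.3f; %.3f), p = %.4g, n = %d\n",
              x$rho, 100 * x$conf_level, x$ci_lo, x$ci_hi, x$p.value, x$n))
  invisible(x)
}

#' @export
print.fv_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %s, p = %.4g\n",
              x$method, format(x$statistic, digits = 5), x$p.value))
  invisible(x)
}

#' Full agreement report for one vital
#'
#' Assembles the agreement battery for a paired cohort: the non-parametric
#' Bland-Altman summary, ICC(2,1) with confidence interval, and the paired
#' Wilcoxon p-value. Repeated pairs per subject can be analysed as they
#' stand or first collapsed to per-subject medians (the repeated pairs are
#' not independent; both conventions are offered).
#'
#' @param pairs A `paired_measurements` data frame (see
#'   [make_paired_dataset()] / [read_pairs_csv()]).
#' @param vital `"RR"` or `"HR"`.
#' @param per_subject Collapse repeated pairs to per-subject medians before
#'   testing.
#' @return A list of class `agreement_report` with `vital`, `n_pairs`,
#'   `median_diff`, `iqr`, `loa`, `icc`, `icc_ci`, `p_wilcoxon`.
#' @examples
#' pm <- make_paired_dataset(10, seed = 1)
#' efos_agreement(pm, "RR")
#' @export
efos_agreement <- function(pairs, vital = c("RR", "HR"),
                           per_subject = FALSE) {
  vital <- match.arg(vital)
  stopifnot(is.data.frame(pairs))
  need <- c("subject", "vital", "reference", "efos")
  if (!all(need %in% names(pairs)))
    fv_stop("agreement", "invalid-params",
            paste("pairs must contain columns:", paste(need, collapse = ", ")))
  sub <- pairs[pairs$vital == vital, , drop = FALSE]
  if (nrow(sub) == 0L)
    fv_stop("agreement", "unknown-vital",
            sprintf("no rows with vital == '%s'", vital))
  if (per_subject) {
    ref <- tapply(sub$reference, sub$subject, stats::median)
    efo <- tapply(sub$efos, sub$subject, stats::median)
  } else {
    ref <- sub$reference; efo <- sub$efos
  }
  ba <- bland_altman(ref, efo)
  ic <- icc(ref, efo)
  wt <- wilcoxon_paired(ref, efo)
  structure(list(vital = vital, n_pairs = length(ref),
                 median_diff = ba$median_diff, iqr = ba$iqr, loa = ba$loa,
                 icc = ic$estimate, icc_ci = c(ic$ci_lo, ic$ci_hi),
                 p_wilcoxon = wt$p.value, per_subject = per_subject),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report: %s (%d pairs%s)\n", x$vital, x$n_pairs,
              if (x$per_subject) ", per-subject medians" else ""))
  cat(sprintf("  difference (reference - pad): median %.3g (IQR %.3g; %.3g)\n",
              x$median_diff, x$iqr[1], x$iqr[2]))
  cat(sprintf("  limits of agreement: (%.3g, %.3g)\n", x$loa[1], x$loa[2]))
  cat(sprintf("  ICC(2,1): %.3f (95%% CI %.3f; %.3f)\n",
              x$icc, x$icc_ci[1], x$icc_ci[2]))
  cat(sprintf("  paired Wilcoxon p = %.4g\n", x$p_wilcoxon))
  invisible(x)
}
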