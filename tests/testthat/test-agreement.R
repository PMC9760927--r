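test_that("Bland-Altman summaries follow the sorted differences", {
  # diffs {-1, 1, 2, 4}: median is the mean of the middle pair
  ba <- bland_altman(c(-1, 1, 2, 4), c(0, 0, 0, 0))
  expect_equal(ba$median_diff, 1.5)
  expect_equal(unname(ba$iqr), c(0.5, 2.5))
  # type-7 empirical 2.5% / 97.5% quantiles of the four differences
  expect_equal(unname(ba$loa), c(-0.85, 3.85))
  # identical methods
  ba0 <- bland_altman(c(3, 5, 9), c(3, 5, 9))
  expect_equal(ba0$median_diff, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  # translation equivariance
  d <- c(-2.5, 0.3, 1.1, 4.2, 5.0)
  b1 <- bland_altman(d, rep(0, 5))
  b2 <- bland_altman(d + 7, rep(0, 5))
  expect_equal(b2$median_diff, b1$median_diff + 7)
  expect_equal(unname(b2$loa), unname(b1$loa) + 7)
  expect_error(bland_altman(c(1, 2), c(1, 2)),
               class = "fibervitals_insufficient-data")
})

test_that("ICC(2,1) matches a from-scratch ANOVA mean-squares oracle", {
  # 4 subjects x 2 methods fixture
  ref <- c(10, 14, 18, 22)
  efo <- c(11, 13, 19, 25)
  got <- icc(ref, efo)
  # independent oracle: two-way ANOVA mean squares via aov, then the
  # ICC(2,1) definition
  df <- data.frame(y = c(ref, efo),
                   subj = factor(rep(1:4, 2)),
                   meth = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + meth, data = df))[[1]][["Mean Sq"]]
  n <- 4; k <- 2
  msr_o <- ms[1]; msc_o <- ms[2]; mse_o <- ms[3]
  icc_o <- (msr_o - mse_o) /
    (msr_o + (k - 1) * mse_o + k * (msc_o - mse_o) / n)
  expect_equal(got$estimate, icc_o, tolerance = 1e-10)
})

test_that("ICC is 1 for exact agreement and rises as pad noise falls", {
  perfect <- icc(c(9, 6, 8, 7, 10), c(9, 6, 8, 7, 10))
  expect_equal(perfect$estimate, 1)
  expect_equal(c(perfect$ci_lo, perfect$ci_hi), c(1, 1))
  # zero-noise synthetic cohort
  pm0 <- make_paired_dataset(12, efos_noise_sd = 0, seed = 2)
  rr0 <- pm0[pm0$vital == "RR", ]
  expect_equal(icc(rr0$reference, rr0$efos)$estimate, 1)
  # monotone improvement over three noise levels, same seed
  iccs <- vapply(c(8, 2, 0.5), function(sd) {
    pm <- make_paired_dataset(12, efos_noise_sd = sd, seed = 2)
    rr <- pm[pm$vital == "RR", ]
    icc(rr$reference, rr$efos)$estimate
  }, numeric(1))
  expect_true(all(diff(iccs) > 0))
  # degenerate: no between-subject variance
  expect_warning(z <- icc(c(5, 5, 5, 5), c(5, 5, 5, 5)),
                 "between-subject")
  expect_equal(z$estimate, 0)
})

test_that("paired Wilcoxon exact p-values match enumeration", {
  # n = 5, all differences positive: one-tailed 1/32, two-sided 1/16
  w <- wilcoxon_paired(c(2, 3, 1, 4, 5))
  expect_equal(w$p.value, 0.0625, tolerance = 1e-12)
  expect_equal(w$method, "exact")
  # agreement with wilcox.test in a tie-free case
  d <- c(1.2, -0.4, 2.2, 3.1, -1.7, 0.6, 2.8, -0.9)
  expect_equal(wilcoxon_paired(d)$p.value,
               stats::wilcox.test(d, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # symmetric sample: no evidence of a shift
  expect_gt(wilcoxon_paired(c(-3, -2, -1, 1, 2, 3))$p.value, 0.5)
  # all-zero differences degenerate to p = 1 with a warning
  expect_warning(z <- wilcoxon_paired(rep(0, 6)), "all-zero")
  expect_equal(z$p.value, 1)
})

test_that("exact and approximate Wilcoxon modes agree at moderate n", {
  set.seed(9)
  d <- round(stats::rnorm(15, mean = 0.4), 2)
  p_exact <- wilcoxon_paired(d, exact_max = 20)$p.value
  p_approx <- wilcoxon_paired(d, exact_max = 0)$p.value
  expect_lt(abs(p_exact - p_approx), 0.02)
})

test_that("Mann-Whitney exact p-values match enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(mw$p.value, 0.1, tolerance = 1e-12)
  expect_equal(mw$method, "exact")
  # identical groups carry no separation
  expect_gt(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))$p.value, 0.9)
  # invariance under common positive rescaling
  a <- c(3, 7, 1, 9, 4); b <- c(2, 8, 6, 5)
  expect_equal(mann_whitney(a, b)$p.value,
               mann_whitney(10 * a, 10 * b)$p.value, tolerance = 1e-12)
  # agreement with wilcox.test in a tie-free case
  expect_equal(mann_whitney(a, b)$p.value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), c(1, 2)),
               class = "fibervitals_insufficient-data")
})

test_that("Brown-Forsythe Levene test detects scale, ignores location", {
  # equal-spread fixture: agreement with car::leveneTest
  a <- c(4.1, 5.2, 3.9, 4.8, 5.0, 4.4, 5.6, 3.8)
  b <- c(6.0, 7.1, 5.8, 6.7, 6.9, 6.3, 7.5, 5.7)
  got <- levene(a, b)
  ref <- car::leveneTest(c(a, b), factor(rep(1:2, each = 8)),
                         center = stats::median)
  expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(got$p.value, ref$`Pr(>F)`[1], tolerance = 1e-12)
  expect_gt(got$p.value, 0.5)
  # a tenfold spread difference at n = 20 per group is detected
  set.seed(31)
  g1 <- stats::rnorm(20, sd = 1)
  g2 <- stats::rnorm(20, sd = 10)
  expect_lt(levene(g1, g2)$p.value, 0.05)
  # pure location shift leaves the statistic unchanged
  expect_equal(levene(g1, g2)$statistic,
               levene(g1 + 100, g2 - 50)$statistic, tolerance = 1e-12)
  # degenerate input: undefined statistic, p = 1
  expect_warning(z <- levene(rep(1, 5), rep(2, 5)), "undefined")
  expect_equal(z$p.value, 1)
})

test_that("Spearman correlation handles monotone maps and ties", {
  x <- c(1, 4, 2, 8, 5, 7)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x^3)$rho, -1)
  # tied fixture against a hand-built mid-rank Pearson computation
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6)
  got <- spearman(xt, yt)
  midrank <- function(v) {
    vapply(v, function(vi) {
      less <- sum(v < vi); eq <- sum(v == vi)
      less + (eq + 1) / 2
    }, numeric(1))
  }
  rx <- midrank(xt); ry <- midrank(yt)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, num / den, tolerance = 1e-12)
  expect_true(got$ci_lo <= got$rho && got$rho <= got$ci_hi)
  expect_error(spearman(rep(1, 5), 1:5),
               class = "fibervitals_constant-input")
})

test_that("agreement invariants hold over random cohorts", {
  set.seed(77)
  for (i in 1:200) {
    d <- stats::rnorm(sample(5:30, 1), sd = stats::runif(1, 0.1, 5))
    ba <- bland_altman(d, rep(0, length(d)))
    expect_true(ba$loa[1] <= ba$median_diff && ba$median_diff <= ba$loa[2])
  }
  for (i in 1:25) {
    n <- sample(5:20, 1)
    ref <- stats::rnorm(n, 100, 20)
    efo <- ref + stats::rnorm(n, 0, 10)
    est <- icc(ref, efo)$estimate
    expect_true(est >= -1 && est <= 1)
    rho <- spearman(ref, efo)$rho
    expect_true(rho >= -1 && rho <= 1)
  }
})

test_that("agreement statistics are invariant to subject ordering", {
  pm <- make_paired_dataset(10, seed = 8)
  rr <- pm[pm$vital == "RR", ]
  set.seed(1)
  perm <- sample(nrow(rr))
  expect_equal(wilcoxon_paired(rr$reference, rr$efos)$p.value,
               wilcoxon_paired(rr$reference[perm], rr$efos[perm])$p.value,
               tolerance = 1e-12)
  expect_equal(icc(rr$reference, rr$efos)$estimate,
               icc(rr$reference[perm], rr$efos[perm])$estimate,
               tolerance = 1e-12)
  expect_equal(bland_altman(rr$reference, rr$efos)$loa,
               bland_altman(rr$reference[perm], rr$efos[perm])$loa,
               tolerance = 1e-12)
})

test_that("the full agreement report assembles all battery components", {
  pm <- make_paired_dataset(15, seed = 4)
  rep_rr <- efos_agreement(pm, "RR")
  expect_s3_class(rep_rr, "agreement_report")
  expect_equal(rep_rr$n_pairs, 45)
  expect_true(is.finite(rep_rr$icc) && is.finite(rep_rr$p_wilcoxon))
  # per-subject medians collapse the repeated pairs
  rep_med <- efos_agreement(pm, "RR", per_subject = TRUE)
  expect_equal(rep_med$n_pairs, 15)
  expect_error(efos_agreement(pm[pm$vital == "RR", ], "HR"),
               class = "fibervitals_unknown-vital")
})
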