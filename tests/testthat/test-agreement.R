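# ICC(2,1), Bland-Altman, Wilcoxon signed-rank.

# build a paired series whose differences have exactly the requested
# mean and sample SD (n = 10): standardized base pattern scaled back up
series_with_bias <- function(mean_bias, sd_bias, n = 10) {
  z <- scale(seq_len(n))[, 1]           # mean 0, sample SD 1
  d <- mean_bias + sd_bias * z
  a <- seq(100, 1000, length.out = n)
  paired_series(sprintf("s%02d", seq_len(n)), a, a + d)
}

test_that("bland_altman reproduces the printed summary arithmetic", {
  # bias 91 +/- 223 -> LOA (-346.08, 528.08)
  ba <- bland_altman(series_with_bias(91, 223))
  expect_equal(ba$mean_bias, 91)
  expect_equal(ba$sd_bias, 223)
  expect_equal(ba$loa_lower, 91 - 1.96 * 223)
  expect_equal(ba$loa_upper, 528.08)
  expect_equal(round(ba$loa_lower), -346)
  # bias -0.026 +/- 0.088 -> upper LOA 0.146 at 3 dp
  ba2 <- bland_altman(series_with_bias(-0.026, 0.088))
  expect_equal(round(ba2$loa_upper, 3), 0.146)
  # identical pairs -> all zero
  ids <- letters[1:5]
  ba3 <- bland_altman(paired_series(ids, 1:5, 1:5))
  expect_equal(c(ba3$mean_bias, ba3$sd_bias, ba3$loa_lower, ba3$loa_upper),
               c(0, 0, 0, 0))
  # LOA invariants hold bit-wise
  expect_identical(ba$loa_lower, ba$mean_bias - 1.96 * ba$sd_bias)
  expect_identical(ba$loa_upper, ba$mean_bias + 1.96 * ba$sd_bias)
  expect_error(paired_series("a", 1, 2), "insufficient-data")
})

test_that("swapping methods negates bias and mirrors the limits of agreement", {
  set.seed(21)
  a <- stats::rnorm(8, 50, 10); b <- a + stats::rnorm(8, 2, 3)
  p1 <- paired_series(1:8, a, b); p2 <- paired_series(1:8, b, a)
  ba1 <- bland_altman(p1); ba2 <- bland_altman(p2)
  expect_equal(ba2$mean_bias, -ba1$mean_bias)
  expect_equal(ba2$loa_lower, -ba1$loa_upper)
  expect_equal(ba2$loa_upper, -ba1$loa_lower)
  expect_equal(icc_absolute_agreement(p1), icc_absolute_agreement(p2))
})

test_that("ICC(2,1) matches the ANOVA oracle on 50 random small tables", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    a <- stats::rnorm(n, 100, 30)
    b <- a * stats::runif(1, 0.8, 1.2) + stats::rnorm(n, 0, 10) +
      stats::runif(1, -10, 10)
    p <- paired_series(seq_len(n), a, b)
    expect_equal(icc_absolute_agreement(p), oracle_icc_21(a, b),
                 tolerance = 1e-10)
  }
})

test_that("ICC limiting cases behave", {
  a <- c(1, 5, 9, 13)
  expect_equal(icc_absolute_agreement(paired_series(1:4, a, a)), 1)
  # anti-correlated, zero-mean -> negative
  expect_lt(icc_absolute_agreement(paired_series(1:4, a - mean(a),
                                                 -(a - mean(a)))), 0)
  # zero total variance -> undefined sentinel
  expect_true(is.na(icc_absolute_agreement(paired_series(1:4, rep(2, 4),
                                                         rep(2, 4)))))
})

test_that("wilcoxon exact branch equals full sign enumeration", {
  # n = 5, all differences positive, no ties -> W = 0, p = 2/32
  p <- paired_series(1:5, rep(0, 5), c(1, 2, 3, 4, 5))
  w <- wilcoxon_signed_rank(p)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$method, "exact")
  # n = 1 nonzero -> p = 1
  p1 <- paired_series(1:2, c(0, 3), c(2, 3))
  expect_equal(wilcoxon_signed_rank(p1)$p_value, 1)
  # antisymmetric differences sit in the centre of the null
  pa <- paired_series(1:4, c(0, 0, 0, 0), c(2, -2, 5, -5))
  expect_equal(wilcoxon_signed_rank(pa)$p_value, 1)
  # all-zero differences: p = 1 with warning
  expect_warning(wz <- wilcoxon_signed_rank(paired_series(1:3, 1:3, 1:3)),
                 "all differences zero")
  expect_equal(wz$p_value, 1)
  # random cases vs the oracle (with and without ties)
  set.seed(41)
  for (i in 1:20) {
    d <- sample(c(-4:-1, 1:4), sample(4:10, 1), replace = TRUE)
    p <- paired_series(seq_along(d), rep(0, length(d)), d)
    expect_equal(wilcoxon_signed_rank(p)$p_value, oracle_wilcoxon(d))
  }
  # no-ties case also agrees with R's exact reference implementation
  set.seed(42)
  d <- sample(1:50, 9) * sample(c(-1, 1), 9, replace = TRUE)
  p <- paired_series(1:9, rep(0, 9), d)
  ref <- stats::wilcox.test(d, exact = TRUE)$p.value
  expect_equal(wilcoxon_signed_rank(p)$p_value, ref)
})

test_that("exact and normal branches agree to ~0.02 at n = 12", {
  set.seed(51)
  for (i in 1:10) {
    d <- stats::rnorm(12)
    p <- paired_series(1:12, rep(0, 12), d)
    pe <- wilcoxon_signed_rank(p, exact_max = 12)$p_value
    pn <- wilcoxon_signed_rank(p, exact_max = 0)$p_value
    expect_lt(abs(pe - pn), 0.02 + 1e-9)
  }
})

test_that("agreement_report aggregates the five depot variables", {
  set.seed(61)
  man <- data.frame(scan_id = sprintf("s%d", 1:8),
                    sat_volume_cm3 = stats::runif(8, 3000, 8000),
                    vat_volume_cm3 = stats::runif(8, 1500, 5000),
                    sat_suv_mean = stats::runif(8, 0.15, 0.35),
                    vat_suv_mean = stats::runif(8, 0.5, 1.0))
  man$vat_sat_ratio <- man$vat_volume_cm3 / man$sat_volume_cm3
  pred <- man
  for (v in setdiff(names(man), "scan_id")) {
    pred[[v]] <- man[[v]] * (1 + stats::rnorm(8, 0, 0.02))
  }
  rep_ <- agreement_report(man, pred)
  expect_equal(nrow(rep_), 5)
  expect_true(all(rep_$icc > 0.9))
  expect_identical(rep_$loa_upper, rep_$mean_bias + 1.96 * rep_$sd_bias)
  # identical tables -> zero bias, ICC 1
  rep0 <- agreement_report(man, man)
  expect_equal(rep0$mean_bias, rep(0, 5))
  expect_equal(rep0$icc, rep(1, 5))
  # disjoint ids -> error
  pred2 <- pred; pred2$scan_id <- sprintf("t%d", 1:8)
  expect_error(agreement_report(man, pred2), "insufficient-data")
})
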