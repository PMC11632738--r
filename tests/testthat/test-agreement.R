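test_that("paired differences use reference minus automated with sample SD", {
  s <- paired_series("M1", c("a", "b", "c"), c(5, 7, 9), c(4, 5, 6))
  d <- paired_differences(s)
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)

  same <- paired_differences(paired_series("M2", 1:4, c(3, 4, 5, 6),
                                           c(3, 4, 5, 6)))
  expect_equal(same$mean, 0)
  expect_equal(same$sd, 0)

  expect_error(paired_series("M1", "a", 1, 2), class = "fm_data_error")
  expect_error(paired_series("M1", c("a", "b"), c(1, 2, 3), c(1, 2)),
               class = "fm_pairing_error")
})

test_that("series built to the published per-method means reproduce the published mean differences", {
  # per-method group means for M1, M2, M3, M7 (20-subject comparison,
  # version 1); the mean paired difference must equal their difference
  cases <- list(M1 = c(62.47, 56.33, 6.14), M2 = c(67.42, 63.95, 3.47),
                M3 = c(32.02, 32.01, 0.01), M7 = c(45.21, 42.39, 2.82))
  dev <- seq(-1.9, 1.9, length.out = 20)   # zero-sum subject spread
  for (m in names(cases)) {
    s <- paired_series(m, 1:20, cases[[m]][1] + dev,
                       cases[[m]][2] + rev(dev))
    expect_equal(paired_differences(s)$mean, cases[[m]][3], tolerance = 1e-9)
  }
})

test_that("the paired t statistic matches the closed form and the published rows", {
  tt <- paired_t_test(6.14, 5.32, 20)
  expect_equal(tt$t, 6.14 / (5.32 / sqrt(20)), tolerance = 1e-12)
  expect_equal(tt$t, 5.161, tolerance = 1e-3)
  expect_equal(tt$df, 19)
  expect_lt(tt$p, 0.001)

  null <- paired_t_test(0, 3.2, 20)
  expect_equal(null$t, 0)
  expect_equal(null$p, 1)

  expect_lt(abs(paired_t_test(3.47, 6.55, 20)$p - 0.029), 0.001)
})

test_that("summary-statistic t-tests agree with stats::t.test on raw data", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    ref <- rnorm(n, 50, 6)
    am <- ref - rnorm(n, runif(1, -2, 2), runif(1, 0.5, 3))
    d <- ref - am
    ours <- paired_t_test(mean(d), sd(d), n)
    oracle <- stats::t.test(ref, am, paired = TRUE)
    expect_equal(ours$t, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("two-sided p agrees with numerical integration of the t density", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    mean_d <- runif(1, -5, 5)
    sd_d <- runif(1, 0.2, 8)
    res <- paired_t_test(mean_d, sd_d, n)
    tail <- stats::integrate(function(x) stats::dt(x, n - 1),
                             lower = abs(res$t), upper = Inf,
                             rel.tol = 1e-10)$value
    expect_equal(res$p, 2 * tail, tolerance = 1e-6)
  }
})

test_that("degenerate zero-SD series follow the stated conventions", {
  z <- paired_t_test(0, 0, 20)
  expect_equal(z$p, 1)
  expect_true(z$degenerate)
  nz <- paired_t_test(1.5, 0, 20)
  expect_equal(nz$p, 0)
  expect_true(nz$degenerate)
  expect_error(paired_t_test(1, 2, 1), class = "fm_data_error")
})

test_that("p-values are invariant under sign flip and t carries the sign", {
  a <- paired_t_test(2.3, 1.7, 15)
  b <- paired_t_test(-2.3, 1.7, 15)
  expect_equal(a$p, b$p)
  expect_equal(a$t, -b$t)
  expect_gt(a$t, 0)
})

test_that("build_report covers 9 measurements x versions with correct flags", {
  set.seed(42)
  mk <- function(values) data.frame(subject_id = sprintf("s%02d", 1:20),
                                    method = "x", values)
  base <- matrix(rep(c(62, 67, 32, 33, 20, 9, 45, 12, 2.2), each = 20),
                 20, 9, dimnames = list(NULL, paste0("M", 1:9)))
  spread <- matrix(rnorm(180, 0, 2), 20, 9)
  cm <- mk(base + spread)

  # identical methods: zero differences, nothing significant
  rep0 <- build_report(cm, cm)
  expect_equal(nrow(rep0), 9)
  expect_true(all(rep0$mean_diff == 0))
  expect_false(any(rep0$sig_05))

  # +2 mm bias on M8 only, 0.3 mm measurement noise
  am1 <- cm
  am1[paste0("M", 1:9)] <- am1[paste0("M", 1:9)] + rnorm(180, 0, 0.3)
  am1$M8 <- am1$M8 - 2
  am2 <- cm
  am2[paste0("M", 1:9)] <- am2[paste0("M", 1:9)] + rnorm(180, 0, 0.3)
  am2$M8 <- am2$M8 - 2
  rep2 <- build_report(cm, am1, am2)
  expect_equal(nrow(rep2), 18)
  expect_true(all(rep2$sig_01[rep2$measurement == "M8"]))
  expect_equal(count_significant(rep2, alpha = 0.01, require_both = TRUE), 1)

  bad <- cm; bad$subject_id <- paste0(bad$subject_id, "_x")
  expect_error(build_report(cm, bad), class = "fm_pairing_error")
  expect_error(build_report(cm[setdiff(names(cm), "M1")], am1),
               class = "fm_data_error")
})

test_that("count_significant saturates at the alpha extremes", {
  rep2 <- agreement_from_summary(reference_agreement_stats())
  expect_equal(count_significant(rep2, alpha = 1.0), 9)
  expect_equal(count_significant(rep2, alpha = 0), 0)
})

test_that("all exactly printed p-values are reproduced from the difference rows", {
  rep2 <- agreement_from_summary(reference_agreement_stats())
  printed <- rbind(
    c("M2", "AM1", 0.029), c("M3", "AM1", 0.983), c("M4", "AM1", 0.037),
    c("M5", "AM1", 0.079), c("M6", "AM1", 0.366), c("M7", "AM1", 0.035),
    c("M9", "AM1", 0.610),
    c("M2", "AM2", 0.330), c("M3", "AM2", 0.244), c("M4", "AM2", 0.304),
    c("M5", "AM2", 0.216), c("M6", "AM2", 0.021), c("M7", "AM2", 0.152),
    c("M8", "AM2", 0.001), c("M9", "AM2", 0.072))
  for (i in seq_len(nrow(printed))) {
    row <- rep2[rep2$measurement == printed[i, 1] &
                  rep2$version == printed[i, 2], ]
    if (printed[i, 1] == "M8") {
      expect_lt(row$p, 0.001)   # printed as p < 0.001
    } else {
      expect_lt(abs(row$p - as.numeric(printed[i, 3])), 0.01)
    }
  }
})
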