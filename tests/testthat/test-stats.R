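# Statistics and imaging metrology.

test_that("exact Wilcoxon enumerates the tied-rank null", {
  # oracle: all C(4,2) rank assignments of {1,2} vs {3,4}
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), "less")$p_value, 1 / 6)
  # identical samples: p = 1
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty sample")
})

test_that("exact enumeration agrees with the reference test when tie-free", {
  set.seed(1)
  for (i in 1:10) {
    x <- stats::rnorm(sample(3:6, 1)); y <- stats::rnorm(sample(3:6, 1), 0.5)
    ours <- wilcoxon_rank_sum(x, y)$p_value
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("large-sample p-values agree with the reference approximation", {
  set.seed(2)
  x <- stats::rnorm(25); y <- stats::rnorm(30, 0.4)
  ours <- wilcoxon_rank_sum(x, y)$p_value
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("rank-sum p-values are uniform under the null", {
  set.seed(3)
  p <- replicate(1000, wilcoxon_rank_sum(stats::rnorm(30), stats::rnorm(32),
                                         exact_max = 0)$p_value)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.05)
})

test_that("empirical ROC and trapezoid AUC match concordance counting", {
  r <- empirical_roc_auc(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)                       # 3 of 4 concordant pairs
  expect_equal(empirical_roc_auc(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE),
                                 direction = "<")$auc, 0.25)
  perfect <- empirical_roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$fpr[1], 0); expect_equal(rev(perfect$tpr)[1], 1)
  expect_true(all(diff(perfect$fpr) >= 0) && all(diff(perfect$tpr) >= 0))
  expect_error(empirical_roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC equals the Mann-Whitney concordance estimator", {
  set.seed(4)
  for (i in 1:20) {
    pos <- stats::rnorm(7, 1); neg <- stats::rnorm(9)
    auc <- empirical_roc_auc(c(pos, neg),
                             rep(c(TRUE, FALSE), c(7, 9)))$auc
    u <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(auc, u, tolerance = 1e-12)
  }
})

test_that("AUC agrees with the independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- stats::rnorm(40); labs <- stats::runif(40) < 0.5
  labs[1:2] <- c(TRUE, FALSE)
  ours <- empirical_roc_auc(scores, labs)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(labs, scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})

test_that("Krippendorff's alpha matches hand-computed coincidences", {
  # unanimous 8 x 48: perfect agreement
  unanimous <- matrix(rep(sample(c("A", "B", "C"), 48, replace = TRUE),
                          each = 8), nrow = 8)
  expect_equal(krippendorff_alpha(unanimous)$alpha, 1)
  # 2 graders, items {A,A},{B,B},{A,B}: D_o = 2, D_e = 18/5, alpha = 4/9
  m <- matrix(c("A", "A", "B", "B", "A", "B"), nrow = 2)
  expect_equal(krippendorff_alpha(m)$alpha, 1 - 2 / (18 / 5))
  # invariance to label renaming (nominal metric)
  m2 <- m; m2[m == "A"] <- "Z"; m2[m == "B"] <- "Q"
  expect_equal(krippendorff_alpha(m2)$alpha, krippendorff_alpha(m)$alpha)
  # independent uniform ratings: alpha near 0
  set.seed(6)
  big <- matrix(sample(c("x", "y"), 2 * 10000, replace = TRUE), nrow = 2)
  expect_lt(abs(krippendorff_alpha(big)$alpha), 0.05)
  # missing ratings allowed; unpairable-only input rejected
  mm <- matrix(c("A", NA, NA, "B"), nrow = 2)
  expect_error(krippendorff_alpha(mm), "no pairable")
})

test_that("the bootstrap CI is seeded and brackets the estimate", {
  set.seed(7)
  m <- matrix(sample(c("A", "B"), 8 * 48, replace = TRUE, prob = c(0.8, 0.2)),
              nrow = 8)
  m[, 1:30] <- "A"
  r1 <- krippendorff_alpha(m, bootstrap_n = 500, seed = 42)
  r2 <- krippendorff_alpha(m, bootstrap_n = 500, seed = 42)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$alpha + 1e-9)
  expect_gte(r1$ci[2], r1$alpha - 1e-9)
})

test_that("classification metrics reproduce confusion-matrix arithmetic", {
  calls <- rep(c("P", "N", "P", "N"), c(9, 1, 2, 8))
  truth <- rep(c("P", "N"), c(10, 10))
  m <- classification_metrics(calls, truth, positive_set = "P")
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 85)
  all_ok <- classification_metrics(truth, truth, positive_set = "P")
  expect_equal(unlist(all_ok[1:3]), c(accuracy = 100, sensitivity = 100,
                                      specificity = 100))
  expect_error(classification_metrics(calls, truth, positive_set = "Z"),
               "empty positive class")
  expect_error(classification_metrics(calls[1:3], truth), "length mismatch")
})

test_that("FWHM estimators recover known widths", {
  x <- seq(-60, 60)
  g <- exp(-x^2 / (2 * 10^2))
  expect_equal(fwhm_of_profile(g, method = "gaussian_fit"),
               2 * sqrt(2 * log(2)) * 10, tolerance = 1e-4)
  expect_equal(fwhm_of_profile(g, method = "linear_crossing"),
               2 * sqrt(2 * log(2)) * 10, tolerance = 0.02)
  # triangle of half-width w has linear-crossing FWHM exactly w
  tri <- pmax(0, 1 - abs(x) / 20)
  expect_equal(fwhm_of_profile(tri, method = "linear_crossing"), 20,
               tolerance = 1e-9)
  # spacing propagates to physical units
  expect_equal(fwhm_of_profile(g, spacing = 2.5, method = "linear_crossing"),
               2.5 * 2 * sqrt(2 * log(2)) * 10, tolerance = 0.05)
  expect_error(fwhm_of_profile(rep(1, 10)), "flat profile")
})

test_that("spectral band limits recover a constructed transducer spectrum", {
  # Gaussian magnitude spectrum: centre 68.5 MHz, -6 dB width 100 MHz
  fs <- 400e6; n <- 4096
  f <- (0:(n - 1)) * fs / n
  f2 <- pmin(f, fs - f)
  sigma <- 50e6 / sqrt(2 * log(10^(6 / 20)))
  mag <- exp(-(f2 - 68.5e6)^2 / (2 * sigma^2))
  x <- Re(stats::fft(mag * exp(-2i * pi * f * 1e-6), inverse = TRUE)) / n
  b <- spectral_band_limits(x, fs)
  expect_equal(b$f_centre / 1e6, 68.5, tolerance = 0.02)
  expect_equal(b$bandwidth / 1e6, 100, tolerance = 0.03)
  expect_equal(b$f_lo / 1e6, 18.5, tolerance = 0.1)
  expect_equal(b$f_hi / 1e6, 118.5, tolerance = 0.02)
  # pure tone: centre at the tone frequency
  tone <- sin(2 * pi * 50e6 * (0:2047) / fs)
  expect_equal(spectral_band_limits(tone, fs)$f_centre / 1e6, 50,
               tolerance = 0.01)
})

test_that("in-air axial resolution converts to tissue by the refractive index", {
  # synthetic mirror A-scan whose FWHM is the printed in-air value
  spacing <- 0.25
  x <- seq(-30, 30, by = spacing)
  sigma <- 9.75 / (2 * sqrt(2 * log(2)))
  prof <- exp(-x^2 / (2 * sigma^2))
  fwhm_air <- fwhm_of_profile(prof, spacing = spacing, method = "gaussian_fit")
  expect_equal(fwhm_air, 9.75, tolerance = 1e-3)
  expect_equal(fwhm_air / 1.38, 7, tolerance = 0.1)
})

test_that("box statistics follow the type-7 quartile and 1.5 IQR fences", {
  b <- box_stats(1:9)
  expect_equal(b$median, 5)
  expect_equal(b$q1, 3)            # type-7 linear interpolation
  expect_equal(b$q3, 7)
  expect_equal(b$whiskers, c(1, 9))
  expect_equal(length(b$outliers), 0)
  bc <- box_stats(rep(4, 6))
  expect_equal(bc$q3 - bc$q1, 0)
  expect_equal(length(bc$outliers), 0)
  bo <- box_stats(c(1, 2, 3, 100))
  expect_true(100 %in% bo$outliers)  # beyond Q3 + 1.5 IQR
  expect_equal(bo$whiskers[2], 3)
})

test_that("ratings tables round-trip through CSV", {
  m <- matrix(sample(c("A", "B"), 8 * 12, replace = TRUE), nrow = 8)
  colnames(m) <- paste0("item", 1:12)
  path <- tempfile(fileext = ".csv")
  write_ratings(m, path)
  back <- read_ratings(path)
  expect_equal(unname(back), unname(m))
  expect_equal(krippendorff_alpha(back)$alpha, krippendorff_alpha(m)$alpha)
})
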