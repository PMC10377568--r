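test_that("the omnibus normality statistic matches an independent reference", {
  # frozen values from scipy.stats.normaltest / skewtest / kurtosistest
  r1 <- dagostino_normality(sin(1:30))
  expect_equal(r1$statistic, 18.607759537316372, tolerance = 1e-12)
  expect_equal(r1$p.value, 9.107021380769058e-05, tolerance = 1e-10)
  expect_equal(r1$z_skew, -0.0818883241060907, tolerance = 1e-10)
  expect_equal(r1$z_kurt, -4.312893905452749, tolerance = 1e-10)
  r2 <- dagostino_normality(sin(1:50)^3 + 0.1 * (1:50))
  expect_equal(r2$statistic, 5.9408367675597695, tolerance = 1e-12)
  expect_equal(r2$p.value, 0.051281850348589356, tolerance = 1e-10)
})

test_that("normality verdicts separate normal from skewed samples", {
  x <- withr::with_seed(1, rnorm(1000))
  expect_true(dagostino_normality(x)$normal)
  y <- withr::with_seed(2, rexp(1000))
  expect_false(dagostino_normality(y)$normal)
  # verdict is correct for most seeds, not just one
  verdicts <- vapply(1:40, function(s)
    dagostino_normality(withr::with_seed(s, rnorm(500)))$normal, logical(1))
  expect_gte(mean(verdicts), 0.9)
  # degenerate and undersized samples
  expect_false(dagostino_normality(rep(1, 20))$normal)
  expect_error(dagostino_normality(rnorm(5)), "n >= 8")
})

test_that("compare_feature picks the gated test and a coherent CI", {
  x <- withr::with_seed(10, rnorm(30))
  y <- withr::with_seed(11, rnorm(30, mean = 5))
  row <- compare_feature(x, y)
  expect_identical(row$test_used, "t")
  expect_true(row$significant)
  expect_true(row$ci_high < 0)  # real - synth with synth 5 sd higher
  # identical samples cannot be significant
  same <- compare_feature(x, x)
  expect_false(same$significant)
  expect_true(same$ci_low <= 0 && same$ci_high >= 0)
  # skewed data routes to the nonparametric path
  a <- withr::with_seed(12, rexp(40))
  b <- withr::with_seed(13, rexp(40))
  rown <- compare_feature(a, b)
  expect_identical(rown$test_used, "mann-whitney")
  # undersized samples cannot pass the normality gate
  small <- compare_feature(rnorm(5), rnorm(5))
  expect_identical(small$test_used, "mann-whitney")
  expect_error(compare_feature(rep(1, 10), rep(1, 10)), "undefined test")
})

test_that("significance is exactly CI exclusion and consistent with the t p-value", {
  withr::with_seed(30, {
    for (i in 1:40) {
      x <- rnorm(25); y <- rnorm(25, mean = runif(1, 0, 1.2))
      row <- compare_feature(x, y)
      expect_identical(row$significant, row$ci_low > 0 || row$ci_high < 0)
      if (row$test_used == "t")
        expect_identical(row$p_value < 0.05, row$significant)
    }
  })
})

test_that("swapping the groups negates the CI and keeps significance", {
  x <- withr::with_seed(21, rnorm(30, 1))
  y <- withr::with_seed(22, rnorm(30))
  r1 <- compare_feature(x, y)
  r2 <- compare_feature(y, x)
  expect_equal(r1$ci_low, -r2$ci_high, tolerance = 1e-8)
  expect_equal(r1$ci_high, -r2$ci_low, tolerance = 1e-8)
  expect_identical(r1$significant, r2$significant)
  a <- withr::with_seed(23, rexp(30))
  b <- withr::with_seed(24, rexp(30) + 1)
  r3 <- compare_feature(a, b)
  r4 <- compare_feature(b, a)
  expect_equal(r3$ci_low, -r4$ci_high, tolerance = 1e-6)
  expect_identical(r3$significant, r4$significant)
})

test_that("build_report yields 23 grouped rows and flags no self-differences", {
  ds <- generate_phantom_dataset(12, size = 32, base_seed = 40)
  feats <- t(vapply(ds, function(p) extract_features(p$image_A, p$mask),
                    numeric(23)))
  rep0 <- build_report(feats, feats)
  expect_s3_class(rep0, "comparison_report")
  expect_equal(nrow(rep0), 23)
  expect_equal(sum(rep0$significant), 0)
  expect_equal(as.vector(table(rep0$family)[c("GLCM", "GLRLM", "GLSZM")]),
               c(8, 7, 8))
  expect_identical(rep0$feature, feature_catalog()$display)
  expect_error(build_report(feats[1, , drop = FALSE], feats), "at least 2")
})
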