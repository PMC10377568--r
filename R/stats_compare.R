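# Per-feature statistical comparison of real versus synthetic radiomic
# feature distributions.  The test choice is gated on normality: when both
# groups pass the D'Agostino-Pearson omnibus test, an unpaired Welch t-test
# with a 95% CI of the mean difference is used; otherwise the Mann-Whitney U
# test with the Hodges-Lehmann estimate and its distribution-free CI.
# Significance is declared exactly when the CI of the difference excludes 0.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness z-score (D'Agostino 1970) and the kurtosis z-score
#' (Anscombe-Glynn 1983) into the omnibus statistic `K^2 = z_s^2 + z_k^2`,
#' referred to a chi-squared distribution with 2 degrees of freedom.  A
#' constant (zero-variance) sample is treated as not normal.
#'
#' @param x Numeric sample of at least 8 values (the omnibus statistic is not
#'   defined below that).
#' @param alpha Significance level for the verdict (default 0.05).
#'
#' @return List with `normal` (logical verdict: `p >= alpha`), `statistic`
#'   (K^2), `p.value`, and the component z-scores `z_skew`, `z_kurt`.
#' @examples
#' x <- withr::with_seed(1, rnorm(100))
#' dagostino_normality(x)$normal
#' @export
dagostino_normality <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8)
    stop("insufficient sample: the omnibus test requires n >= 8", call. = FALSE)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) {
    return(list(normal = FALSE, statistic = NA_real_, p.value = 0,
                z_skew = NA_real_, z_kurt = NA_real_, degenerate = TRUE))
  }
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)

  # skewness z (D'Agostino)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  a <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- .Machine$double.eps
  z_skew <- delta * log(y / a + sqrt((y / a)^2 + 1))

  # kurtosis z (Anscombe-Glynn)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- (term1 - term2) / sqrt(2 / (9 * A))

  k2 <- z_skew^2 + z_kurt^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(normal = p >= alpha, statistic = k2, p.value = p,
       z_skew = z_skew, z_kurt = z_kurt, degenerate = FALSE)
}

# distribution-free Hodges-Lehmann CI from sorted pairwise differences
# (normal-approximation rank indices); fallback when wilcox.test cannot
# produce an interval (heavy ties)
.hl_ci_manual <- function(x, y, conf.level) {
  d <- sort(as.vector(outer(x, y, "-")))
  m <- length(x); n <- length(y); mn <- length(d)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  se <- sqrt(m * n * (m + n + 1) / 12)
  k <- max(1, floor(m * n / 2 - z * se))
  list(estimate = stats::median(d), ci = c(d[k], d[mn + 1 - k]))
}

#' Compare one feature between real and synthetic groups
#'
#' Applies the normality-gated comparison: if *both* samples pass
#' [dagostino_normality()] at `alpha`, an unpaired Welch t-test with a
#' `1 - alpha` CI of the mean difference (real minus synthetic); otherwise
#' the Mann-Whitney U test with the Hodges-Lehmann estimate of the location
#' difference and its distribution-free CI.  Samples too small for the
#' normality test (n < 8) fall back to the nonparametric path.  The
#' `significant` flag is exactly "the CI excludes 0".
#'
#' @param x_real,x_synth Numeric samples (each of size >= 2).
#' @param alpha Significance level (default 0.05).
#' @param feature Optional feature name recorded in the output row.
#'
#' @return A one-row data frame (a `ComparisonRow`): `feature`, `mean_real`,
#'   `se_real`, `mean_synth`, `se_synth`, `test_used` ("t" or
#'   "mann-whitney"), `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `significant`.
#' @export
compare_feature <- function(x_real, x_synth, alpha = 0.05, feature = NA_character_) {
  if (length(x_real) < 2 || length(x_synth) < 2)
    stop("both samples must have size >= 2", call. = FALSE)
  if (stats::sd(x_real) == 0 && stats::sd(x_synth) == 0 &&
      x_real[1] == x_synth[1])
    stop("undefined test: both samples are a single identical constant", call. = FALSE)

  pass <- function(v) {
    if (length(v) < 8) return(FALSE)
    dagostino_normality(v, alpha)$normal
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))

  if (pass(x_real) && pass(x_synth)) {
    tt <- stats::t.test(x_real, x_synth, var.equal = FALSE, conf.level = 1 - alpha)
    test_used <- "t"
    est <- unname(tt$estimate[1] - tt$estimate[2])
    ci <- as.numeric(tt$conf.int)
    p <- tt$p.value
  } else {
    wt <- tryCatch(
      suppressWarnings(stats::wilcox.test(x_real, x_synth, conf.int = TRUE,
                                          conf.level = 1 - alpha,
                                          exact = FALSE, correct = TRUE)),
      error = function(e) NULL)
    test_used <- "mann-whitney"
    if (is.null(wt) || any(!is.finite(wt$conf.int))) {
      hl <- .hl_ci_manual(x_real, x_synth, 1 - alpha)
      est <- hl$estimate
      ci <- hl$ci
      p <- tryCatch(
        suppressWarnings(stats::wilcox.test(x_real, x_synth, exact = FALSE)$p.value),
        error = function(e) NA_real_)
    } else {
      est <- unname(wt$estimate)
      ci <- as.numeric(wt$conf.int)
      p <- wt$p.value
    }
  }
  data.frame(
    feature = feature,
    mean_real = mean(x_real), se_real = se(x_real),
    mean_synth = mean(x_synth), se_synth = se(x_synth),
    test_used = test_used,
    estimate = est, ci_low = ci[1], ci_high = ci[2],
    p_value = p,
    significant = ci[1] > 0 || ci[2] < 0,
    stringsAsFactors = FALSE
  )
}

#' Build the 23-feature real-versus-synthetic comparison report
#'
#' Runs [compare_feature()] on every radiomic feature, producing one row per
#' feature grouped GLCM, GLRLM, GLSZM.  Input feature sets may be matrices
#' (one row per image, 23 named columns as produced by [extract_features()])
#' or lists of such feature vectors.
#'
#' @param features_real,features_synth Feature matrices or lists of feature
#'   vectors.
#' @param alpha Significance level (default 0.05).
#'
#' @return Object of class `comparison_report`: a 23-row data frame with a
#'   `family` column plus the [compare_feature()] columns, and attributes
#'   `alpha`, `n_real`, `n_synth`.
#' @export
build_report <- function(features_real, features_synth, alpha = 0.05) {
  as_mat <- function(f) {
    if (is.list(f) && !is.data.frame(f)) f <- do.call(rbind, f)
    as.matrix(f)
  }
  fr <- as_mat(features_real)
  fs <- as_mat(features_synth)
  if (nrow(fr) < 2 || nrow(fs) < 2)
    stop("each group needs at least 2 feature vectors", call. = FALSE)
  cat23 <- feature_catalog()
  missing <- setdiff(cat23$name, colnames(fr))
  if (length(missing))
    stop("feature columns missing: ", paste(missing, collapse = ", "), call. = FALSE)

  rows <- lapply(seq_len(nrow(cat23)), function(k) {
    nm <- cat23$name[k]
    row <- tryCatch(
      compare_feature(fr[, nm], fs[, nm], alpha, feature = cat23$display[k]),
      error = function(e) data.frame(
        feature = cat23$display[k], mean_real = mean(fr[, nm]),
        se_real = 0, mean_synth = mean(fs[, nm]), se_synth = 0,
        test_used = "none", estimate = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, significant = FALSE,
        stringsAsFactors = FALSE))
    cbind(family = cat23$family[k], row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_real") <- nrow(fr)
  attr(out, "n_synth") <- nrow(fs)
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Radiomic comparison report (alpha = %.3g, n = %d real / %d synthetic)\n",
              attr(x, "alpha"), attr(x, "n_real"), attr(x, "n_synth")))
  cat(sprintf("%d of %d features significantly different\n\n",
              sum(x$significant), nrow(x)))
  df <- as.data.frame(x)
  df$mean_real <- sprintf("%.4g ± %.2g", x$mean_real, x$se_real)
  df$mean_synth <- sprintf("%.4g ± %.2g", x$mean_synth, x$se_synth)
  df$ci <- sprintf("[%.4g, %.4g]%s", x$ci_low, x$ci_high,
                   ifelse(x$significant, " *", ""))
  print(df[, c("family", "feature", "mean_real", "mean_synth", "test_used", "ci")],
        right = FALSE)
  invisible(x)
}
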