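make_q <- function(levels, n_bins, mask = NULL) {
  if (is.null(mask)) mask <- (levels > 0) + 0
  structure(list(levels = levels, n_bins = as.integer(n_bins),
                 bin_edges = seq(0, 1, length.out = n_bins + 1), mask = mask),
            class = "quantized_image")
}

test_that("GLCM counts pixel pairs symmetrically and normalizes", {
  q <- make_q(matrix(c(1L, 1L, 1L, 2L), 2, byrow = TRUE), 2)
  M <- glcm_matrix(q, 1, matrix(c(0, 1), 1))
  expect_equal(M$p, matrix(c(0.5, 0.25, 0.25, 0), 2, byrow = TRUE))
  # constant image concentrates all mass at (1, 1)
  Mc <- glcm_matrix(make_q(matrix(1L, 3, 3), 2))
  expect_equal(Mc$p[1, 1], 1)
  # symmetry and unit mass on random inputs
  withr::with_seed(7, {
    for (i in 1:10) {
      lev <- matrix(sample(0:4, 64, replace = TRUE), 8)
      if (sum(lev > 0) < 4) next
      M <- glcm_matrix(make_q(lev, 4))
      expect_equal(sum(M$p), 1, tolerance = 1e-12)
      expect_equal(M$p, t(M$p), tolerance = 1e-12)
      expect_true(all(M$p >= 0))
    }
  })
})

test_that("GLCM features match hand computations and analytic limits", {
  q <- make_q(matrix(c(1L, 1L, 1L, 2L), 2, byrow = TRUE), 2)
  f <- glcm_features(glcm_matrix(q, 1, matrix(c(0, 1), 1)))
  expect_equal(unname(f["contrast"]), 0.5)
  expect_equal(unname(f["energy"]), 0.375)
  # constant image limits
  fc <- glcm_features(glcm_matrix(make_q(matrix(1L, 4, 4), 3)))
  expect_equal(unname(fc["contrast"]), 0)
  expect_equal(unname(fc["energy"]), 1)
  expect_equal(unname(fc["entropy"]), 0)
  expect_equal(unname(fc["homogeneity"]), 1)
  expect_equal(unname(fc["correlation"]), 0)  # degenerate-by-convention
  expect_true(attr(fc, "degenerate_correlation"))
  # uniform joint distribution maximizes entropy at 2 log2 B
  for (B in c(2, 4, 8)) {
    Mu <- structure(list(p = matrix(1 / B^2, B, B), offsets_used = NULL,
                         radius = 1), class = "glc_matrix")
    expect_equal(unname(glcm_features(Mu)["entropy"]), 2 * log2(B))
  }
})

test_that("GLRLM accumulates maximal runs and its features check out", {
  q <- make_q(matrix(c(1L, 1L, 2L), 1), 2)
  R <- glrlm_matrix(q, matrix(c(0, 1), 1))
  expect_equal(R$n_runs, 2)
  expect_equal(R$r[1, 2], 1)
  expect_equal(R$r[2, 1], 1)
  f <- glrlm_features(R)
  expect_equal(unname(f["short_run_emphasis"]), 0.625)
  expect_equal(unname(f["high_grey_level_run_emphasis"]), 2.5)
  expect_equal(unname(f["grey_level_nonuniformity"]), 1)
  expect_equal(unname(f["run_length_nonuniformity"]), 1)
  # one constant row is a single run of its length
  Rc <- glrlm_matrix(make_q(matrix(2L, 1, 5), 2), matrix(c(0, 1), 1))
  expect_equal(Rc$n_runs, 1)
  expect_equal(Rc$r[2, 5], 1)
  fc <- glrlm_features(Rc)
  expect_equal(unname(fc["grey_level_nonuniformity"]), 1)
  expect_equal(unname(fc["short_run_emphasis"]), 1 / 25)
  # runs partition pixels: sum j r(i,j) = pixels x directions
  withr::with_seed(11, {
    for (i in 1:10) {
      lev <- matrix(sample(0:3, 100, replace = TRUE), 10)
      if (sum(lev > 0) < 4) next
      R <- glrlm_matrix(make_q(lev, 3))
      expect_equal(sum(t(R$r) * seq_len(ncol(R$r))), 4 * sum(lev > 0))
      expect_equal(sum(R$r), R$n_runs)
    }
  })
})

test_that("GLSZM labels connected zones and its features check out", {
  q <- make_q(matrix(c(1L, 1L, 1L, 2L), 2, byrow = TRUE), 2)
  S <- glszm_matrix(q, 8)
  expect_equal(S$n_zones, 2)
  expect_equal(S$s[1, 3], 1)
  expect_equal(S$s[2, 1], 1)
  f <- glszm_features(S)
  expect_equal(unname(f["grey_level_mean"]), 1.5)
  expect_equal(unname(f["grey_level_variance"]), 0.25)
  expect_equal(unname(f["large_zone_emphasis"]), 5)
  expect_equal(unname(f["high_grey_level_emphasis"]), 2.5)
  expect_equal(unname(f["large_zone_low_grey_level_emphasis"]), 4.625)
  # constant mask = one zone covering all in-mask pixels
  Sc <- glszm_matrix(make_q(matrix(1L, 4, 4), 2), 8)
  expect_equal(Sc$n_zones, 1)
  expect_equal(Sc$s[1, 16], 1)
  # 4- vs 8-connectivity: diagonal pair merges only under 8
  lev <- matrix(0L, 3, 3); lev[1, 1] <- 1L; lev[2, 2] <- 1L
  expect_equal(glszm_matrix(make_q(lev, 2, mask = matrix(1, 3, 3)), 8)$n_zones, 1)
  expect_equal(glszm_matrix(make_q(lev, 2, mask = matrix(1, 3, 3)), 4)$n_zones, 2)
  # zones partition pixels
  withr::with_seed(13, {
    for (i in 1:10) {
      lev <- matrix(sample(0:3, 144, replace = TRUE), 12)
      if (sum(lev > 0) < 4) next
      S <- glszm_matrix(make_q(lev, 3))
      expect_equal(sum(t(S$s) * seq_len(ncol(S$s))), sum(lev > 0))
    }
  })
})

test_that("extract_features returns 23 finite named values with stable order", {
  pair <- generate_phantom_pair(32, tissue_model(seed = 5))
  f <- extract_features(pair$image_A, pair$mask)
  expect_length(f, 23)
  expect_true(all(is.finite(f)))
  expect_identical(names(f), feature_catalog()$name)
  expect_identical(feature_catalog()$family,
                   c(rep("GLCM", 8), rep("GLRLM", 7), rep("GLSZM", 8)))
})

test_that("features are invariant under 90-degree rotation with combined offsets", {
  withr::with_seed(21, {
    for (i in 1:5) {
      img <- matrix(runif(16 * 16), 16)
      mask <- matrix(1, 16, 16)
      f1 <- extract_features(img, mask, n_bins = 6)
      rot <- t(img)[ncol(img):1, ]  # 90-degree rotation
      f2 <- extract_features(rot, mask, n_bins = 6)
      expect_equal(f1, f2, tolerance = 1e-12)
    }
  })
})

test_that("pixels outside the mask never influence the features", {
  withr::with_seed(31, {
    rm <- random_masked_image(99, size = 16)
    f1 <- extract_features(rm$image, rm$mask, n_bins = 5, normalize = FALSE)
    pert <- rm$image
    pert[rm$mask == 0] <- runif(sum(rm$mask == 0))
    f2 <- extract_features(pert, rm$mask, n_bins = 5, normalize = FALSE)
    expect_equal(f1, f2, tolerance = 1e-14)
  })
})

test_that("feature bounds hold on random images", {
  withr::with_seed(41, {
    for (i in 1:10) {
      rm <- random_masked_image(i + 500, size = 12)
      B <- 6
      q <- quantize(rm$image, rm$mask, B)
      fg <- glcm_features(glcm_matrix(q))
      expect_true(fg["energy"] > 0 && fg["energy"] <= 1)
      expect_true(fg["homogeneity"] > 0 && fg["homogeneity"] <= 1)
      expect_true(fg["entropy"] >= 0 && fg["entropy"] <= 2 * log2(B) + 1e-12)
      fr <- glrlm_features(glrlm_matrix(q))
      expect_true(fr["short_run_emphasis"] > 0 &&
                    fr["short_run_emphasis"] <= 1 + 1e-12)
    }
  })
})

test_that("matrices and features match the brute-force oracle on small images", {
  # deeper sweep lives in the acceptance suite; spot-check here
  for (seed in 1:10) {
    rm <- random_masked_image(seed, size = 12)
    B <- 5
    q <- quantize(rm$image, rm$mask, B)
    offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
    expect_equal(glcm_matrix(q)$p, oracle_glcm(q$levels, B, offs),
                 tolerance = 1e-12)
    R <- glrlm_matrix(q)
    expect_equal(R$r, oracle_glrlm(q$levels, B, offs), ignore_attr = TRUE,
                 tolerance = 1e-12)
    S <- glszm_matrix(q)
    expect_equal(S$s, oracle_glszm(q$levels, B, 8), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(unname(extract_features(rm$image, rm$mask, n_bins = B)),
                 unname(oracle_features(rm$image, rm$mask, B)),
                 tolerance = 1e-10)
  }
})
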