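const_batch <- function(v, n = 2, size = 8) {
  lapply(seq_len(n), function(i) matrix(v, size, size))
}

test_that("cycle-consistency loss follows its algebra", {
  batch <- const_batch(0.5)
  expect_equal(cycle_consistency_loss(identity, identity, batch, batch), 0)
  # one generator shifts by +0.1 (in range), the other is the identity:
  # both round trips miss by 0.1
  add1 <- function(x) x + 0.1
  expect_equal(cycle_consistency_loss(add1, identity, batch, batch), 0.2)
  withr::with_seed(50, {
    spec <- gan_spec(image_size = 16, base_channels = 2, n_res_blocks = 1)
    G1 <- build_generator(spec)
    G2 <- build_generator(spec)
    imgs <- lapply(1:3, function(i) matrix(runif(256), 16))
  })
  expect_gte(cycle_consistency_loss(G1, G2, imgs, imgs), 0)
  expect_error(cycle_consistency_loss(function(x) matrix(0, 2, 2), identity,
                                      batch, batch), "shape")
})

test_that("adversarial loss matches closed forms and stays finite", {
  half <- function(x) matrix(0.5, 4, 4)
  al <- adversarial_loss(half, const_batch(0.2), const_batch(0.8))
  expect_equal(al$discriminator, 2 * log(2), tolerance = 1e-12)
  expect_equal(al$generator, log(2), tolerance = 1e-12)
  # a perfect discriminator's loss vanishes (up to the clamp)
  perfect <- local({
    i <- 0
    function(x) matrix(mean(x) > 0.5, 4, 4)  # 1 on "real" (0.8), 0 on fake (0.2)
  })
  al2 <- adversarial_loss(perfect, const_batch(0.8), const_batch(0.2))
  expect_lt(al2$discriminator, 1e-6)
  # extreme scores stay finite under the clamp
  zero <- function(x) matrix(0, 4, 4)
  al3 <- adversarial_loss(zero, const_batch(0.5), const_batch(0.5))
  expect_true(is.finite(al3$generator) && is.finite(al3$discriminator))
  # least-squares form
  al4 <- adversarial_loss(half, const_batch(0.5), const_batch(0.5), form = "lsgan")
  expect_equal(al4$discriminator, 0.25 + 0.25)
})

test_that("the full objective is exactly linear in its two weights", {
  withr::with_seed(51, {
    spec <- gan_spec(image_size = 16, base_channels = 2, n_res_blocks = 1)
    pair <- list(G_A2B = build_generator(spec), G_B2A = build_generator(spec),
                 D_A = build_discriminator(spec), D_B = build_discriminator(spec))
    bA <- lapply(1:2, function(i) matrix(runif(256), 16))
    bB <- lapply(1:2, function(i) matrix(runif(256), 16))
  })
  t1 <- cyclegan_total_loss(pair, bA, bB, spec)
  comp <- attr(t1, "components")
  expect_equal(as.numeric(t1),
               spec$lambda_gan * comp["adversarial"] + spec$lambda_cyc * comp["cycle"],
               ignore_attr = TRUE)
  # doubling lambda_cyc doubles exactly the cycle contribution
  spec2 <- spec; spec2$lambda_cyc <- 20
  t2 <- cyclegan_total_loss(pair, bA, bB, spec2)
  expect_equal(as.numeric(t2 - t1), 10 * comp[["cycle"]], tolerance = 1e-12)
  spec3 <- spec; spec3$lambda_gan <- 3
  t3 <- cyclegan_total_loss(pair, bA, bB, spec3)
  expect_equal(as.numeric(t3 - t1), 2 * comp[["adversarial"]], tolerance = 1e-12)
  # defaults carry the reference weights
  expect_equal(gan_spec()$lambda_cyc, 10)
  expect_equal(gan_spec()$lambda_gan, 1)
  # identity generators with a fixed discriminator leave only the adversarial part
  pid <- list(G_A2B = identity, G_B2A = identity,
              D_A = function(x) matrix(0.5, 2, 2),
              D_B = function(x) matrix(0.5, 2, 2))
  t4 <- cyclegan_total_loss(pid, bA, bB, spec)
  expect_equal(attr(t4, "components")[["cycle"]], 0)
  expect_equal(as.numeric(t4), spec$lambda_gan * 2 * log(2), tolerance = 1e-12)
})

test_that("auxiliary losses vanish on identical pairs and behave on shifts", {
  withr::with_seed(52, {
    tgt <- lapply(1:2, function(i) matrix(runif(256, 0.2, 0.7), 16))
    spec <- gan_spec(image_size = 16, base_channels = 2, n_res_blocks = 1)
    D <- build_discriminator(spec)
  })
  feat <- function(x) net_forward(D, as_tensor3(x), upto = D$feature_layer)$out
  a0 <- auxiliary_losses(tgt, tgt, feature_fn = feat)
  expect_equal(unname(a0), rep(0, 4))
  # constant shift: voxel-wise = c, gradient difference = 0
  shifted <- lapply(tgt, function(x) x + 0.1)
  a1 <- auxiliary_losses(shifted, tgt)
  expect_equal(unname(a1["voxelwise"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(a1["gradient_difference"]), 0, tolerance = 1e-12)
  # structural term is bounded by SSIM's range
  noisy <- lapply(tgt, function(x) clip01(x + matrix(rnorm(256, sd = 0.3), 16)))
  a2 <- auxiliary_losses(noisy, tgt)
  expect_gte(unname(a2["structural"]), 0)
  expect_lte(unname(a2["structural"]), 2)
  expect_error(auxiliary_losses(tgt, list(matrix(0, 2, 2), matrix(0, 2, 2))),
               "shape")
})

test_that("SSIM is 1 on identical images and decreases under noise", {
  x <- matrix(runif(400), 20)
  expect_equal(ssim_index(x, x), 1, tolerance = 1e-9)
  y <- withr::with_seed(53, clip01(x + matrix(rnorm(400, sd = 0.2), 20)))
  expect_lt(ssim_index(x, y), 1)
  expect_gte(ssim_index(x, y), -1)
})

test_that("the supervised objective respects its weights and pairing", {
  withr::with_seed(54, {
    spec <- gan_spec(image_size = 16, base_channels = 2, n_res_blocks = 1,
                     model_kind = "dc2anet")
    pair <- list(G_A2B = build_generator(spec), G_B2A = build_generator(spec),
                 D_A = build_discriminator(spec, TRUE),
                 D_B = build_discriminator(spec, TRUE))
    bA <- lapply(1:2, function(i) matrix(runif(256), 16))
    bB <- lapply(1:2, function(i) matrix(runif(256), 16))
  })
  expect_equal(unname(gan_spec(model_kind = "dc2anet")$sup_weights), rep(1, 6))
  total <- dc2anet_sup_loss(pair, bA, bB, spec)
  terms <- attr(total, "terms")
  expect_equal(as.numeric(total), sum(terms), tolerance = 1e-12)  # unit weights
  # zeroing all but the voxel weight reduces the loss to the L1 terms
  spec_v <- spec
  spec_v$sup_weights <- c(adversarial = 0, cycle = 0, voxel = 1, gradient = 0,
                          perceptual = 0, structural = 0)
  tv <- dc2anet_sup_loss(pair, bA, bB, spec_v)
  expect_equal(as.numeric(tv), terms[["voxel"]], tolerance = 1e-12)
  # identity generators on identical aligned domains: everything but the
  # adversarial term is 0
  pid <- list(G_A2B = identity, G_B2A = identity,
              D_A = pair$D_A, D_B = pair$D_B)
  t0 <- dc2anet_sup_loss(pid, bA, bA, spec)
  tm <- attr(t0, "terms")
  expect_equal(unname(tm[c("cycle", "voxel", "gradient", "structural")]),
               rep(0, 4), tolerance = 1e-12)
  expect_gt(tm[["adversarial"]], 0)
  expect_error(dc2anet_sup_loss(pair, bA, bB[1], spec), "aligned")
})
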