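# Loss algebra of the translation models, plus hand-derived gradients of the
# supervised image-level terms (used by the training loop).

as_batch <- function(x) if (is.list(x)) x else list(x)

#' Cycle-consistency loss
#'
#' Mean L1 of the forward round trip `G_B2A(G_A2B(A))` against `A` plus the
#' backward round trip `G_A2B(G_B2A(B))` against `B`, averaged over the
#' batch.  Identity generators give exactly 0.
#'
#' @param G_A2B,G_B2A Generators: `mri_generator` objects or plain functions
#'   mapping a matrix to a matrix (e.g. `identity`).
#' @param batch_A,batch_B Matrices or lists of matrices.
#' @return Nonnegative scalar.
#' @export
cycle_consistency_loss <- function(G_A2B, G_B2A, batch_A, batch_B) {
  batch_A <- as_batch(batch_A)
  batch_B <- as_batch(batch_B)
  fwd <- mean(vapply(batch_A, function(a) {
    rec <- g_apply(G_B2A, g_apply(G_A2B, a))
    if (!identical(dim(rec), dim(a))) stop("cycle shape mismatch", call. = FALSE)
    mean(abs(rec - a))
  }, numeric(1)))
  bwd <- mean(vapply(batch_B, function(b) {
    rec <- g_apply(G_A2B, g_apply(G_B2A, b))
    if (!identical(dim(rec), dim(b))) stop("cycle shape mismatch", call. = FALSE)
    mean(abs(rec - b))
  }, numeric(1)))
  fwd + bwd
}

# pointwise adversarial loss and its gradient w.r.t. the score map p;
# target 1 = "call it real", 0 = "call it fake"
.adv_terms <- function(p, target, form = "log", eps = 1e-7) {
  n <- length(p)
  if (form == "lsgan") {
    return(list(loss = mean((p - target)^2), dp = 2 * (p - target) / n))
  }
  if (target == 1) {
    pc <- pmax(p, eps)
    list(loss = -mean(log(pc)), dp = -1 / (pc * n))
  } else {
    pc <- pmax(1 - p, eps)
    list(loss = -mean(log(pc)), dp = 1 / (pc * n))
  }
}

#' Adversarial loss (generator and discriminator terms)
#'
#' Binary cross-entropy form (natural logarithm), averaged over the patch
#' score map and the batch: the discriminator minimizes
#' `-log D(real) - log(1 - D(fake))`, the generator minimizes
#' `-log D(fake)`.  Probabilities are clamped to `[eps, 1 - eps]` so both
#' terms stay finite.  A least-squares form is available via `form`.
#'
#' @param D Discriminator: `mri_discriminator` or a function mapping an image
#'   to a score array.
#' @param real_batch,fake_batch Matrices or lists of matrices.
#' @param form `"log"` (default) or `"lsgan"`.
#' @param eps Probability clamp.
#' @return List with `generator` and `discriminator` loss values.
#' @export
adversarial_loss <- function(D, real_batch, fake_batch, form = c("log", "lsgan"),
                             eps = 1e-7) {
  form <- match.arg(form)
  real_batch <- as_batch(real_batch)
  fake_batch <- as_batch(fake_batch)
  p_real <- unlist(lapply(real_batch, function(x) as.vector(d_apply(D, x))))
  p_fake <- unlist(lapply(fake_batch, function(x) as.vector(d_apply(D, x))))
  gen <- .adv_terms(p_fake, 1, form, eps)$loss
  disc <- .adv_terms(p_real, 1, form, eps)$loss + .adv_terms(p_fake, 0, form, eps)$loss
  list(generator = gen, discriminator = disc)
}

#' Full CycleGAN generator objective
#'
#' `lambda_gan` times the two generator-side adversarial terms plus
#' `lambda_cyc` times the cycle-consistency loss; exactly linear in the two
#' weights.
#'
#' @param pair A `translator_pair` (or any list with `G_A2B`, `G_B2A`, `D_A`,
#'   `D_B`).
#' @param batch_A,batch_B Matrices or lists of matrices.
#' @param spec A [gan_spec()] supplying `lambda_cyc`, `lambda_gan`,
#'   `adv_form`.
#' @return Scalar total with attribute `"components"` (adversarial, cycle).
#' @export
cyclegan_total_loss <- function(pair, batch_A, batch_B, spec) {
  batch_A <- as_batch(batch_A)
  batch_B <- as_batch(batch_B)
  fake_B <- lapply(batch_A, function(a) g_apply(pair$G_A2B, a))
  fake_A <- lapply(batch_B, function(b) g_apply(pair$G_B2A, b))
  p_fB <- unlist(lapply(fake_B, function(x) as.vector(d_apply(pair$D_B, x))))
  p_fA <- unlist(lapply(fake_A, function(x) as.vector(d_apply(pair$D_A, x))))
  adv <- .adv_terms(p_fB, 1, spec$adv_form)$loss + .adv_terms(p_fA, 1, spec$adv_form)$loss
  cyc <- cycle_consistency_loss(pair$G_A2B, pair$G_B2A, batch_A, batch_B)
  total <- spec$lambda_gan * adv + spec$lambda_cyc * cyc
  attr(total, "components") <- c(adversarial = adv, cycle = cyc)
  total
}

# ---- SSIM -------------------------------------------------------------------

.ssim_window <- function(k = 11, sigma = 1.5) {
  g <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# valid windowed correlation of a matrix with a k x k kernel
.win_filter <- function(x, w) {
  k <- nrow(w)
  ci <- conv_idx(nrow(x), ncol(x), k, 1L, 0L)
  cols <- matrix(x[as.vector(ci$idx)], nrow = nrow(ci$idx))
  matrix(cols %*% as.vector(w), ci$Ho, ci$Wo)
}

# adjoint of .win_filter: scatter a (Ho x Wo) field back to image support
.win_filter_adj <- function(d, H, W, w) {
  k <- nrow(w)
  ci <- conv_idx(H, W, k, 1L, 0L)
  wv <- as.vector(w)
  out <- numeric(H * W)
  dv <- as.vector(d)
  for (j in seq_len(k * k)) {
    rows <- ci$idx[, j]
    out[rows] <- out[rows] + dv * wv[j]
  }
  matrix(out, H, W)
}

#' Structural similarity index between two images
#'
#' Windowed SSIM with an 11 x 11 Gaussian window (sigma 1.5) and the standard
#' stabilization constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic
#' range `L`.
#'
#' @param x,y Numeric matrices of identical dimensions.
#' @param dynamic_range Intensity range `L` (default 1 for unit-scaled
#'   images).
#' @return Mean SSIM over the valid window positions, in `[-1, 1]`.
#' @export
ssim_index <- function(x, y, dynamic_range = 1) {
  .ssim_parts(x, y, dynamic_range)$mssim
}

.ssim_parts <- function(x, y, dynamic_range = 1) {
  if (!identical(dim(x), dim(y))) stop("SSIM shape mismatch", call. = FALSE)
  w <- .ssim_window()
  if (nrow(x) < nrow(w) || ncol(x) < ncol(w))
    w <- .ssim_window(k = min(dim(x), 11) - (min(dim(x), 11) + 1) %% 2)
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  mx <- .win_filter(x, w); my <- .win_filter(y, w)
  sxx <- .win_filter(x * x, w) - mx^2
  syy <- .win_filter(y * y, w) - my^2
  sxy <- .win_filter(x * y, w) - mx * my
  A1 <- 2 * mx * my + C1; A2 <- 2 * sxy + C2
  B1 <- mx^2 + my^2 + C1; B2 <- sxx + syy + C2
  S <- (A1 * A2) / (B1 * B2)
  list(mssim = mean(S), S = S, mx = mx, my = my, A1 = A1, A2 = A2,
       B1 = B1, B2 = B2, w = w)
}

# gradient of (1 - mean SSIM(x, y)) with respect to x
.ssim_loss_grad <- function(x, y, dynamic_range = 1) {
  p <- .ssim_parts(x, y, dynamic_range)
  H <- nrow(x); W <- ncol(x)
  n <- length(p$S)
  dS_dmx <- 2 * p$my * p$A2 / (p$B1 * p$B2) - 2 * p$mx * p$S / p$B1
  dS_dsxx <- -p$S / p$B2
  dS_dsxy <- 2 * p$A1 / (p$B1 * p$B2)
  g <- .win_filter_adj(dS_dmx, H, W, p$w) +
    2 * x * .win_filter_adj(dS_dsxx, H, W, p$w) -
    2 * .win_filter_adj(dS_dsxx * p$mx, H, W, p$w) +
    y * .win_filter_adj(dS_dsxy, H, W, p$w) -
    .win_filter_adj(dS_dsxy * p$my, H, W, p$w)
  list(loss = 1 - p$mssim, grad = -g / n)
}

# gradient-difference loss: L1 between finite-difference gradient magnitudes
# along rows and columns (averaged over the two directions), plus gradient
.grad_diff_loss_grad <- function(g, t) {
  H <- nrow(g); W <- ncol(g)
  ur <- g[-1, , drop = FALSE] - g[-H, , drop = FALSE]
  tr <- t[-1, , drop = FALSE] - t[-H, , drop = FALSE]
  uc <- g[, -1, drop = FALSE] - g[, -W, drop = FALSE]
  tc <- t[, -1, drop = FALSE] - t[, -W, drop = FALSE]
  lr <- mean(abs(abs(ur) - abs(tr)))
  lc <- mean(abs(abs(uc) - abs(tc)))
  dgr <- sign(abs(ur) - abs(tr)) * sign(ur) / length(ur) / 2
  dgc <- sign(abs(uc) - abs(tc)) * sign(uc) / length(uc) / 2
  dg <- matrix(0, H, W)
  dg[-1, ] <- dg[-1, , drop = FALSE] + dgr
  dg[-H, ] <- dg[-H, , drop = FALSE] - dgr
  dg[, -1] <- dg[, -1, drop = FALSE] + dgc
  dg[, -W] <- dg[, -W, drop = FALSE] - dgc
  list(loss = (lr + lc) / 2, grad = dg)
}

#' Auxiliary supervised losses
#'
#' The four aligned-pair losses of the dual cycle-consistent model:
#' voxel-wise (mean L1), gradient difference (mean L1 between
#' finite-difference gradient magnitudes along rows and columns), structural
#' (`1 -` mean SSIM) and perceptual (mean L1 between intermediate
#' discriminator feature maps of generated versus target).  All four are 0
#' when `generated == target`.
#'
#' @param generated,target Aligned matrices or lists of matrices of identical
#'   shapes.
#' @param feature_fn Optional function mapping an image to a feature array
#'   (e.g. discriminator features); without it the perceptual term is `NA`.
#' @return Named numeric vector: `voxelwise`, `gradient_difference`,
#'   `perceptual`, `structural`.
#' @export
auxiliary_losses <- function(generated, target, feature_fn = NULL) {
  gb <- as_batch(generated)
  tb <- as_batch(target)
  if (length(gb) != length(tb)) stop("batch lengths differ", call. = FALSE)
  vox <- gd <- str <- perc <- numeric(length(gb))
  for (i in seq_along(gb)) {
    g <- gb[[i]]; t <- tb[[i]]
    if (!identical(dim(g), dim(t))) stop("shape mismatch", call. = FALSE)
    vox[i] <- mean(abs(g - t))
    gd[i] <- .grad_diff_loss_grad(g, t)$loss
    str[i] <- 1 - ssim_index(g, t)
    perc[i] <- if (is.null(feature_fn)) NA_real_ else {
      fg <- feature_fn(g); ft <- feature_fn(t)
      mean(abs(fg - ft))
    }
  }
  c(voxelwise = mean(vox), gradient_difference = mean(gd),
    perceptual = mean(perc), structural = mean(str))
}

#' Supervised objective of the dual cycle-consistent model
#'
#' Weighted sum (per `spec$sup_weights`, all 1 by default) of the conditional
#' adversarial term, the dual cycle-consistency term, and the four auxiliary
#' losses (voxel-wise, gradient difference, perceptual, structural), with
#' every term accumulated over both mapping directions.  Requires aligned
#' (paired) batches.
#'
#' @param pair A `translator_pair` with conditional discriminators.
#' @param batch_A,batch_B Aligned batches (equal length, matching shapes).
#' @param spec A [gan_spec()].
#' @return Scalar total with attribute `"terms"`, the named breakdown.
#' @export
dc2anet_sup_loss <- function(pair, batch_A, batch_B, spec) {
  batch_A <- as_batch(batch_A)
  batch_B <- as_batch(batch_B)
  if (length(batch_A) != length(batch_B))
    stop("supervised loss needs aligned pairs: batch lengths differ", call. = FALSE)
  w <- spec$sup_weights
  fl_B <- if (inherits(pair$D_B, "mri_discriminator")) pair$D_B$feature_layer else NULL

  adv <- cyc <- vox <- gd <- perc <- str <- 0
  for (i in seq_along(batch_A)) {
    a <- batch_A[[i]]; b <- batch_B[[i]]
    if (!identical(dim(a), dim(b)))
      stop("supervised loss needs aligned pairs: shape mismatch", call. = FALSE)
    fB <- g_apply(pair$G_A2B, a)
    fA <- g_apply(pair$G_B2A, b)
    p_fB <- as.vector(d_apply(pair$D_B, fB, src = a))
    p_fA <- as.vector(d_apply(pair$D_A, fA, src = b))
    adv <- adv + .adv_terms(p_fB, 1, spec$adv_form)$loss +
      .adv_terms(p_fA, 1, spec$adv_form)$loss
    cyc <- cyc + mean(abs(g_apply(pair$G_B2A, fB) - a)) +
      mean(abs(g_apply(pair$G_A2B, fA) - b))
    vox <- vox + mean(abs(fB - b)) + mean(abs(fA - a))
    gd <- gd + .grad_diff_loss_grad(fB, b)$loss + .grad_diff_loss_grad(fA, a)$loss
    str <- str + (1 - ssim_index(fB, b)) + (1 - ssim_index(fA, a))
    perc <- perc + .disc_feature_l1(pair$D_B, a, fB, b) +
      .disc_feature_l1(pair$D_A, b, fA, a)
  }
  n <- length(batch_A)
  terms <- c(adversarial = adv, cycle = cyc, voxel = vox, gradient = gd,
             perceptual = perc, structural = str) / n
  total <- sum(w * terms)
  attr(total, "terms") <- terms
  total
}

# mean L1 between discriminator features of (src, candidate) and (src, target)
.disc_feature_l1 <- function(D, src, candidate, target) {
  if (!inherits(D, "mri_discriminator")) return(0)
  fl <- D$feature_layer
  xg <- array(c(src, candidate), c(dim(src), 2))
  xt <- array(c(src, target), c(dim(src), 2))
  if (!isTRUE(D$conditional)) {
    xg <- as_tensor3(candidate)
    xt <- as_tensor3(target)
  }
  fg <- net_forward(D, xg, upto = fl, keep_cols = FALSE)$out
  ft <- net_forward(D, xt, upto = fl, keep_cols = FALSE)$out
  mean(abs(fg - ft))
}
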