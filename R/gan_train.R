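# Seeded desk-scale training loop for the two translation models.  Per step:
# `gen_iters` generator updates on the current batch, then `disc_iters`
# discriminator updates.  Adam (beta1 = 0.5) with the piecewise-linear
# learning-rate schedule.  The dual cycle-consistent ("dc2anet") model
# alternates one supervised step (conditional adversarial + cycle + the four
# aligned auxiliary losses) and one unsupervised step (cycle + adversarial
# only) across batches.

# gradient of the generator-side objective for one aligned pair (a, b);
# returns parameter gradients for both generators plus the loss components
.gen_pair_grads <- function(G1, G2, D_A, D_B, a, b, spec, supervised) {
  a3 <- as_tensor3(a)
  b3 <- as_tensor3(b)
  npix <- length(a3)
  cond <- spec$model_kind == "dc2anet"
  w <- spec$sup_weights
  w_adv <- if (supervised) w[["adversarial"]] else spec$lambda_gan
  w_cyc <- if (supervised) w[["cycle"]] else spec$lambda_cyc

  f1 <- net_forward(G1, a3)          # fake B
  f2 <- net_forward(G2, f1$out)      # reconstructed A
  f3 <- net_forward(G2, b3)          # fake A
  f4 <- net_forward(G1, f3$out)      # reconstructed B
  fakeB <- f1$out; fakeA <- f3$out

  cyc_l <- mean(abs(f2$out - a3)) + mean(abs(f4$out - b3))
  d_recA <- w_cyc * sign(f2$out - a3) / npix
  d_recB <- w_cyc * sign(f4$out - b3) / npix

  # adversarial push on the fakes (through the discriminators, frozen)
  adv_one <- function(D, fake, src) {
    x <- if (cond) array(c(src, fake), c(dim(src)[1:2], 2)) else fake
    fd <- net_forward(D, x, keep_cols = FALSE)
    at <- .adv_terms(as.vector(fd$out), 1, spec$adv_form)
    dx <- net_backward(D, fd$caches, array(at$dp, dim(fd$out)),
                       param_grads = FALSE)$dx
    dfake <- if (cond) array(dx[, , 2], dim(fake)) else dx
    list(loss = at$loss, dfake = dfake)
  }
  advB <- adv_one(D_B, fakeB, a3)
  advA <- adv_one(D_A, fakeA, b3)
  adv_l <- advB$loss + advA$loss
  d_fakeB <- w_adv * advB$dfake
  d_fakeA <- w_adv * advA$dfake

  sup_terms <- c(voxel = NA_real_, gradient = NA_real_, perceptual = NA_real_,
                 structural = NA_real_)
  if (supervised) {
    fBm <- matrix(fakeB, nrow(a), ncol(a))
    fAm <- matrix(fakeA, nrow(a), ncol(a))
    sup <- .sup_pair_grads(D_B, a, fBm, b, spec) # direction A -> B
    sup2 <- .sup_pair_grads(D_A, b, fAm, a, spec) # direction B -> A
    d_fakeB <- d_fakeB + array(sup$grad, dim(fakeB))
    d_fakeA <- d_fakeA + array(sup2$grad, dim(fakeA))
    sup_terms <- sup$terms + sup2$terms
  }

  bk2 <- net_backward(G2, f2$caches, d_recA)
  bk4 <- net_backward(G1, f4$caches, d_recB)
  d_fakeB <- d_fakeB + bk2$dx
  d_fakeA <- d_fakeA + bk4$dx
  bk1 <- net_backward(G1, f1$caches, d_fakeB)
  bk3 <- net_backward(G2, f3$caches, d_fakeA)

  list(g1 = grads_add(bk4$grads, bk1$grads),
       g2 = grads_add(bk2$grads, bk3$grads),
       adv = adv_l, cycle = cyc_l, sup_terms = sup_terms)
}

# supervised image-level terms for one direction: candidate `g` against
# aligned target `t` with conditioning source `src`; loss gradients w.r.t. g
.sup_pair_grads <- function(D, src, g, t, spec) {
  w <- spec$sup_weights
  n <- length(g)
  vox_l <- mean(abs(g - t))
  grad <- w[["voxel"]] * sign(g - t) / n
  gd <- .grad_diff_loss_grad(g, t)
  grad <- grad + w[["gradient"]] * gd$grad
  ss <- .ssim_loss_grad(g, t)
  grad <- grad + w[["structural"]] * ss$grad
  perc_l <- 0
  if (inherits(D, "mri_discriminator") && w[["perceptual"]] > 0) {
    fl <- D$feature_layer
    xg <- if (isTRUE(D$conditional)) array(c(src, g), c(dim(g), 2)) else as_tensor3(g)
    xt <- if (isTRUE(D$conditional)) array(c(src, t), c(dim(g), 2)) else as_tensor3(t)
    fg <- net_forward(D, xg, upto = fl, keep_cols = FALSE)
    ft <- net_forward(D, xt, upto = fl, keep_cols = FALSE)$out
    perc_l <- mean(abs(fg$out - ft))
    dfeat <- sign(fg$out - ft) / length(ft)
    dx <- net_backward(D, fg$caches, dfeat, from = fl, param_grads = FALSE)$dx
    dcand <- if (isTRUE(D$conditional)) matrix(dx[, , 2], nrow(g)) else matrix(dx, nrow(g))
    grad <- grad + w[["perceptual"]] * dcand
  }
  list(grad = grad,
       terms = c(voxel = vox_l, gradient = gd$loss, perceptual = perc_l,
                 structural = ss$loss))
}

# one discriminator update on a batch; returns new (D, opt) and the loss
.disc_update <- function(D, G, batch_src, batch_real, spec, opt, lr, t_step) {
  cond <- spec$model_kind == "dc2anet"
  grads <- NULL
  loss <- 0
  for (i in seq_along(batch_real)) {
    src3 <- as_tensor3(batch_src[[i]])
    real <- batch_real[[i]]
    fake <- matrix(net_forward(G, src3, keep_cols = FALSE)$out,
                   nrow(real), ncol(real))
    xr <- if (cond) array(c(batch_src[[i]], real), c(dim(real), 2)) else as_tensor3(real)
    xf <- if (cond) array(c(batch_src[[i]], fake), c(dim(real), 2)) else as_tensor3(fake)
    fr <- net_forward(D, xr)
    ar <- .adv_terms(as.vector(fr$out), 1, spec$adv_form)
    grads <- grads_add(grads, net_backward(D, fr$caches, array(ar$dp, dim(fr$out)))$grads)
    ff <- net_forward(D, xf)
    af <- .adv_terms(as.vector(ff$out), 0, spec$adv_form)
    grads <- grads_add(grads, net_backward(D, ff$caches, array(af$dp, dim(ff$out)))$grads)
    loss <- loss + ar$loss + af$loss
  }
  grads <- grads_scale(grads, 1 / length(batch_real))
  st <- net_adam_step(D, opt, grads, lr, t_step)
  list(D = st$net, opt = st$opt, loss = loss / length(batch_real))
}

#' Train a translation model
#'
#' Seeded, reproducible Adam training of either model on a list of aligned
#' phantom (or real) slice pairs.  Each step performs
#' `schedule$gen_iters` generator updates followed by
#' `schedule$disc_iters` discriminator updates on the same batch; the
#' learning rate follows [lr_at_epoch()].  Training aborts with a diagnostic
#' if any loss becomes non-finite.
#'
#' @param dataset List of `paired_slice` objects (>= 2), all of
#'   `spec$image_size`.
#' @param spec A [gan_spec()].
#' @param schedule A [train_schedule()].
#' @param verbose Print per-epoch losses.
#'
#' @return Object of class `translator_pair`: generators `G_A2B`, `G_B2A`,
#'   discriminators `D_A`, `D_B`, the `spec` and `schedule`, and `history`
#'   (a per-epoch data frame of every loss component and the learning rate).
#' @export
train_translator <- function(dataset, spec, schedule, verbose = FALSE) {
  stopifnot(inherits(spec, "gan_spec"), inherits(schedule, "train_schedule"))
  if (length(dataset) < 2) stop("need at least 2 pairs", call. = FALSE)
  sz <- dim(dataset[[1]]$image_A)
  if (sz[1] != spec$image_size || sz[2] != spec$image_size)
    stop("dataset image size does not match `spec$image_size`", call. = FALSE)
  cond <- spec$model_kind == "dc2anet"

  withr::with_seed(schedule$seed, {
    G1 <- build_generator(spec)   # A -> B
    G2 <- build_generator(spec)   # B -> A
    D_B <- build_discriminator(spec, conditional = cond)
    D_A <- build_discriminator(spec, conditional = cond)
    opt_g1 <- opt_g2 <- opt_dA <- opt_dB <- NULL
    t_g <- t_d <- 0L
    hist <- vector("list", schedule$epochs)

    for (ep in seq_len(schedule$epochs) - 1L) {
      lr <- lr_at_epoch(schedule, ep)
      ord <- sample(length(dataset))
      starts <- seq(1, length(ord), by = schedule$batch_size)
      acc <- list(adv = c(), cyc = c(), disc = c(), vox = c(), grd = c(),
                  prc = c(), str = c())
      for (bi in seq_along(starts)) {
        take <- ord[starts[bi]:min(starts[bi] + schedule$batch_size - 1, length(ord))]
        batch <- dataset[take]
        ab <- lapply(batch, `[[`, "image_A")
        bb <- lapply(batch, `[[`, "image_B")
        supervised <- cond && (bi %% 2L == 1L)

        for (it in seq_len(schedule$gen_iters)) {
          g1 <- g2 <- NULL
          adv_l <- cyc_l <- 0
          sup_acc <- c(voxel = 0, gradient = 0, perceptual = 0, structural = 0)
          for (i in seq_along(batch)) {
            pg <- .gen_pair_grads(G1, G2, D_A, D_B, ab[[i]], bb[[i]], spec, supervised)
            g1 <- grads_add(g1, pg$g1)
            g2 <- grads_add(g2, pg$g2)
            adv_l <- adv_l + pg$adv
            cyc_l <- cyc_l + pg$cycle
            if (supervised) sup_acc <- sup_acc + pg$sup_terms
          }
          nb <- length(batch)
          g1 <- grads_scale(g1, 1 / nb)
          g2 <- grads_scale(g2, 1 / nb)
          t_g <- t_g + 1L
          s1 <- net_adam_step(G1, opt_g1, g1, lr, t_g)
          G1 <- s1$net; opt_g1 <- s1$opt
          s2 <- net_adam_step(G2, opt_g2, g2, lr, t_g)
          G2 <- s2$net; opt_g2 <- s2$opt
          acc$adv <- c(acc$adv, adv_l / nb)
          acc$cyc <- c(acc$cyc, cyc_l / nb)
          if (supervised) {
            acc$vox <- c(acc$vox, sup_acc[["voxel"]] / nb)
            acc$grd <- c(acc$grd, sup_acc[["gradient"]] / nb)
            acc$prc <- c(acc$prc, sup_acc[["perceptual"]] / nb)
            acc$str <- c(acc$str, sup_acc[["structural"]] / nb)
          }
        }
        for (it in seq_len(schedule$disc_iters)) {
          t_d <- t_d + 1L
          uB <- .disc_update(D_B, G1, ab, bb, spec, opt_dB, lr, t_d)
          D_B <- uB$D; opt_dB <- uB$opt
          uA <- .disc_update(D_A, G2, bb, ab, spec, opt_dA, lr, t_d)
          D_A <- uA$D; opt_dA <- uA$opt
          acc$disc <- c(acc$disc, (uA$loss + uB$loss) / 2)
        }
      }
      row <- data.frame(
        epoch = ep, lr = lr,
        loss_adv_gen = mean(acc$adv), loss_cycle = mean(acc$cyc),
        loss_disc = mean(acc$disc),
        loss_voxel = if (length(acc$vox)) mean(acc$vox) else NA_real_,
        loss_gradient = if (length(acc$grd)) mean(acc$grd) else NA_real_,
        loss_perceptual = if (length(acc$prc)) mean(acc$prc) else NA_real_,
        loss_structural = if (length(acc$str)) mean(acc$str) else NA_real_
      )
      if (!all(is.finite(unlist(row[c("loss_adv_gen", "loss_cycle", "loss_disc")]))))
        stop(sprintf("training diverged at epoch %d: non-finite loss", ep), call. = FALSE)
      hist[[ep + 1L]] <- row
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  adv %.4f  cycle %.4f  disc %.4f",
                        ep, lr, row$loss_adv_gen, row$loss_cycle, row$loss_disc))
    }
    structure(list(G_A2B = G1, G_B2A = G2, D_A = D_A, D_B = D_B,
                   spec = spec, schedule = schedule,
                   history = do.call(rbind, hist)),
              class = "translator_pair")
  })
}
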