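#' Configuration of a translation model
#'
#' Collects the architecture and loss weights of the cross-contrast
#' translation models.  Full-scale defaults follow the reference training
#' configuration (256 x 256 inputs, 9 residual blocks, cycle weight 10,
#' adversarial weight 1, unit weights on all six supervised terms); tests and
#' demos use reduced sizes.
#'
#' @param image_size Input side length in pixels; must be divisible by 4
#'   (two stride-2 downsampling stages).
#' @param base_channels Width of the first convolution (default 64).
#' @param n_res_blocks Residual block count (default 9).
#' @param lambda_cyc Cycle-consistency weight (default 10).
#' @param lambda_gan Adversarial weight (default 1).
#' @param sup_weights Named weights of the six supervised loss terms of the
#'   dual cycle-consistent model (all 1 by default).
#' @param model_kind `"cyclegan"` (unconditional discriminators) or
#'   `"dc2anet"` (conditional discriminators plus supervised losses).
#' @param adv_form Adversarial loss form: `"log"` (cross-entropy, default) or
#'   `"lsgan"` (least squares).
#'
#' @return Object of class `gan_spec`.
#' @export
gan_spec <- function(image_size = 256, base_channels = 64, n_res_blocks = 9,
                     lambda_cyc = 10, lambda_gan = 1,
                     sup_weights = c(adversarial = 1, cycle = 1, voxel = 1,
                                     gradient = 1, perceptual = 1, structural = 1),
                     model_kind = c("cyclegan", "dc2anet"),
                     adv_form = c("log", "lsgan")) {
  model_kind <- match.arg(model_kind)
  adv_form <- match.arg(adv_form)
  if (image_size %% 4 != 0) stop("`image_size` must be divisible by 4", call. = FALSE)
  if (n_res_blocks < 1) stop("`n_res_blocks` must be >= 1", call. = FALSE)
  if (lambda_cyc < 0 || lambda_gan < 0 || any(sup_weights < 0))
    stop("loss weights must be >= 0", call. = FALSE)
  need <- c("adversarial", "cycle", "voxel", "gradient", "perceptual", "structural")
  if (!all(need %in% names(sup_weights)))
    stop("`sup_weights` must name all six terms: ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 base_channels = as.integer(base_channels),
                 n_res_blocks = as.integer(n_res_blocks),
                 lambda_cyc = lambda_cyc, lambda_gan = lambda_gan,
                 sup_weights = sup_weights[need], model_kind = model_kind,
                 adv_form = adv_form),
            class = "gan_spec")
}

#' Training schedule
#'
#' Defaults follow the reference configuration: 400 epochs, batch size 2,
#' Adam with initial learning rate 2e-4 held constant for the first 200
#' epochs then decayed linearly to 0, and 3 generator updates per
#' discriminator update.
#'
#' @param epochs Total epochs.
#' @param batch_size Images per step.
#' @param lr_initial Initial learning rate.
#' @param decay_start_epoch Epoch (0-based) at which linear decay begins.
#' @param gen_iters,disc_iters Generator/discriminator update counts per step.
#' @param seed RNG seed controlling initialization and batch order.
#'
#' @return Object of class `train_schedule`.
#' @export
train_schedule <- function(epochs = 400, batch_size = 2, lr_initial = 2e-4,
                           decay_start_epoch = 200, gen_iters = 3,
                           disc_iters = 1, seed = 1L) {
  if (decay_start_epoch > epochs)
    stop("`decay_start_epoch` cannot exceed `epochs`", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_initial = lr_initial,
                 decay_start_epoch = as.integer(decay_start_epoch),
                 gen_iters = as.integer(gen_iters),
                 disc_iters = as.integer(disc_iters), seed = as.integer(seed)),
            class = "train_schedule")
}

#' Learning rate at a given epoch
#'
#' Constant at `lr_initial` before `decay_start_epoch`, then linearly decayed
#' to exactly 0 at `epochs`.
#'
#' @param schedule A [train_schedule()].
#' @param epoch 0-based epoch index.
#' @return The learning rate.
#' @examples
#' s <- train_schedule()
#' lr_at_epoch(s, c(0, 300, 400))
#' @export
lr_at_epoch <- function(schedule, epoch) {
  ifelse(epoch < schedule$decay_start_epoch,
         schedule$lr_initial,
         schedule$lr_initial * (schedule$epochs - epoch) /
           (schedule$epochs - schedule$decay_start_epoch))
}

#' Build a translation generator
#'
#' Residual-block generator: a 7x7 convolution, two stride-2 downsampling
#' convolutions, `n_res_blocks` residual blocks, two nearest-neighbor
#' upsampling + convolution stages, and a final 7x7 convolution; instance
#' normalization throughout and a sigmoid output so generated images live in
#' `[0, 1]`.  Weights are drawn normal(0, 0.02) from the current RNG state.
#'
#' @param spec A [gan_spec()].
#' @return Object of class `mri_generator`.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "gan_spec"))
  F <- spec$base_channels
  layers <- list(
    nn_conv(1, F, 7, 1, 3), nn_instnorm(), nn_relu(),
    nn_conv(F, 2 * F, 3, 2, 1), nn_instnorm(), nn_relu(),
    nn_conv(2 * F, 4 * F, 3, 2, 1), nn_instnorm(), nn_relu()
  )
  for (i in seq_len(spec$n_res_blocks)) layers <- c(layers, list(nn_resblock(4 * F)))
  layers <- c(layers, list(
    nn_upsample(), nn_conv(4 * F, 2 * F, 3, 1, 1), nn_instnorm(), nn_relu(),
    nn_upsample(), nn_conv(2 * F, F, 3, 1, 1), nn_instnorm(), nn_relu(),
    nn_conv(F, 1, 7, 1, 3), nn_sigmoid()
  ))
  structure(list(layers = layers, image_size = spec$image_size,
                 n_res_blocks = spec$n_res_blocks),
            class = "mri_generator")
}

#' Build a patch discriminator
#'
#' Strided-convolution patch classifier with instance normalization and leaky
#' ReLU activations, ending in a sigmoid score map (one realism probability
#' per receptive-field patch).  The conditional variant consumes the
#' concatenation of the source image and the candidate target as a 2-channel
#' input, so its verdict depends on the (source, candidate) pairing.
#'
#' @param spec A [gan_spec()].
#' @param conditional If TRUE, build the 2-channel conditional variant.
#' @return Object of class `mri_discriminator` with a `feature_layer` index
#'   marking the intermediate activation used by the perceptual loss.
#' @export
build_discriminator <- function(spec, conditional = FALSE) {
  stopifnot(inherits(spec, "gan_spec"))
  if (spec$image_size < 16)
    stop("patch discriminator needs `image_size` >= 16", call. = FALSE)
  F <- spec$base_channels
  in_ch <- if (conditional) 2L else 1L
  layers <- list(
    nn_conv(in_ch, F, 4, 2, 1), nn_lrelu(),
    nn_conv(F, 2 * F, 4, 2, 1), nn_instnorm(), nn_lrelu(),
    nn_conv(2 * F, 4 * F, 4, 1, 1), nn_instnorm(), nn_lrelu(),
    nn_conv(4 * F, 1, 4, 1, 1), nn_sigmoid()
  )
  structure(list(layers = layers, conditional = conditional, feature_layer = 5L),
            class = "mri_discriminator")
}

# apply a generator (or plain function) to one 2D image
g_apply <- function(G, image) {
  if (is.function(G)) return(G(image))
  stopifnot(inherits(G, "mri_generator"))
  out <- net_forward(G, as_tensor3(image), keep_cols = FALSE)$out
  matrix(out, dim(out)[1], dim(out)[2])
}

# discriminator score map for one image (matrix) with optional conditioning
# source; returns the raw probability array
d_apply <- function(D, image, src = NULL) {
  if (is.function(D)) return(D(image))
  stopifnot(inherits(D, "mri_discriminator"))
  x <- if (isTRUE(D$conditional)) {
    if (is.null(src)) stop("conditional discriminator needs `src`", call. = FALSE)
    array(c(src, image), c(dim(image), 2))
  } else as_tensor3(image)
  net_forward(D, x, keep_cols = FALSE)$out
}

#' Translate an image with a trained pair
#'
#' @param pair A `translator_pair` from [train_translator()].
#' @param image Numeric matrix in `[0, 1]`.
#' @param direction `"A2B"` or `"B2A"`.
#' @return The translated image, same shape, values in `[0, 1]`.
#' @export
translate <- function(pair, image, direction = c("A2B", "B2A")) {
  direction <- match.arg(direction)
  stopifnot(inherits(pair, "translator_pair"))
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("input image must lie in [0, 1]", call. = FALSE)
  G <- if (direction == "A2B") pair$G_A2B else pair$G_B2A
  g_apply(G, image)
}

#' @export
print.translator_pair <- function(x, ...) {
  cat(sprintf("<translator_pair> %s, %dx%d, trained %d epochs\n",
              x$spec$model_kind, x$spec$image_size, x$spec$image_size,
              if (is.null(x$history)) 0L else max(x$history$epoch + 1L, 0L)))
  invisible(x)
}
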