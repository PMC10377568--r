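#' Tissue model for phantom slice pairs
#'
#' Defines the per-class mean intensities of a simple layered brain phantom in
#' two MRI-like contrasts.  Domain A mimics a T2-weighted appearance (fluid
#' bright), domain B a FLAIR appearance (fluid attenuated, lesions bright).
#' The translation task between the two domains is therefore a learnable,
#' anatomy-preserving per-class intensity remapping.
#'
#' @param intensity_A Named numeric vector of per-class mean intensities in
#'   `[0, 1]` for domain A (T2W-like).  Classes are used in order: outer
#'   tissue, inner white-matter-like band, central fluid-like region, lesion.
#'   Fewer classes yield simpler phantoms (a single class gives a uniform
#'   disc).
#' @param intensity_B Per-class mean intensities for domain B (FLAIR-like);
#'   must have the same length as `intensity_A`.
#' @param noise_sigma Standard deviation of the additive Gaussian acquisition
#'   noise, in intensity units.  Noise is drawn independently for the two
#'   domains.
#' @param seed Integer RNG seed; fully determines the generated pair.
#'
#' @return An object of class `tissue_model`.
#' @examples
#' tm <- tissue_model(noise_sigma = 0)
#' pair <- generate_phantom_pair(32, tm)
#' range(pair$image_A)
#' @export
tissue_model <- function(intensity_A = c(outer = 0.45, white = 0.35, fluid = 0.90, lesion = 0.70),
                         intensity_B = c(outer = 0.50, white = 0.40, fluid = 0.10, lesion = 0.85),
                         noise_sigma = 0.02,
                         seed = 1L) {
  if (length(intensity_A) != length(intensity_B) || length(intensity_A) < 1)
    stop("`intensity_A` and `intensity_B` must be non-empty and of equal length", call. = FALSE)
  if (any(intensity_A < 0 | intensity_A > 1) || any(intensity_B < 0 | intensity_B > 1))
    stop("tissue intensities must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1 || noise_sigma < 0)
    stop("`noise_sigma` must be a single value >= 0", call. = FALSE)
  structure(
    list(intensity_A = intensity_A, intensity_B = intensity_B,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "tissue_model"
  )
}

# label map: 0 background, 1 outer tissue, 2 white-matter-like band,
# 3 central fluid-like region, 4 lesion blobs (as far as the tissue model
# defines classes)
.phantom_labels <- function(size, n_classes) {
  r0 <- size / 2 + stats::runif(1, -0.03, 0.03) * size
  c0 <- size / 2 + stats::runif(1, -0.03, 0.03) * size
  a <- size * stats::runif(1, 0.33, 0.44)  # semi-axis along columns
  b <- size * stats::runif(1, 0.27, 0.38)  # semi-axis along rows
  theta <- stats::runif(1, 0, pi)
  r_band <- stats::runif(1, 0.72, 0.82)
  r_fluid <- stats::runif(1, 0.28, 0.36)

  rr <- matrix(rep(seq_len(size), times = size), size) - r0  # row offsets
  cc <- matrix(rep(seq_len(size), each = size), size) - c0   # col offsets
  xr <- cos(theta) * rr + sin(theta) * cc
  yr <- -sin(theta) * rr + cos(theta) * cc
  rho <- sqrt((xr / b)^2 + (yr / a)^2)

  lab <- matrix(0L, size, size)
  lab[rho <= 1] <- 1L
  if (n_classes >= 2) lab[rho <= r_band] <- 2L
  if (n_classes >= 3) lab[rho <= r_fluid] <- 3L
  if (n_classes >= 4) {
    n_les <- sample(0:2, 1)
    eligible <- which(rho > 0.42 & rho < 0.72 & lab %in% c(1L, 2L))
    for (i in seq_len(n_les)) {
      if (length(eligible) == 0) break
      ctr <- eligible[sample.int(length(eligible), 1)]
      lr <- (ctr - 1L) %% size + 1L
      lc <- (ctr - 1L) %/% size + 1L
      lrad <- size * stats::runif(1, 0.05, 0.10)
      dist2 <- (rr + r0 - lr)^2 + (cc + c0 - lc)^2
      lab[dist2 <= lrad^2 & lab %in% c(1L, 2L)] <- 4L
    }
  }
  lab
}

#' Generate one aligned phantom slice pair
#'
#' Draws an elliptical "brain" containing nested elliptical tissue regions
#' (outer tissue, white-matter-like band, central fluid-like region, optional
#' lesion blobs), then renders the same anatomy in both contrasts by the
#' tissue model's per-class intensities plus independent Gaussian noise.
#' All geometry and noise is determined by `tissue$seed`.
#'
#' @param size Image side length in pixels; must be at least 16.
#' @param tissue A [tissue_model()].
#'
#' @return An object of class `paired_slice`: a list with elements
#'   `image_A`, `image_B` (numeric matrices in `[0, 1]`), `mask`
#'   (0/1 matrix, 1 = brain), `labels` (integer region map) and `id`.
#' @examples
#' pair <- generate_phantom_pair(64, tissue_model(seed = 7))
#' mean(pair$mask)
#' @export
generate_phantom_pair <- function(size, tissue = tissue_model()) {
  if (!is.numeric(size) || length(size) != 1 || size < 16)
    stop("`size` must be a single value >= 16", call. = FALSE)
  if (!inherits(tissue, "tissue_model"))
    stop("`tissue` must be a tissue_model object", call. = FALSE)
  size <- as.integer(size)
  K <- length(tissue$intensity_A)
  withr::with_seed(tissue$seed, {
    lab <- .phantom_labels(size, K)
    mask <- (lab > 0) + 0
    lut_A <- c(0, unname(tissue$intensity_A))
    lut_B <- c(0, unname(tissue$intensity_B))
    img_A <- matrix(lut_A[lab + 1L], size, size)
    img_B <- matrix(lut_B[lab + 1L], size, size)
    if (tissue$noise_sigma > 0) {
      img_A <- img_A + matrix(stats::rnorm(size^2, sd = tissue$noise_sigma), size) * mask
      img_B <- img_B + matrix(stats::rnorm(size^2, sd = tissue$noise_sigma), size) * mask
    }
    structure(
      list(image_A = clip01(img_A), image_B = clip01(img_B), mask = mask,
           labels = lab, id = sprintf("phantom_seed%d", tissue$seed)),
      class = "paired_slice"
    )
  })
}

#' Generate a dataset of phantom slice pairs
#'
#' Produces `n_pairs` slices with per-slice seeds `base_seed + index`, so the
#' ellipse geometry and lesion placement vary across slices while the whole
#' dataset is reproducible from `base_seed`.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param size Image side length in pixels (default 64; use 256 to mirror the
#'   full-resolution setting).
#' @param base_seed Integer; slice `i` uses seed `base_seed + i`.
#' @param tissue A [tissue_model()]; its `seed` field is overridden per slice.
#'
#' @return A list of `paired_slice` objects with ids `phantom_001`, ...
#' @examples
#' ds <- generate_phantom_dataset(3, size = 32, base_seed = 10)
#' length(ds)
#' @export
generate_phantom_dataset <- function(n_pairs, size = 64, base_seed = 1L,
                                     tissue = tissue_model()) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1 || n_pairs < 1)
    stop("`n_pairs` must be a single value >= 1", call. = FALSE)
  n_pairs <- as.integer(n_pairs)
  lapply(seq_len(n_pairs), function(i) {
    ti <- tissue
    ti$seed <- as.integer(base_seed + i)
    p <- generate_phantom_pair(size, ti)
    p$id <- sprintf("phantom_%03d", i)
    p
  })
}

#' Controlled corruption of an image
#'
#' Blends an image with a smoothed copy of itself and adds Gaussian noise,
#' both scaled by `level`.  Used to create synthetic-quality surrogates with
#' a known, tunable departure from the original: `level = 0` returns the
#' input unchanged, and the expected MAE against the input grows with
#' `level`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param level Corruption strength in `[0, 1]`.
#' @param seed Integer RNG seed for the noise draw.
#'
#' @return A numeric matrix of the same dimensions, clipped to `[0, 1]`.
#' @examples
#' img <- generate_phantom_pair(32)$image_A
#' mean(abs(img - degrade(img, 0.5, seed = 3)))
#' @export
degrade <- function(image, level, seed = 1L) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1 || is.na(level) ||
      level < 0 || level > 1)
    stop("`level` must be a single value in [0, 1]", call. = FALSE)
  if (level == 0) return(image)
  withr::with_seed(as.integer(seed), {
    sm <- gauss_blur(image, sigma = 0.5 + 2.5 * level)
    noise <- matrix(stats::rnorm(length(image), sd = 0.08 * level), nrow(image))
    clip01((1 - 0.6 * level) * image + 0.6 * level * sm + noise)
  })
}

#' @export
print.paired_slice <- function(x, ...) {
  cat(sprintf("<paired_slice> %s: %dx%d, mask fraction %.2f\n",
              x$id, nrow(x$image_A), ncol(x$image_A), mean(x$mask)))
  invisible(x)
}
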