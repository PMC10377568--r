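#' Read a 2D grayscale image
#'
#' Reads PNG (8- or 16-bit grayscale) or NIfTI (`.nii`/`.nii.gz`) files into a
#' numeric matrix.  PNG values are returned on their stored integer scale
#' (an 8-bit pixel of 255 reads as 255.0); NIfTI data have their slope and
#' intercept applied.  Single-slice 3D volumes are squeezed to 2D; genuine
#' multi-slice volumes require an explicit `slice` index.
#'
#' @param path File path.
#' @param slice Optional slice index for multi-slice NIfTI volumes.
#'
#' @return A numeric matrix of intensities.
#' @export
read_image <- function(path, slice = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    arr <- as.array(RNifti::readNifti(path))
    dm <- dim(arr)
    if (length(dm) > 2) {
      extra <- dm[-(1:2)]
      if (all(extra == 1)) {
        dim(arr) <- dm[1:2]
      } else if (!is.null(slice)) {
        arr <- array(arr, c(dm[1], dm[2], prod(extra)))[, , slice]
      } else {
        stop("ambiguous multi-slice volume: supply `slice`", call. = FALSE)
      }
    }
    return(matrix(as.numeric(arr), dim(arr)[1], dim(arr)[2]))
  }
  if (grepl("\\.png$", lower)) {
    depth <- .png_bit_depth(path)
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    return(arr * (2^depth - 1))
  }
  stop(sprintf("unsupported image format: %s", path), call. = FALSE)
}

# bit depth lives in byte 25 of the IHDR chunk
.png_bit_depth <- function(path) {
  as.integer(readBin(path, "raw", n = 25)[25])
}

#' Write a 2D image to PNG or NIfTI
#'
#' PNG output is 8-bit and expects intensities in `[0, 1]` (values are
#' clipped); NIfTI output stores the raw values (float32 by default).
#'
#' @param image Numeric matrix.
#' @param path Destination path; format chosen by extension.
#' @param datatype NIfTI on-disk type, `"float"` (default) or `"double"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, datatype = "float") {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    RNifti::writeNifti(RNifti::asNifti(image, datatype = datatype), path)
  } else if (grepl("\\.png$", lower)) {
    png::writePNG(clip01(image), path)
  } else {
    stop(sprintf("unsupported image format: %s", path), call. = FALSE)
  }
  invisible(path)
}

#' Min-max rescale an image to the unit interval
#'
#' @param image Numeric matrix with at least two distinct finite values.
#' @return `(x - min) / (max - min)`, spanning `[0, 1]` exactly.
#' @examples
#' normalize_unit(matrix(c(2, 4, 8, 2), 2))
#' @export
normalize_unit <- function(image) {
  rng <- range(image, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("degenerate intensity range: image must have >= 2 distinct values",
         call. = FALSE)
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Fixed-bin discretization of a masked image
#'
#' Maps in-mask intensities to integer gray levels `1..n_bins` using a fixed
#' number of equal-width bins spanning the in-mask intensity range (bin width
#' `w = (max - min) / n_bins`, `level(x) = min(floor((x - min)/w) + 1,
#' n_bins)`).  Pixels outside the mask get level 0.  A constant in-mask image
#' maps to level 1 everywhere inside the mask (with a unit-width degenerate
#' bin grid).
#'
#' @param image Numeric matrix.
#' @param mask 0/1 matrix of the same dimensions with at least one foreground
#'   pixel; if `NULL`, the whole image is used.
#' @param n_bins Number of gray levels (default 20, the extraction setting
#'   used throughout this package; >= 2).
#'
#' @return An object of class `quantized_image`: list with `levels` (integer
#'   matrix), `n_bins`, `bin_edges` (length `n_bins + 1`, strictly
#'   increasing) and `mask`.
#' @examples
#' img <- matrix(c(0, 0.5, 1, 0.2), 2)
#' quantize(img, n_bins = 4)$levels
#' @export
quantize <- function(image, mask = NULL, n_bins = 20) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (is.null(mask)) mask <- matrix(1, nrow(image), ncol(image))
  if (!identical(dim(image), dim(mask)))
    stop("`image` and `mask` dimensions differ", call. = FALSE)
  if (!is_binary_mask(mask)) stop("`mask` must be a 0/1 matrix", call. = FALSE)
  if (sum(mask) == 0) stop("empty mask", call. = FALSE)
  if (!is.numeric(n_bins) || n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  n_bins <- as.integer(n_bins)

  inside <- mask == 1
  vals <- image[inside]
  mn <- min(vals)
  mx <- max(vals)
  lev <- matrix(0L, nrow(image), ncol(image))
  if (mx == mn) {
    lev[inside] <- 1L
    edges <- mn + seq(0, n_bins)  # degenerate: unit-width convention
  } else {
    w <- (mx - mn) / n_bins
    lev[inside] <- pmin(as.integer(floor((vals - mn) / w)) + 1L, n_bins)
    edges <- seq(mn, mx, length.out = n_bins + 1)
  }
  structure(list(levels = lev, n_bins = n_bins, bin_edges = edges, mask = mask),
            class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image> %dx%d, %d bins, %d in-mask pixels\n",
              nrow(x$levels), ncol(x$levels), x$n_bins, sum(x$mask)))
  invisible(x)
}
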