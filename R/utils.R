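# internal helpers shared across modules

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @noRd
is_binary_mask <- function(mask) {
  is.matrix(mask) && all(mask %in% c(0, 1))
}

# truncated, row-renormalized Gaussian blur; dense band matrices are cheap at
# slice sizes (<= 512 per side)
.blur_kernel_mat <- function(n, sigma) {
  K <- outer(seq_len(n), seq_len(n), function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
  K / rowSums(K)
}

gauss_blur <- function(image, sigma) {
  Kr <- .blur_kernel_mat(nrow(image), sigma)
  Kc <- .blur_kernel_mat(ncol(image), sigma)
  Kr %*% image %*% t(Kc)
}

mae_images <- function(a, b) mean(abs(a - b))
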