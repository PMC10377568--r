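#' Pixel-level fidelity between a real and a synthetic image
#'
#' Computes the three agreement metrics over the evaluated pixels (the whole
#' image, or a mask restriction): mean absolute error, mean squared error and
#' peak signal-to-noise ratio `10 log10(MAX^2 / MSE)` in dB, where `MAX` is
#' the largest pixel value over *both* images in the evaluated region.  PSNR
#' is `+Inf` exactly when MSE is 0.
#'
#' @param real,synthetic Numeric matrices of identical dimensions.
#' @param mask Optional 0/1 matrix restricting the evaluation (1 = evaluate).
#'
#' @return Object of class `fidelity_result`: list with `mae`, `mse`, `psnr`,
#'   `n` (pixel count) and `max_value`.
#' @examples
#' fidelity(matrix(c(0, 1), 1), matrix(c(0, 0.5), 1))
#' @export
fidelity <- function(real, synthetic, mask = NULL) {
  if (!identical(dim(real), dim(synthetic)))
    stop("`real` and `synthetic` dimensions differ", call. = FALSE)
  if (is.null(mask)) {
    r <- as.vector(real); s <- as.vector(synthetic)
  } else {
    if (!identical(dim(mask), dim(real)))
      stop("`mask` dimensions differ from images", call. = FALSE)
    if (sum(mask) == 0) stop("empty mask", call. = FALSE)
    keep <- mask == 1
    r <- real[keep]; s <- synthetic[keep]
  }
  n <- length(r)
  mx <- max(r, s)
  if (mx == 0) stop("undefined MAX: both images are identically zero", call. = FALSE)
  mse <- mean((r - s)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(mx^2 / mse)
  structure(list(mae = mean(abs(r - s)), mse = mse, psnr = psnr,
                 n = n, max_value = mx),
            class = "fidelity_result")
}

#' Summarize fidelity metrics over a set of image pairs
#'
#' Computes a [fidelity()] result per pair and reports the mean and population
#' standard deviation of each metric across pairs.  Pairs with infinite PSNR
#' (identical images) are excluded from the PSNR moments and counted
#' separately.
#'
#' @param pairs List of `list(real =, synthetic =)` pairs (a `real`/`synth`
#'   naming, or unnamed two-element lists, is also accepted).
#' @param mask Optional shared 0/1 evaluation mask.
#'
#' @return A data frame with columns `metric`, `mean`, `sd`, `n`, plus an
#'   attribute `n_psnr_inf`.
#' @export
summarize_fidelity <- function(pairs, mask = NULL) {
  if (length(pairs) < 1) stop("`pairs` must contain at least one pair", call. = FALSE)
  res <- lapply(pairs, function(p) {
    r <- p$real %||% p[[1]]
    s <- p$synthetic %||% p$synth %||% p[[2]]
    fidelity(r, s, mask)
  })
  mae <- vapply(res, `[[`, numeric(1), "mae")
  mse <- vapply(res, `[[`, numeric(1), "mse")
  psnr <- vapply(res, `[[`, numeric(1), "psnr")
  fin <- is.finite(psnr)
  pop_sd <- function(x) if (length(x) == 0) NA_real_ else sqrt(mean((x - mean(x))^2))
  out <- data.frame(
    metric = c("mae", "mse", "psnr"),
    mean = c(mean(mae), mean(mse), if (any(fin)) mean(psnr[fin]) else NA_real_),
    sd = c(pop_sd(mae), pop_sd(mse), pop_sd(psnr[fin])),
    n = c(length(mae), length(mse), sum(fin)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_psnr_inf") <- sum(!fin)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf("<fidelity> MAE %.6g  MSE %.6g  PSNR %.4g dB  (n = %d, MAX = %.4g)\n",
              x$mae, x$mse, x$psnr, x$n, x$max_value))
  invisible(x)
}
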