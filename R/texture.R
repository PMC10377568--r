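# Gray-level texture matrices (GLCM, GLRLM, GLSZM) and the 23 radiomic
# features used to compare real and synthetic MRI slices.  All three matrices
# are computed from a quantized_image: gray levels are indexed from 1 so the
# low-gray-level emphasis terms (1/i^2) stay finite, and pixels outside the
# mask never contribute (level 0 breaks pixel pairs, runs and zones).

.combined_offsets <- function(radius) {
  rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1)) * radius
}

# level values of (start, end) pixels for all displaced in-image pairs
.shifted_pairs <- function(L, dr, dc) {
  H <- nrow(L); W <- ncol(L)
  rs <- seq_len(H - abs(dr))
  cs <- if (dc >= 0) seq_len(W - dc) else seq(1 - dc, W)
  if (length(rs) == 0 || length(cs) == 0)
    return(list(a = integer(0), b = integer(0)))
  list(a = L[rs, cs, drop = FALSE], b = L[rs + dr, cs + dc, drop = FALSE])
}

#' Gray-level co-occurrence matrix
#'
#' Counts in-mask pixel pairs at the given displacement(s), symmetrized (each
#' pair counted in both orders), pools the counts over all offsets, then
#' normalizes to a joint probability matrix.  `offsets = "combined"` uses the
#' four unique 2D directions (0,r), (r,0), (r,r), (r,-r).
#'
#' @param q A [quantize()]d image.
#' @param radius Neighborhood distance (default 1).
#' @param offsets Either `"combined"` or an integer matrix with one
#'   `(delta_row, delta_col)` offset per row.
#'
#' @return Object of class `glc_matrix`: list with `p` (B x B probability
#'   matrix summing to 1, symmetric), `offsets_used`, `radius`.
#' @export
glcm_matrix <- function(q, radius = 1, offsets = "combined") {
  stopifnot(inherits(q, "quantized_image"))
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  off <- if (identical(offsets, "combined")) .combined_offsets(radius) else as.matrix(offsets)
  B <- q$n_bins
  counts <- matrix(0, B, B)
  for (k in seq_len(nrow(off))) {
    sp <- .shifted_pairs(q$levels, off[k, 1], off[k, 2])
    keep <- sp$a > 0 & sp$b > 0
    a <- sp$a[keep]; b <- sp$b[keep]
    if (length(a)) {
      counts <- counts + matrix(tabulate((a - 1L) * B + b, nbins = B * B), B,
                                byrow = TRUE)
    }
  }
  counts <- counts + t(counts)  # symmetrize: both orders
  total <- sum(counts)
  if (total == 0) stop("degenerate texture: no valid in-mask pixel pair", call. = FALSE)
  structure(list(p = counts / total, offsets_used = off, radius = radius),
            class = "glc_matrix")
}

#' GLCM texture features
#'
#' Computes the eight co-occurrence features from a normalized, symmetric
#' GLCM: auto correlation, cluster prominence, cluster shade, contrast,
#' correlation, energy, entropy (base-2 logarithm, with `0 log 0 := 0`) and
#' homogeneity (inverse-difference form `1 / (1 + |i - j|)`).  For a constant
#' image the marginal standard deviation is zero and correlation is defined
#' as 0 by convention (flagged via the `"degenerate_correlation"` attribute).
#'
#' @param M A [glcm_matrix()].
#' @return Named numeric vector of 8 features.
#' @export
glcm_features <- function(M) {
  stopifnot(inherits(M, "glc_matrix"))
  p <- M$p
  B <- nrow(p)
  i <- matrix(rep(seq_len(B), times = B), B)  # row index
  j <- matrix(rep(seq_len(B), each = B), B)   # col index
  pi_marg <- rowSums(p)  # == colSums by symmetry
  mu <- sum(seq_len(B) * pi_marg)
  sigma2 <- sum(seq_len(B)^2 * pi_marg) - mu^2
  sigma <- sqrt(max(sigma2, 0))

  degenerate <- sigma < 1e-12
  correlation <- if (degenerate) 0 else sum((i - mu) * (j - mu) * p) / (sigma * sigma)

  pos <- p > 0
  out <- c(
    auto_correlation = sum(i * j * p),
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    contrast = sum((i - j)^2 * p),
    correlation = correlation,
    energy = sum(p^2),
    entropy = -sum(p[pos] * log2(p[pos])),
    homogeneity = sum(p / (1 + abs(i - j)))
  )
  attr(out, "degenerate_correlation") <- degenerate
  out
}

# maximal runs of equal nonzero level along one direction; returns a
# two-column matrix (level, length)
.runs_along <- function(L, dr, dc) {
  H <- nrow(L); W <- ncol(L)
  lines <- if (dr == 0 && dc == 1) {
    split(L, row(L))
  } else if (dr == 1 && dc == 0) {
    split(L, col(L))
  } else if (dr == 1 && dc == 1) {
    split(L, col(L) - row(L))
  } else if (dr == 1 && dc == -1) {
    split(L, col(L) + row(L))
  } else {
    stop("unsupported run direction", call. = FALSE)
  }
  res <- lapply(lines, function(v) {
    r <- rle(as.vector(v))
    keep <- r$values > 0
    cbind(r$values[keep], r$lengths[keep])
  })
  do.call(rbind, res)
}

#' Gray-level run-length matrix
#'
#' Runs are maximal consecutive in-mask pixels of equal gray level along each
#' direction; mask gaps (level 0) terminate runs.  Counts are accumulated
#' over directions.  `directions = "combined"` uses (0,1), (1,0), (1,1),
#' (1,-1).
#'
#' @param q A [quantize()]d image.
#' @param directions `"combined"` or an integer matrix of unit directions.
#' @return Object of class `rl_matrix`: list with `r` (B x Lmax count
#'   matrix), `n_runs`, `directions_used`.
#' @export
glrlm_matrix <- function(q, directions = "combined") {
  stopifnot(inherits(q, "quantized_image"))
  if (sum(q$mask) == 0) stop("empty mask", call. = FALSE)
  dirs <- if (identical(directions, "combined")) .combined_offsets(1) else as.matrix(directions)
  B <- q$n_bins
  all_runs <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(k)
    .runs_along(q$levels, dirs[k, 1], dirs[k, 2])))
  Lmax <- max(all_runs[, 2])
  r <- matrix(tabulate((all_runs[, 1] - 1L) * Lmax + all_runs[, 2],
                       nbins = B * Lmax), B, byrow = TRUE)
  structure(list(r = r, n_runs = sum(r), directions_used = dirs),
            class = "rl_matrix")
}

#' GLRLM texture features
#'
#' The seven run-length features, computed from run counts `r(i, j)`
#' normalized by the total run count: gray-level nonuniformity, high
#' gray-level run emphasis, long-run high/low gray-level emphasis, low
#' gray-level run emphasis, run-length nonuniformity and short-run emphasis.
#'
#' @param R A [glrlm_matrix()].
#' @return Named numeric vector of 7 features.
#' @export
glrlm_features <- function(R) {
  stopifnot(inherits(R, "rl_matrix"))
  r <- R$r
  Nr <- R$n_runs
  if (Nr < 1) stop("run-length matrix has no runs", call. = FALSE)
  B <- nrow(r); Lm <- ncol(r)
  i <- matrix(rep(seq_len(B), times = Lm), B)
  j <- matrix(rep(seq_len(Lm), each = B), B)
  rn <- r / Nr
  c(
    grey_level_nonuniformity = sum(rowSums(r)^2) / Nr,
    high_grey_level_run_emphasis = sum(i^2 * rn),
    long_run_high_grey_level_emphasis = sum(i^2 * j^2 * rn),
    long_run_low_grey_level_emphasis = sum((j^2 / i^2) * rn),
    low_gray_level_run_emphasis = sum(rn / i^2),
    run_length_nonuniformity = sum(colSums(r)^2) / Nr,
    short_run_emphasis = sum(rn / j^2)
  )
}

#' Gray-level size-zone matrix
#'
#' Zones are connected components (4- or 8-connectivity, default 8) of
#' in-mask pixels sharing the same gray level; `s(i, j)` counts zones of
#' level `i` and size `j` pixels.
#'
#' @param q A [quantize()]d image.
#' @param connectivity 4 or 8 (default 8).
#' @return Object of class `sz_matrix`: list with `s` (B x Zmax count
#'   matrix), `n_zones`, `connectivity`.
#' @export
glszm_matrix <- function(q, connectivity = 8) {
  stopifnot(inherits(q, "quantized_image"))
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8", call. = FALSE)
  L <- q$levels
  if (sum(q$mask) == 0) stop("empty mask", call. = FALSE)
  H <- nrow(L); W <- ncol(L)
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))

  edges <- integer(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    rs <- seq_len(H - dr)
    cs <- if (dc >= 0) seq_len(W - dc) else seq(1 - dc, W)
    a_lin <- as.vector(outer(rs, (cs - 1L) * H, "+"))
    b_lin <- as.vector(outer(rs + dr, (cs + dc - 1L) * H, "+"))
    same <- L[a_lin] > 0 & L[a_lin] == L[b_lin]
    edges <- c(edges, rbind(a_lin[same], b_lin[same]))
  }
  g <- igraph::make_graph(edges, n = H * W, directed = FALSE)
  memb <- igraph::components(g)$membership
  inside <- which(L > 0)
  zone_of <- memb[inside]
  zone_size <- table(zone_of)
  zone_level <- L[inside][!duplicated(zone_of)]
  names(zone_level) <- zone_of[!duplicated(zone_of)]
  sizes <- as.integer(zone_size[names(zone_level)])

  B <- q$n_bins
  Zmax <- max(sizes)
  s <- matrix(tabulate((zone_level - 1L) * Zmax + sizes, nbins = B * Zmax),
              B, byrow = TRUE)
  structure(list(s = s, n_zones = sum(s), connectivity = connectivity),
            class = "sz_matrix")
}

#' GLSZM texture features
#'
#' The eight size-zone features, from zone counts `s(i, j)` and the
#' zone-level marginal `p_i = sum_j s(i, j) / N_s`: gray-level mean,
#' gray-level nonuniformity, gray-level variance, high gray-level emphasis,
#' large-zone emphasis, large-zone high/low gray-level emphasis and low
#' gray-level emphasis.
#'
#' @param S A [glszm_matrix()].
#' @return Named numeric vector of 8 features.
#' @export
glszm_features <- function(S) {
  stopifnot(inherits(S, "sz_matrix"))
  s <- S$s
  Ns <- S$n_zones
  if (Ns < 1) stop("size-zone matrix has no zones", call. = FALSE)
  B <- nrow(s); Zm <- ncol(s)
  i <- matrix(rep(seq_len(B), times = Zm), B)
  j <- matrix(rep(seq_len(Zm), each = B), B)
  p_i <- rowSums(s) / Ns
  glm <- sum(seq_len(B) * p_i)
  c(
    grey_level_mean = glm,
    grey_level_nonuniformity = sum(rowSums(s)^2) / Ns,
    grey_level_variance = sum(seq_len(B)^2 * p_i) - glm^2,
    high_grey_level_emphasis = sum(i^2 * s) / Ns,
    large_zone_emphasis = sum(j^2 * s) / Ns,
    large_zone_high_grey_level_emphasis = sum(i^2 * j^2 * s) / Ns,
    large_zone_low_grey_level_emphasis = sum((j^2 / i^2) * s) / Ns,
    low_grey_level_emphasis = sum(s / i^2) / Ns
  )
}

#' Catalog of the 23 radiomic features
#'
#' @return A data frame with columns `family` (GLCM/GLRLM/GLSZM), `name`
#'   (internal snake_case key used in feature vectors) and `display`
#'   (conventional report name).
#' @export
feature_catalog <- function() {
  data.frame(
    family = c(rep("GLCM", 8), rep("GLRLM", 7), rep("GLSZM", 8)),
    name = c(
      paste0("GLCM_", c("auto_correlation", "cluster_prominence", "cluster_shade",
                        "contrast", "correlation", "energy", "entropy", "homogeneity")),
      paste0("GLRLM_", c("grey_level_nonuniformity", "high_grey_level_run_emphasis",
                         "long_run_high_grey_level_emphasis",
                         "long_run_low_grey_level_emphasis",
                         "low_gray_level_run_emphasis",
                         "run_length_nonuniformity", "short_run_emphasis")),
      paste0("GLSZM_", c("grey_level_mean", "grey_level_nonuniformity",
                         "grey_level_variance", "high_grey_level_emphasis",
                         "large_zone_emphasis",
                         "large_zone_high_grey_level_emphasis",
                         "large_zone_low_grey_level_emphasis",
                         "low_grey_level_emphasis"))
    ),
    display = c(
      "Auto Correlation", "Cluster Prominence", "Cluster Shade", "Contrast",
      "Correlation", "Energy", "Entropy", "Homogeneity",
      "Grey Level Nonuniformity", "High Grey Level Run Emphasis",
      "Long Run High Grey Level Emphasis", "Long Run Low Grey Level Emphasis",
      "Low Gray Level Run Emphasis", "Run Length Nonuniformity",
      "Short Run Emphasis",
      "Grey Level Mean", "Grey Level Nonuniformity", "Grey Level Variance",
      "High Grey Level Emphasis", "Large Zone Emphasis",
      "Large Zone High Grey Level Emphasis",
      "Large Zone Low Grey Level Emphasis", "Low Grey Level Emphasis"
    ),
    stringsAsFactors = FALSE
  )
}

#' Extract the 23 radiomic features from one image
#'
#' Full per-slice pipeline: min-max normalization to `[0, 1]`, fixed-bin
#' discretization over the masked region, construction of the GLCM, GLRLM and
#' GLSZM matrices with pooled ("combined") direction aggregation, and the 23
#' named features.  Defaults match the extraction settings used throughout
#' this package: 20 bins, radius 1, combined offsets, 8-connected zones.
#'
#' @param image Numeric matrix.
#' @param mask Optional 0/1 matrix (1 = analyze); `NULL` uses all pixels.
#' @param n_bins Number of gray levels (default 20).
#' @param radius GLCM neighborhood distance (default 1).
#' @param offsets `"combined"` or explicit offset matrix (GLCM/GLRLM).
#' @param connectivity GLSZM zone connectivity, 4 or 8.
#' @param normalize Rescale intensities to `[0, 1]` first (default TRUE;
#'   skipped automatically for a constant image).
#'
#' @return Named numeric vector of 23 finite values, ordered GLCM, GLRLM,
#'   GLSZM as in [feature_catalog()].
#' @examples
#' pair <- generate_phantom_pair(32)
#' f <- extract_features(pair$image_A, pair$mask)
#' length(f)
#' @export
extract_features <- function(image, mask = NULL, n_bins = 20, radius = 1,
                             offsets = "combined", connectivity = 8,
                             normalize = TRUE) {
  if (normalize && length(unique(as.vector(image))) > 1)
    image <- normalize_unit(image)
  q <- quantize(image, mask, n_bins)
  fg <- glcm_features(glcm_matrix(q, radius, offsets))
  fr <- glrlm_features(glrlm_matrix(q, if (identical(offsets, "combined")) "combined" else offsets))
  fs <- glszm_features(glszm_matrix(q, connectivity))
  out <- c(fg, fr, fs)
  names(out) <- feature_catalog()$name
  stopifnot(all(is.finite(out)))
  out
}
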