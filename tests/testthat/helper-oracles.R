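# Independent brute-force reference implementations used to validate the
# texture stack.  These are deliberately naive (explicit per-pixel loops,
# stack-based flood fill) and share no code with the package.

oracle_quantize <- function(image, mask, n_bins) {
  lev <- matrix(0L, nrow(image), ncol(image))
  vals <- image[mask == 1]
  mn <- min(vals); mx <- max(vals)
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    if (mask[i, j] != 1) next
    if (mx == mn) { lev[i, j] <- 1L; next }
    w <- (mx - mn) / n_bins
    lev[i, j] <- as.integer(min(floor((image[i, j] - mn) / w) + 1, n_bins))
  }
  lev
}

oracle_glcm <- function(lev, B, offsets) {
  H <- nrow(lev); W <- ncol(lev)
  counts <- matrix(0, B, B)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    for (i in seq_len(H)) for (j in seq_len(W)) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 < 1 || i2 > H || j2 < 1 || j2 > W) next
      a <- lev[i, j]; b <- lev[i2, j2]
      if (a > 0 && b > 0) {
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(p) {
  B <- nrow(p)
  mu <- 0; for (i in 1:B) for (j in 1:B) mu <- mu + i * p[i, j]
  s2 <- 0; for (i in 1:B) for (j in 1:B) s2 <- s2 + (i - mu)^2 * p[i, j]
  sdv <- sqrt(s2)
  ac <- cp <- cs <- ct <- cor <- en <- ent <- hom <- 0
  for (i in 1:B) for (j in 1:B) {
    v <- p[i, j]
    ac <- ac + i * j * v
    cp <- cp + (i + j - 2 * mu)^4 * v
    cs <- cs + (i + j - 2 * mu)^3 * v
    ct <- ct + (i - j)^2 * v
    if (sdv > 1e-12) cor <- cor + (i - mu) * (j - mu) * v / (sdv * sdv)
    en <- en + v^2
    if (v > 0) ent <- ent - v * log2(v)
    hom <- hom + v / (1 + abs(i - j))
  }
  c(ac, cp, cs, ct, cor, en, ent, hom)
}

oracle_glrlm <- function(lev, B, directions) {
  runs <- list()
  H <- nrow(lev); W <- ncol(lev)
  for (k in seq_len(nrow(directions))) {
    dr <- directions[k, 1]; dc <- directions[k, 2]
    # line starting points: cells with no valid predecessor along (dr, dc)
    for (i0 in seq_len(H)) for (j0 in seq_len(W)) {
      pi <- i0 - dr; pj <- j0 - dc
      if (pi >= 1 && pi <= H && pj >= 1 && pj <= W) next
      i <- i0; j <- j0
      cur <- 0L; len <- 0L
      while (i >= 1 && i <= H && j >= 1 && j <= W) {
        v <- lev[i, j]
        if (v == cur && v > 0) {
          len <- len + 1L
        } else {
          if (cur > 0) runs[[length(runs) + 1]] <- c(cur, len)
          cur <- v; len <- 1L
        }
        i <- i + dr; j <- j + dc
      }
      if (cur > 0) runs[[length(runs) + 1]] <- c(cur, len)
    }
  }
  rm <- do.call(rbind, runs)
  Lmax <- max(rm[, 2])
  out <- matrix(0, B, Lmax)
  for (r in seq_len(nrow(rm))) out[rm[r, 1], rm[r, 2]] <- out[rm[r, 1], rm[r, 2]] + 1
  out
}

oracle_glrlm_features <- function(r) {
  Nr <- sum(r); B <- nrow(r); Lm <- ncol(r)
  gln <- sum(sapply(1:B, function(i) sum(r[i, ])^2)) / Nr
  rln <- sum(sapply(1:Lm, function(j) sum(r[, j])^2)) / Nr
  hg <- lrhg <- lrlg <- lg <- sre <- 0
  for (i in 1:B) for (j in 1:Lm) {
    v <- r[i, j] / Nr
    hg <- hg + i^2 * v
    lrhg <- lrhg + i^2 * j^2 * v
    lrlg <- lrlg + j^2 / i^2 * v
    lg <- lg + v / i^2
    sre <- sre + v / j^2
  }
  c(gln, hg, lrhg, lrlg, lg, rln, sre)
}

oracle_glszm <- function(lev, B, connectivity = 8) {
  H <- nrow(lev); W <- ncol(lev)
  seen <- matrix(FALSE, H, W)
  nb <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  zones <- list()
  for (i0 in seq_len(H)) for (j0 in seq_len(W)) {
    if (seen[i0, j0] || lev[i0, j0] == 0) next
    v <- lev[i0, j0]
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE; size <- 0L
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(nb))) {
        ni <- cur[1] + nb[k, 1]; nj <- cur[2] + nb[k, 2]
        if (ni < 1 || ni > H || nj < 1 || nj > W) next
        if (!seen[ni, nj] && lev[ni, nj] == v) {
          seen[ni, nj] <- TRUE
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(v, size)
  }
  zm <- do.call(rbind, zones)
  Zmax <- max(zm[, 2])
  out <- matrix(0, B, Zmax)
  for (r in seq_len(nrow(zm))) out[zm[r, 1], zm[r, 2]] <- out[zm[r, 1], zm[r, 2]] + 1
  out
}

oracle_glszm_features <- function(s) {
  Ns <- sum(s); B <- nrow(s); Zm <- ncol(s)
  p_i <- rowSums(s) / Ns
  glm <- sum((1:B) * p_i)
  glv <- sum((1:B)^2 * p_i) - glm^2
  gln <- sum(rowSums(s)^2) / Ns
  hg <- lz <- lzhg <- lzlg <- lg <- 0
  for (i in 1:B) for (j in 1:Zm) {
    v <- s[i, j] / Ns
    hg <- hg + i^2 * v
    lz <- lz + j^2 * v
    lzhg <- lzhg + i^2 * j^2 * v
    lzlg <- lzlg + j^2 / i^2 * v
    lg <- lg + v / i^2
  }
  c(glm, gln, glv, hg, lz, lzhg, lzlg, lg)
}

# all 23 features via the oracle path, ordered as feature_catalog()
oracle_features <- function(image, mask, n_bins, radius = 1) {
  img <- if (length(unique(as.vector(image))) > 1)
    (image - min(image)) / (max(image) - min(image)) else image
  lev <- oracle_quantize(img, mask, n_bins)
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1)) * radius
  dirs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  c(oracle_glcm_features(oracle_glcm(lev, n_bins, offs)),
    oracle_glrlm_features(oracle_glrlm(lev, n_bins, dirs)),
    oracle_glszm_features(oracle_glszm(lev, n_bins, 8)))
}

# random masked test image with at least a few in-mask pixels
random_masked_image <- function(seed, size = NULL, p_mask = 0.85) {
  withr::with_seed(seed, {
    n <- if (is.null(size)) sample(8:24, 1) else size
    img <- matrix(stats::runif(n * n), n)
    mask <- matrix(stats::rbinom(n * n, 1, p_mask), n)
    if (sum(mask) < 8) mask[sample(n * n, 8)] <- 1
    list(image = img, mask = mask)
  })
}
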