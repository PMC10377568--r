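# Minimal convolutional network engine used by the translation models.
# Pure vectorized R: convolutions are im2col gathers followed by BLAS matrix
# multiplies, and every layer carries a hand-derived backward pass.  Images
# are (H, W, C) arrays processed one at a time (training batches are small).
# The engine is deliberately small: exactly the layers the generator and
# patch discriminator need.

.conv_idx_cache <- new.env(parent = emptyenv())

# gather indices for im2col at a given geometry; memoized since the models
# reuse a handful of shapes thousands of times
conv_idx <- function(H, W, k, stride, pad) {
  key <- paste(H, W, k, stride, pad, sep = "_")
  got <- .conv_idx_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  r0 <- (seq_len(Ho) - 1L) * stride
  c0 <- (seq_len(Wo) - 1L) * stride
  base <- as.vector(outer(r0, c0 * Hp, "+"))          # 0-based top-left, col-major
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))
  idx <- outer(base, off, "+") + 1L                   # (Ho*Wo) x k^2
  val <- list(idx = idx, idxv = as.vector(idx), Ho = Ho, Wo = Wo,
              Hp = Hp, Wp = Wp, n_out = Ho * Wo)
  assign(key, val, envir = .conv_idx_cache)
  val
}

# ---- layer constructors -----------------------------------------------------
# weight layout: W is (k^2 * in_ch) x out_ch with kernel offsets column-major
# (d_row fastest) within each input-channel block

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, init_sd = 0.02) {
  list(type = "conv",
       W = matrix(stats::rnorm(k * k * in_ch * out_ch, 0, init_sd),
                  k * k * in_ch, out_ch),
       b = numeric(out_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

nn_instnorm <- function(eps = 1e-5) list(type = "instnorm", eps = eps)
nn_relu <- function() list(type = "relu")
nn_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nn_sigmoid <- function() list(type = "sigmoid")
nn_upsample <- function() list(type = "upsample")

nn_resblock <- function(ch) {
  list(type = "resblock",
       layers = list(nn_conv(ch, ch, 3, 1, 1), nn_instnorm(), nn_relu(),
                     nn_conv(ch, ch, 3, 1, 1), nn_instnorm()))
}

# ---- forward / backward -----------------------------------------------------

layer_forward <- function(ly, x, keep_cols = TRUE) {
  switch(ly$type,
    conv = {
      d <- dim(x)
      r <- conv2d_fwd(x, d[1], d[2], d[3], ly$W, ly$b, ly$k, ly$stride, ly$pad,
                      keep_cols)
      out <- r$out
      dim(out) <- c(r$Ho, r$Wo, ly$out_ch)
      list(out = out, cache = list(cols = r$cols, xdim = d))
    },
    instnorm = {
      d <- dim(x)
      hw <- d[1] * d[2]
      xm <- x
      dim(xm) <- c(hw, d[3])
      mu <- .colMeans(xm, hw, d[3])
      xc <- xm - rep(mu, each = hw)
      v <- .colMeans(xc * xc, hw, d[3])
      istd <- 1 / sqrt(v + ly$eps)
      xhat <- xc * rep(istd, each = hw)
      dim(xhat) <- d
      list(out = xhat, cache = list(xhat = xhat, istd = istd))
    },
    relu = list(out = x * (x > 0), cache = x > 0),
    lrelu = {
      pos <- x > 0
      list(out = x * (pos + ly$alpha * !pos), cache = pos)
    },
    sigmoid = {
      s <- 1 / (1 + exp(-x))
      list(out = s, cache = s)
    },
    upsample = {
      d <- dim(x)
      list(out = x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
                   drop = FALSE],
           cache = d)
    },
    resblock = {
      h <- x
      caches <- vector("list", length(ly$layers))
      for (i in seq_along(ly$layers)) {
        fw <- layer_forward(ly$layers[[i]], h, keep_cols)
        h <- fw$out
        caches[[i]] <- fw$cache
      }
      list(out = x + h, cache = caches)
    },
    stop("unknown layer type: ", ly$type)
  )
}

layer_backward <- function(ly, cache, dout, param_grads = TRUE) {
  switch(ly$type,
    conv = {
      d <- cache$xdim
      dm <- dout
      dim(dm) <- c(length(dout) / ly$out_ch, ly$out_ch)
      cols <- if (is.null(cache$cols)) matrix(0, 0, 0) else cache$cols
      r <- conv2d_bwd(cols, ly$W, dm, d[1], d[2], d[3],
                      ly$k, ly$stride, ly$pad, param_grads)
      dx <- r$dx
      dim(dx) <- d
      list(dx = dx,
           grads = if (param_grads) list(W = r$dW, b = as.vector(r$db)) else NULL)
    },
    instnorm = {
      d <- dim(dout)
      hw <- d[1] * d[2]
      dy <- dout
      dim(dy) <- c(hw, d[3])
      xh <- cache$xhat
      dim(xh) <- c(hw, d[3])
      m1 <- .colMeans(dy, hw, d[3])
      m2 <- .colMeans(dy * xh, hw, d[3])
      dx <- (dy - rep(m1, each = hw) - xh * rep(m2, each = hw)) *
        rep(cache$istd, each = hw)
      dim(dx) <- d
      list(dx = dx, grads = NULL)
    },
    relu = list(dx = dout * cache, grads = NULL),
    lrelu = list(dx = dout * (cache + ly$alpha * !cache), grads = NULL),
    sigmoid = list(dx = dout * cache * (1 - cache), grads = NULL),
    upsample = {
      d2 <- dim(dout)
      odd_r <- seq(1, d2[1], by = 2)
      odd_c <- seq(1, d2[2], by = 2)
      dr <- dout[odd_r, , , drop = FALSE] + dout[odd_r + 1, , , drop = FALSE]
      dx <- dr[, odd_c, , drop = FALSE] + dr[, odd_c + 1, , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    resblock = {
      g <- dout
      grads <- vector("list", length(ly$layers))
      for (i in rev(seq_along(ly$layers))) {
        bk <- layer_backward(ly$layers[[i]], cache[[i]], g, param_grads)
        g <- bk$dx
        grads[i] <- list(bk$grads)  # keep NULL slots in place
      }
      list(dx = dout + g, grads = grads)
    },
    stop("unknown layer type: ", ly$type)
  )
}

# forward through a network (list with $layers); caches kept for backward
net_forward <- function(net, x, upto = length(net$layers), keep_cols = TRUE) {
  caches <- vector("list", upto)
  for (i in seq_len(upto)) {
    fw <- layer_forward(net$layers[[i]], x, keep_cols)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

# backward from layer `from` down to the input; returns input gradient and a
# per-layer gradient structure aligned with net$layers
net_backward <- function(net, caches, dout, from = length(caches),
                         param_grads = TRUE) {
  grads <- vector("list", length(net$layers))
  g <- dout
  for (i in rev(seq_len(from))) {
    bk <- layer_backward(net$layers[[i]], caches[[i]], g, param_grads)
    g <- bk$dx
    grads[i] <- list(bk$grads)  # keep NULL slots in place
  }
  list(dx = g, grads = grads)
}

# ---- gradient bookkeeping and Adam ------------------------------------------

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

grads_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, grads_scale, s = s))
  g * s
}

adam_init_like <- function(g) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, adam_init_like))
  list(m = g * 0, v = g * 0)
}

# one Adam step over the whole network; opt is created lazily on first call
net_adam_step <- function(net, opt, grads, lr, t, beta1 = 0.5, beta2 = 0.999,
                          eps = 1e-8) {
  step_layer <- function(ly, o, g) {
    if (is.null(g)) return(list(ly = ly, o = o))
    if (identical(ly$type, "resblock")) {
      for (i in seq_along(ly$layers)) {
        r <- step_layer(ly$layers[[i]], o[[i]], g[[i]])
        ly$layers[[i]] <- r$ly
        o[i] <- list(r$o)  # keep NULL slots in place
      }
      return(list(ly = ly, o = o))
    }
    for (nm in c("W", "b")) {
      gv <- g[[nm]]
      if (is.null(gv)) next
      st <- o[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gv
      st$v <- beta2 * st$v + (1 - beta2) * gv^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      ly[[nm]] <- ly[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      o[[nm]] <- st
    }
    list(ly = ly, o = o)
  }
  if (is.null(opt)) {
    opt <- lapply(net$layers, function(ly) {
      if (identical(ly$type, "conv"))
        list(W = list(m = ly$W * 0, v = ly$W * 0),
             b = list(m = ly$b * 0, v = ly$b * 0))
      else if (identical(ly$type, "resblock"))
        lapply(ly$layers, function(l2)
          if (identical(l2$type, "conv"))
            list(W = list(m = l2$W * 0, v = l2$W * 0),
                 b = list(m = l2$b * 0, v = l2$b * 0))
          else NULL)
      else NULL
    })
  }
  for (i in seq_along(net$layers)) {
    r <- step_layer(net$layers[[i]], opt[[i]], grads[[i]])
    net$layers[[i]] <- r$ly
    opt[i] <- list(r$o)  # keep NULL slots in place
  }
  list(net = net, opt = opt)
}

as_tensor3 <- function(x) {
  if (length(dim(x)) == 3) return(x)
  array(x, c(dim(x), 1))
}
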