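# Minimal 3D convolutional network primitives.
#
# Feature maps are stored as dense matrices (n_voxels x channels) with the
# spatial shape carried alongside; convolutions are evaluated as im2col
# gathers followed by BLAS matrix products, and every operation has an
# explicit reverse-mode companion. Kernel size is fixed at 3 with "same"
# padding; stride is 1 or 2 (2 halves each even axis).

# gather the 27 shifted blocks of a padded feature map into the im2col
# matrix (n_out x 27*C); column order: channels within kernel offset,
# offsets ordered with axis 1 fastest.
im2col3 <- function(x, shape, stride = 1L) {
  d <- as.integer(shape); C <- ncol(x)
  dp <- d + 2L
  Xp <- array(0, c(dp, C))
  Xp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- array(x, c(d, C))
  s1 <- seq.int(1L, d[1], by = stride)
  s2 <- seq.int(1L, d[2], by = stride)
  s3 <- seq.int(1L, d[3], by = stride)
  n_out <- length(s1) * length(s2) * length(s3)
  cols <- vector("list", 27L)
  k <- 1L
  for (c3 in 0:2) for (c2 in 0:2) for (c1 in 0:2) {
    cols[[k]] <- matrix(Xp[c1 + s1, c2 + s2, c3 + s3, , drop = FALSE],
                        nrow = n_out)
    k <- k + 1L
  }
  list(M = do.call(cbind, cols),
       out_shape = c(length(s1), length(s2), length(s3)))
}

# scatter-add the im2col gradient back onto the (unpadded) input grid
col2im3 <- function(dM, shape, stride = 1L, C) {
  d <- as.integer(shape)
  dp <- d + 2L
  s1 <- seq.int(1L, d[1], by = stride)
  s2 <- seq.int(1L, d[2], by = stride)
  s3 <- seq.int(1L, d[3], by = stride)
  os <- c(length(s1), length(s2), length(s3))
  dXp <- array(0, c(dp, C))
  k <- 1L
  for (c3 in 0:2) for (c2 in 0:2) for (c1 in 0:2) {
    blk <- array(dM[, ((k - 1L) * C + 1L):(k * C)], c(os, C))
    dXp[c1 + s1, c2 + s2, c3 + s3, ] <-
      dXp[c1 + s1, c2 + s2, c3 + s3, ] + blk
    k <- k + 1L
  }
  matrix(dXp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), , drop = FALSE],
         nrow = prod(d))
}

conv3_forward <- function(x, shape, layer, stride = 1L, keep_M = FALSE) {
  r <- conv3_fwd_cpp(x, as.integer(shape), as.integer(stride), layer$W,
                     layer$b, keep_M)
  list(y = r$y, shape = as.integer(r$shape), M = r$M)
}

# backward reusing the cached im2col matrix from the forward pass
conv3_backward_m <- function(dY, M, n_in, shape, layer, stride = 1L) {
  r <- conv3_bwd_m_cpp(dY, M, as.numeric(n_in), as.integer(shape),
                       as.integer(stride), layer$W)
  list(dW = r$dW, db = drop(r$db), dX = r$dX)
}

# gradients w.r.t. layer parameters and input; the im2col matrix is rebuilt
# from the cached input rather than stored (memory over speed)
conv3_backward <- function(dY, x, shape, layer, stride = 1L) {
  r <- conv3_bwd_cpp(dY, x, as.integer(shape), as.integer(stride), layer$W)
  list(dW = r$dW, db = drop(r$db), dX = r$dX)
}

# pure-R reference implementations of the convolution (used as the test
# oracle for the compiled kernels)
conv3_forward_ref <- function(x, shape, layer, stride = 1L) {
  ic <- im2col3(x, shape, stride)
  y <- ic$M %*% layer$W
  y <- sweep(y, 2L, layer$b, "+")
  list(y = y, shape = ic$out_shape)
}

conv3_backward_ref <- function(dY, x, shape, layer, stride = 1L) {
  ic <- im2col3(x, shape, stride)
  dW <- crossprod(ic$M, dY)
  db <- colSums(dY)
  dM <- dY %*% t(layer$W)
  dX <- col2im3(dM, shape, stride, C = ncol(x))
  list(dW = dW, db = db, dX = dX)
}

leaky_forward <- function(x, alpha) {
  neg <- x < 0
  x[neg] <- alpha * x[neg]
  list(y = x, neg = neg)
}

leaky_backward <- function(dY, neg, alpha) {
  dY[neg] <- alpha * dY[neg]
  dY
}

# nearest-neighbour 2x upsampling index (output linear voxel -> input)
upsample_index <- function(shape_in) {
  d <- as.integer(shape_in)
  i1 <- rep.int(rep(seq_len(d[1]), each = 2L), 4L * d[2] * d[3])
  i2 <- rep.int(rep(seq_len(d[2]), each = 4L * d[1]), 2L * d[3])
  i3 <- rep(seq_len(d[3]), each = 8L * d[1] * d[2])
  i1 + (i2 - 1L) * d[1] + (i3 - 1L) * d[1] * d[2]
}

upsample_forward <- function(x, shape) {
  idx <- upsample_index(shape)
  list(y = x[idx, , drop = FALSE], shape = 2L * as.integer(shape), idx = idx)
}

upsample_backward <- function(dY, idx) {
  rowsum(dY, group = idx, reorder = TRUE)
}

# He-style initialisation for LeakyReLU layers; kernel 3^3
init_conv <- function(c_in, c_out, alpha, rng_sd = NULL) {
  fan_in <- 27 * c_in
  sd <- if (is.null(rng_sd)) sqrt(2 / ((1 + alpha^2) * fan_in)) else rng_sd
  list(W = matrix(stats::rnorm(27 * c_in * c_out, sd = sd), 27 * c_in, c_out),
       b = numeric(c_out))
}

# ---- Adam over a nested list of parameter arrays --------------------------

adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(a) a * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        key <- if (!is.null(names(p))) names(p)[i] else i
        r <- walk(p[[key]], g[[key]], m[[key]], v[[key]])
        out_p[[key]] <- r$p; out_m[[key]] <- r$m; out_v[[key]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- smooth field expansion ----------------------------------------------
# The field head predicts displacement coefficients on a coarse control
# grid (stride 2^k); the full-resolution field is their trilinear
# interpolation, like a free-form deformation with one control point per
# block. Interpolation weights depend only on the geometry, so they are
# cached per (coarse shape, k).

.field_interp_cache <- new.env(parent = emptyenv())

field_interp_plan <- function(cshape, k) {
  key <- paste(c(cshape, k), collapse = "_")
  hit <- .field_interp_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- 2^k
  fshape <- as.integer(cshape) * as.integer(s)
  g <- coord_grid(fshape)
  cc <- cbind((g[, 1] - 0.5) / s + 0.5,
              (g[, 2] - 0.5) / s + 0.5,
              (g[, 3] - 0.5) / s + 0.5)
  d <- as.integer(cshape)
  c1 <- pmin(pmax(cc[, 1], 1), d[1]); c2 <- pmin(pmax(cc[, 2], 1), d[2])
  c3 <- pmin(pmax(cc[, 3], 1), d[3])
  f1 <- pmin(floor(c1), max(d[1] - 1L, 1L))
  f2 <- pmin(floor(c2), max(d[2] - 1L, 1L))
  f3 <- pmin(floor(c3), max(d[3] - 1L, 1L))
  t1 <- c1 - f1; t2 <- c2 - f2; t3 <- c3 - f3
  o1 <- as.integer(d[1] > 1L); o2 <- as.integer(d[2] > 1L)
  o3 <- as.integer(d[3] > 1L)
  base <- f1 + (f2 - 1) * d[1] + (f3 - 1) * d[1] * d[2]
  corners <- cbind(base,
                   base + o1,
                   base + o2 * d[1],
                   base + o1 + o2 * d[1],
                   base + o3 * d[1] * d[2],
                   base + o1 + o3 * d[1] * d[2],
                   base + o2 * d[1] + o3 * d[1] * d[2],
                   base + o1 + o2 * d[1] + o3 * d[1] * d[2])
  weights <- cbind((1 - t1) * (1 - t2) * (1 - t3),
                   t1 * (1 - t2) * (1 - t3),
                   (1 - t1) * t2 * (1 - t3),
                   t1 * t2 * (1 - t3),
                   (1 - t1) * (1 - t2) * t3,
                   t1 * (1 - t2) * t3,
                   (1 - t1) * t2 * t3,
                   t1 * t2 * t3)
  plan <- list(corners = corners, weights = weights,
               n_coarse = prod(d), fshape = fshape)
  .field_interp_cache[[key]] <- plan
  plan
}

# expand coarse coefficients (n_coarse x 3) to the fine grid
field_expand <- function(x, cshape, k) {
  if (k == 0L) return(x)
  pl <- field_interp_plan(cshape, k)
  out <- matrix(0, nrow(pl$corners), ncol(x))
  for (j in 1:8)
    out <- out + pl$weights[, j] * x[pl$corners[, j], , drop = FALSE]
  out
}

# transpose: scatter a fine-grid gradient back onto the control grid
field_expand_backward <- function(dY, cshape, k) {
  if (k == 0L) return(dY)
  pl <- field_interp_plan(cshape, k)
  out <- matrix(0, pl$n_coarse, ncol(dY))
  for (j in 1:8) {
    acc <- rowsum(pl$weights[, j] * dY, group = pl$corners[, j],
                  reorder = FALSE)
    idx <- as.integer(rownames(acc))
    out[idx, ] <- out[idx, ] + acc
  }
  out
}

# rescale a nested gradient list so its global L2 norm is at most max_norm
clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  sq <- function(g) if (is.list(g)) sum(vapply(g, sq, 0)) else sum(g^2)
  nrm <- sqrt(sq(grads))
  if (nrm <= max_norm) return(grads)
  scale <- max_norm / nrm
  rapply(grads, function(a) a * scale, how = "replace")
}

# elementwise sum of two nested gradient lists
grad_accumulate <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (i in seq_along(a)) {
      key <- if (!is.null(names(a))) names(a)[i] else i
      a[[key]] <- grad_accumulate(a[[key]], b[[key]])
    }
    return(a)
  }
  a + b
}
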