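#' Configuration of the deformable registration network
#'
#' Hyperparameters of the unsupervised registration model: a 3D U-Net with
#' `n_levels` stride-2 encoder convolutions (kernel 3, LeakyReLU), a
#' mirrored decoder with nearest-neighbour upsampling and concatenation
#' skip connections, and a linear field head. The loss is
#' `-MI(f, w) + lambda1 * smoothness + lambda2 * L2`, minimised with Adam.
#'
#' Defaults follow the published recipe: 4 levels, kernel 3, stride 2,
#' LeakyReLU alpha 0.2, lambda1 = 1e-2, lambda2 = 1e-5, learning rate 1e-4,
#' 200 epochs, batch size 1. `base_channels`, `mi_bins` and the Parzen
#' `mi_kernel_width` are implementation choices documented in the methods
#' vignette.
#'
#' @param n_levels encoder/decoder depth.
#' @param kernel_size convolution kernel (only 3 supported).
#' @param stride encoder stride (only 2 supported).
#' @param base_channels channels of the first encoder level; deeper levels
#'   use twice this.
#' @param leaky_relu_alpha negative-slope of the activations.
#' @param lambda1,lambda2 weights of the smoothness and L2 penalties.
#' @param mi_bins intensity bins of the mutual-information estimator.
#' @param mi_kernel_width Parzen kernel width on the [0,1] intensity scale
#'   (default one bin width).
#' @param learning_rate,epochs,batch_size Adam recipe. `learning_rate`
#'   may be a vector of per-epoch rates (its last value is reused past
#'   its length), supporting step decay.
#' @param loss_reduction `"sum"` evaluates the smoothness and L2 penalties
#'   as plain sums over voxels (the form in which the equations are
#'   written and in which [smoothness_loss()] / [l2_penalty()] report
#'   them); `"mean"` divides both by the voxel count before weighting, the
#'   per-voxel normalisation standard in unsupervised-registration
#'   implementations, which keeps the published lambda values on a
#'   comparable scale to the MI term at any grid size.
#' @param max_grad_norm clip the global L2 norm of the parameter gradient
#'   to this value before each optimiser step (`Inf` disables); stabilises
#'   the short aggressive training schedules used at desk scale.
#' @param field_stride resolution of the predicted field: the decoder
#'   stops `log2(field_stride)` levels above full resolution, the linear
#'   head predicts the field there, and the result is block-expanded to
#'   the full grid. Deformations at the anatomical correlation length
#'   remain fully representable on the coarse grid, but per-voxel sub-bin
#'   intensity adjustments — a known failure mode in which an
#'   unconstrained field sharpens the joint histogram (raising MI)
#'   without aligning anything — are not, and the full-resolution decoder
#'   convolutions (the bulk of the compute) are skipped. 1 predicts at
#'   full resolution.
#' @param field_expansion how the coarse control-grid coefficients are
#'   reconstructed on the full grid inside the training objective:
#'   `"nearest"` (block-constant; resistant to sub-voxel
#'   histogram-sharpening because intensities can only be manipulated in
#'   whole blocks) or `"trilinear"` (smooth, free-form-deformation-like).
#'   Inference through [register()] always reconstructs the learned
#'   coefficients trilinearly, giving a spatially smooth deformation.
#' @param seed integer seed driving parameter initialisation and the
#'   training-case order.
#' @return list of class `dlir_config`.
#' @export
dlir_config <- function(n_levels = 4L, kernel_size = 3L, stride = 2L,
                        base_channels = 8L, leaky_relu_alpha = 0.2,
                        lambda1 = 1e-2, lambda2 = 1e-5, mi_bins = 32L,
                        mi_kernel_width = 1 / mi_bins,
                        learning_rate = 1e-4, epochs = 200L, batch_size = 1L,
                        loss_reduction = c("sum", "mean"),
                        max_grad_norm = 1, field_stride = 2L,
                        field_expansion = c("nearest", "trilinear"),
                        seed = 1L) {
  field_expansion <- match.arg(field_expansion)
  loss_reduction <- match.arg(loss_reduction)
  if (!field_stride %in% c(1L, 2L, 4L))
    stop("'field_stride' must be 1, 2 or 4")
  if (kernel_size != 3L) stop("only kernel_size = 3 is supported")
  if (stride != 2L) stop("only stride = 2 is supported")
  if (mi_bins < 2L) stop("'mi_bins' must be at least 2")
  if (lambda1 < 0 || lambda2 < 0) stop("lambda weights must be non-negative")
  structure(list(n_levels = as.integer(n_levels), kernel_size = 3L,
                 stride = 2L, base_channels = as.integer(base_channels),
                 leaky_relu_alpha = leaky_relu_alpha, lambda1 = lambda1,
                 lambda2 = lambda2, mi_bins = as.integer(mi_bins),
                 mi_kernel_width = mi_kernel_width,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 loss_reduction = loss_reduction,
                 max_grad_norm = max_grad_norm,
                 field_stride = as.integer(field_stride),
                 field_expansion = field_expansion,
                 seed = as.integer(seed)),
            class = "dlir_config")
}

#' Spatial shape of the deepest encoder features
#'
#' Each encoder level halves every spatial axis, so a shape `s` maps to
#' `s / 2^n_levels`. Errors name the first axis that is not divisible.
#'
#' @param input_shape integer length-3.
#' @param n_levels encoder depth.
#' @return integer length-3.
#' @export
encoder_output_shape <- function(input_shape, n_levels = 4L) {
  s <- as.integer(input_shape)
  div <- 2L^n_levels
  for (ax in 1:3) {
    if (s[ax] %% div != 0L)
      stop(sprintf("axis %d (size %d) is not divisible by 2^%d = %d",
                   ax, s[ax], n_levels, div))
  }
  s %/% div
}

#' Build an (untrained) registration network
#'
#' Constructs the U-Net for a given input shape: the network takes the
#' moving and fixed volumes concatenated as a 2-channel input (channel
#' order m, f) and outputs a 3-component displacement field of the same
#' spatial shape, in voxel units. The field head is linear with
#' small-variance initialisation so the initial warp is close to identity;
#' all other layers use LeakyReLU. Initialisation is deterministic under
#' `config$seed`.
#'
#' @param config a [dlir_config()].
#' @param input_shape spatial shape of the training volumes (each axis
#'   divisible by `2^n_levels`).
#' @return object of class `dlir_model` (untrained).
#' @export
dlir_build <- function(config = dlir_config(), input_shape) {
  stopifnot(inherits(config, "dlir_config"))
  encoder_output_shape(input_shape, config$n_levels)  # validates divisibility
  L <- config$n_levels; B <- config$base_channels
  alpha <- config$leaky_relu_alpha
  enc_ch <- c(B, rep(2L * B, L - 1L))
  dec_out <- ifelse(seq_len(L - 1L) >= 2L, 2L * B, B)  # indexed by level l
  layers <- with_seed(config$seed, {
    enc <- vector("list", L)
    c_in <- 2L
    for (l in seq_len(L)) {
      enc[[l]] <- init_conv(c_in, enc_ch[l], alpha)
      c_in <- enc_ch[l]
    }
    k <- as.integer(round(log2(config$field_stride)))
    dec <- vector("list", L - 1L)
    c_prev <- enc_ch[L]
    for (l in rev(seq_len(L - 1L))) {
      if (l < k) break   # decoder stops at the field resolution
      dec[[l]] <- init_conv(c_prev + enc_ch[l], dec_out[l], alpha)
      c_prev <- dec_out[l]
    }
    dec0 <- if (k == 0L) init_conv(c_prev, B, alpha) else NULL
    head <- init_conv(if (k == 0L) B else c_prev, 3L, alpha, rng_sd = 1e-5)
    dec[vapply(dec, is.null, TRUE)] <- list(list())  # unused coarse levels
    out <- list(enc = enc, dec = dec)
    if (!is.null(dec0)) out$dec0 <- dec0
    out$head <- head
    out
  })
  sig <- c(sprintf("input: 2 channels, %s", paste(input_shape, collapse = "x")),
           sprintf("enc%d: conv3 stride2 -> %d ch, LeakyReLU(%.2g)",
                   seq_len(L), enc_ch, alpha))
  structure(list(layers = layers, config = config,
                 input_shape = as.integer(input_shape),
                 enc_channels = enc_ch, dec_channels = dec_out,
                 encoder_signature = sig, trained = FALSE, history = NULL),
            class = "dlir_model")
}

#' @export
print.dlir_model <- function(x, ...) {
  cat(sprintf("<dlir_model> %s, %d-level U-Net, base %d channels%s\n",
              paste(x$input_shape, collapse = "x"), x$config$n_levels,
              x$config$base_channels,
              if (x$trained) " (trained)" else " (untrained)"))
  deep <- encoder_output_shape(x$input_shape, x$config$n_levels)
  cat(sprintf("  deepest encoder features: %s x %d channels\n",
              paste(deep, collapse = "x"), x$enc_channels[x$config$n_levels]))
  if (!is.null(x$history))
    cat(sprintf("  final training loss: %.5f after %d epochs\n",
                x$history$loss[nrow(x$history)], nrow(x$history)))
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

net_forward <- function(model, x0, cache = FALSE, expansion = NULL) {
  cfg <- model$config; L <- cfg$n_levels; alpha <- cfg$leaky_relu_alpha
  expansion <- expansion %||% cfg$field_expansion %||% "nearest"
  k <- as.integer(round(log2(cfg$field_stride %||% 1L)))
  ly <- model$layers
  shp <- model$input_shape
  enc_in <- vector("list", L); enc_in_shape <- vector("list", L)
  enc_neg <- vector("list", L); enc_out <- vector("list", L)
  enc_shape <- vector("list", L)
  h <- x0; sh <- shp
  enc_M <- vector("list", L)
  for (l in seq_len(L)) {
    enc_in[[l]] <- h; enc_in_shape[[l]] <- sh
    cv <- conv3_forward(h, sh, ly$enc[[l]], stride = 2L, keep_M = cache)
    lk <- leaky_forward(cv$y, alpha)
    h <- lk$y; sh <- cv$shape
    enc_neg[[l]] <- lk$neg; enc_out[[l]] <- h; enc_shape[[l]] <- sh
    enc_M[[l]] <- cv$M
  }
  dec_levels <- if (L - 1L >= max(k, 1L)) rev(seq.int(max(k, 1L), L - 1L))
                else integer(0)
  dec_neg <- vector("list", L - 1L); dec_M <- vector("list", L - 1L)
  dec_ncol <- integer(L - 1L)
  up_idx <- vector("list", L)
  d <- h; dsh <- sh
  for (l in dec_levels) {
    up <- upsample_forward(d, dsh)
    up_idx[[l + 1L]] <- up$idx
    d <- cbind(up$y, enc_out[[l]]); dsh <- up$shape
    dec_ncol[l] <- ncol(d)
    cv <- conv3_forward(d, dsh, ly$dec[[l]], stride = 1L, keep_M = cache)
    lk <- leaky_forward(cv$y, alpha)
    d <- lk$y; dec_neg[[l]] <- lk$neg
    dec_M[[l]] <- cv$M
  }
  if (k == 0L) {
    up <- upsample_forward(d, dsh)
    up_idx[[1L]] <- up$idx
    d0_in <- up$y; dsh <- up$shape
    cv0 <- conv3_forward(d0_in, dsh, ly$dec0, stride = 1L, keep_M = cache)
    lk0 <- leaky_forward(cv0$y, alpha)
    d <- lk0$y
    d0_M <- cv0$M; d0_neg <- lk0$neg
  } else { d0_M <- NULL; d0_neg <- NULL }
  cvh <- conv3_forward(d, dsh, ly$head, stride = 1L, keep_M = cache)
  head_shape <- dsh
  field <- if (expansion == "trilinear") {
    field_expand(cvh$y, head_shape, k)
  } else {
    fld <- cvh$y
    if (k > 0L) for (i in seq_len(k)) {
      up <- upsample_forward(fld, dsh)
      fld <- up$y; dsh <- up$shape
    }
    fld
  }
  out <- list(field = field)
  if (cache) {
    out$cache <- list(enc_in_shape = enc_in_shape,
                      enc_neg = enc_neg, enc_out = enc_out,
                      enc_shape = enc_shape, enc_M = enc_M,
                      enc_nin = c(nrow(x0),
                                  vapply(enc_out[-L], nrow, 0)),
                      dec_levels = dec_levels,
                      dec_neg = dec_neg, dec_M = dec_M,
                      dec_ncol = dec_ncol, up_idx = up_idx,
                      d0_M = d0_M, d0_neg = d0_neg,
                      head_M = cvh$M, head_shape = head_shape,
                      k = k, expansion = expansion, n_full = nrow(x0))
  }
  out
}

net_backward <- function(model, cache, dfield) {
  cfg <- model$config; L <- cfg$n_levels; alpha <- cfg$leaky_relu_alpha
  ly <- model$layers
  k <- cache$k
  g <- list(enc = vector("list", L), dec = vector("list", L - 1L))
  dhead <- if (cache$expansion == "trilinear") {
    field_expand_backward(dfield, cache$head_shape, k)
  } else {
    sh <- as.integer(model$input_shape)
    dY <- dfield
    for (i in seq_len(k)) {
      half <- sh %/% 2L
      dY <- rowsum(dY, group = upsample_index(half), reorder = TRUE)
      sh <- half
    }
    dY
  }
  n_head <- nrow(dhead)
  bh <- conv3_backward_m(dhead, cache$head_M, n_head, cache$head_shape,
                         ly$head, 1L)
  g$head <- list(W = bh$dW, b = bh$db)
  gd <- bh$dX
  if (k == 0L) {
    d0 <- leaky_backward(gd, cache$d0_neg, alpha)
    b0 <- conv3_backward_m(d0, cache$d0_M, nrow(d0), cache$head_shape,
                           ly$dec0, 1L)
    g$dec0 <- list(W = b0$dW, b = b0$db)
    gd <- upsample_backward(b0$dX, cache$up_idx[[1L]])
  }
  g_skip <- vector("list", L)
  for (l in sort(cache$dec_levels)) {
    gd <- leaky_backward(gd, cache$dec_neg[[l]], alpha)
    bl <- conv3_backward_m(gd, cache$dec_M[[l]], nrow(gd),
                           cache$enc_shape[[l]], ly$dec[[l]], 1L)
    g$dec[[l]] <- list(W = bl$dW, b = bl$db)
    c_up <- cache$dec_ncol[l] - ncol(cache$enc_out[[l]])
    g_skip[[l]] <- bl$dX[, (c_up + 1L):cache$dec_ncol[l], drop = FALSE]
    gd <- upsample_backward(bl$dX[, seq_len(c_up), drop = FALSE],
                            cache$up_idx[[l + 1L]])
  }
  g_out <- gd  # gradient w.r.t. enc_out[[L]]
  for (l in rev(seq_len(L))) {
    if (l < L && !is.null(g_skip[[l]])) g_out <- g_out + g_skip[[l]]
    g_out <- leaky_backward(g_out, cache$enc_neg[[l]], alpha)
    bl <- conv3_backward_m(g_out, cache$enc_M[[l]], cache$enc_nin[l],
                           cache$enc_in_shape[[l]], ly$enc[[l]], 2L)
    g$enc[[l]] <- list(W = bl$dW, b = bl$db)
    g_out <- bl$dX
  }
  # same structural order as model$layers for the optimiser tree-walk
  g$dec[vapply(g$dec, is.null, TRUE)] <- list(list())
  out <- list(enc = g$enc, dec = g$dec)
  if (!is.null(ly$dec0)) out$dec0 <- g$dec0
  out$head <- g$head
  out
}

# encoder-only forward pass (used by the strategy classifier)
encoder_forward <- function(model, x0) {
  cfg <- model$config; L <- cfg$n_levels
  h <- x0; sh <- model$input_shape
  for (l in seq_len(L)) {
    cv <- conv3_forward(h, sh, model$layers$enc[[l]], stride = 2L)
    h <- leaky_forward(cv$y, cfg$leaky_relu_alpha)$y
    sh <- cv$shape
  }
  list(features = h, shape = sh)
}

# ---- spatial transformer --------------------------------------------------

#' Warp a moving volume with a displacement field
#'
#' Applies the spatial transformer: `w(x) = m(x + u(x))` with trilinear
#' interpolation, clamping samples outside the moving grid to the border.
#' The zero field is the exact identity (no interpolation error at grid
#' points).
#'
#' @param moving a [volume3d()] (or bare 3D array).
#' @param field a [displacement_field()] (or 4D array, voxel units) of the
#'   same spatial shape.
#' @return warped volume, same type as `moving`.
#' @export
warp_volume <- function(moving, field) {
  m_arr <- if (is_volume3d(moving)) moving$data else moving
  u <- if (inherits(field, "displacement_field")) field$u else field
  d <- dim(m_arr)
  if (!all(dim(u)[1:3] == d)) stop("field and moving shapes differ")
  g <- coord_grid(d)
  n <- nrow(g)
  coords <- g + matrix(u, nrow = n)
  w <- array(sample_trilinear(m_arr, coords), d)
  if (is_volume3d(moving))
    volume3d(w, moving$spacing, moving$origin, moving$modality)
  else w
}

# warp + derivative of each warped voxel w.r.t. its own displacement
# vector; compiled hot path, with the R sampler kept as reference
warp_with_grad <- function(m_arr, u) {
  d <- dim(m_arr)
  warp_grad_cpp(as.numeric(m_arr), as.integer(d),
                matrix(u, nrow = prod(d)), TRUE)
}

warp_with_grad_ref <- function(m_arr, u) {
  d <- dim(m_arr)
  g <- coord_grid(d)
  coords <- g + matrix(u, nrow = nrow(g))
  sample_trilinear(m_arr, coords, gradient = TRUE)
}

# ---- mutual information ---------------------------------------------------

#' Mutual information between two volumes
#'
#' Estimates MI (natural log) of the intensity distributions of two
#' volumes on a shared equal-width binning after per-image min-max
#' normalisation. `method = "hard"` is the exact histogram estimator used
#' as the test oracle; `method = "soft"` is the differentiable
#' Gaussian-Parzen estimator used as the similarity term of the
#' registration loss (`L_sim = -MI`). If either image has fewer than two
#' occupied bins the MI is 0 by convention.
#'
#' @param f,w volumes ([volume3d()] or 3D arrays) of equal shape.
#' @param bins number of intensity bins.
#' @param mask optional binary mask restricting the voxel population.
#' @param method `"hard"` or `"soft"`.
#' @param kernel_width Parzen kernel width on the normalised [0,1] scale
#'   (soft method).
#' @return list with `mi` (non-negative scalar, nats) and `dist`, an
#'   `intensity_joint` object: `joint` (bins x bins, sums to 1),
#'   `marginal_f`, `marginal_w`, `bin_edges`.
#' @export
mutual_information <- function(f, w, bins = 32L, mask = NULL,
                               method = c("hard", "soft"),
                               kernel_width = 1 / bins) {
  method <- match.arg(method)
  fv <- as.numeric(if (is_volume3d(f)) f$data else f)
  wv <- as.numeric(if (is_volume3d(w)) w$data else w)
  if (length(fv) != length(wv)) stop("'f' and 'w' must have equal shapes")
  if (!is.null(mask)) {
    mk <- as.logical(mask_data(mask))
    if (!any(mk)) stop("empty mask")
    fv <- fv[mk]; wv <- wv[mk]
  }
  fn <- normalize01(fv); wn <- normalize01(wv)
  if (is.null(fn) || is.null(wn)) {
    edges <- seq(0, 1, length.out = bins + 1)
    joint <- matrix(0, bins, bins); joint[1, 1] <- 1
    dist <- intensity_joint(joint, edges, edges)
    return(list(mi = 0, dist = dist))
  }
  if (method == "hard") mi_hard(fn, wn, bins) else
    mi_soft(fn, wn, bins, kernel_width)
}

normalize01 <- function(v) {
  r <- range(v)
  if (r[2] - r[1] <= 0) return(NULL)
  (v - r[1]) / (r[2] - r[1])
}

# modality-aware intensity preparation for the network and the MI loss:
# CT-like volumes are clipped to a soft-tissue window (-150..250 HU-like
# units) before min-max normalisation, so the air-bone dynamic range does
# not crush soft-tissue contrast into a fraction of a histogram bin;
# other modalities are plain min-max normalised
prep_intensities <- function(v) {
  if (is_volume3d(v)) {
    x <- as.numeric(v$data)
    if (v$modality == "CT-like") x <- pmin(pmax(x, -150), 250)
  } else x <- as.numeric(v)
  normalize01(x)
}

intensity_joint <- function(joint, edges_f, edges_w) {
  structure(list(joint = joint,
                 marginal_f = rowSums(joint),
                 marginal_w = colSums(joint),
                 bin_edges = list(f = edges_f, w = edges_w)),
            class = "intensity_joint")
}

mi_hard <- function(fn, wn, bins) {
  bi <- pmin(pmax(findInterval(fn, seq(0, 1, length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  bj <- pmin(pmax(findInterval(wn, seq(0, 1, length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(bi + (bj - 1L) * bins, nbins = bins * bins)
  P <- matrix(counts / length(fn), bins, bins)
  pf <- rowSums(P); pw <- colSums(P)
  nz <- P > 0
  mi <- sum(P[nz] * (log(P[nz]) -
                     log(pf[row(P)[nz]]) - log(pw[col(P)[nz]])))
  edges <- seq(0, 1, length.out = bins + 1)
  list(mi = max(mi, 0), dist = intensity_joint(P, edges, edges))
}

# Gaussian-Parzen soft binning on [0,1]; per-voxel normalised bin weights
parzen_weights <- function(v, bins, sigma) {
  centers <- (seq_len(bins) - 0.5) / bins
  G <- exp(-outer(v, centers, "-")^2 / (2 * sigma^2))
  G / rowSums(G)
}

mi_soft <- function(fn, wn, bins, sigma, want_grad = FALSE) {
  r <- mi_soft_cpp(fn, wn, as.integer(bins), sigma, want_grad)
  edges <- seq(0, 1, length.out = bins + 1)
  out <- list(mi = r$mi, dist = intensity_joint(r$joint, edges, edges))
  if (want_grad) out$dmi_dw <- as.numeric(r$dmi_dw)
  out
}

# pure-R reference implementation (test oracle for the compiled estimator)
mi_soft_ref <- function(fn, wn, bins, sigma, want_grad = FALSE) {
  eps <- 1e-10
  n <- length(fn)
  centers <- (seq_len(bins) - 0.5) / bins
  A <- parzen_weights(fn, bins, sigma)
  B <- parzen_weights(wn, bins, sigma)
  P <- crossprod(A, B) / n
  pf <- rowSums(P); pw <- colSums(P)
  lp <- log(P + eps) - outer(log(pf + eps), log(pw + eps), "+")
  mi <- sum(P * lp)
  edges <- seq(0, 1, length.out = bins + 1)
  out <- list(mi = max(mi, 0), dist = intensity_joint(P, edges, edges))
  if (want_grad) {
    # dMI/dP_ij = log(P/(pf pw)) - 1; chain through B's per-voxel softmax
    Gp <- lp - 1
    D <- (A %*% Gp) / n                       # n x bins, dMI/dB
    CW <- outer(wn, centers, function(v, c) (c - v) / sigma^2)
    mu <- rowSums(B * CW)
    out$dmi_dw <- rowSums(D * B * (CW - mu))
  }
  out
}

# ---- regularisers ---------------------------------------------------------

#' Displacement-field smoothness penalty
#'
#' Sum over voxels of the squared Euclidean norm of the spatial gradient
#' of the displacement, with gradients by forward differences (the last
#' voxel along each axis contributes a zero difference). Absolutely
#' homogeneous of degree 2.
#'
#' @param field a [displacement_field()] or 4D array (voxel units).
#' @return non-negative scalar.
#' @export
smoothness_loss <- function(field) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  total <- 0
  for (comp in 1:3) for (ax in 1:3) {
    dif <- forward_diff(u[, , , comp], ax)
    total <- total + sum(dif^2)
  }
  total
}

forward_diff <- function(a, ax) {
  d <- dim(a)
  if (d[ax] == 1L) return(array(0, d))
  idx_hi <- lapply(seq_along(d), function(i) seq_len(d[i]))
  idx_lo <- idx_hi
  idx_hi[[ax]] <- 2:d[ax]; idx_lo[[ax]] <- 1:(d[ax] - 1L)
  dif <- array(0, d)
  slice <- do.call(`[`, c(list(a), idx_hi, drop = FALSE)) -
           do.call(`[`, c(list(a), idx_lo, drop = FALSE))
  do.call(`[<-`, c(list(dif), idx_lo, list(slice)))
}

smoothness_grad <- function(u) {
  g <- array(0, dim(u))
  for (comp in 1:3) for (ax in 1:3) {
    dif <- forward_diff(u[, , , comp], ax)
    d <- dim(dif)
    idx_hi <- lapply(seq_along(d), function(i) seq_len(d[i]))
    idx_lo <- idx_hi
    idx_hi[[ax]] <- 2:d[ax]; idx_lo[[ax]] <- 1:(d[ax] - 1L)
    gc <- g[, , , comp]
    lo <- do.call(`[`, c(list(dif), idx_lo, drop = FALSE))
    gc <- do.call(`[<-`, c(list(gc), idx_lo,
                           list(do.call(`[`, c(list(gc), idx_lo,
                                               drop = FALSE)) - 2 * lo)))
    gc <- do.call(`[<-`, c(list(gc), idx_hi,
                           list(do.call(`[`, c(list(gc), idx_hi,
                                               drop = FALSE)) + 2 * lo)))
    g[, , , comp] <- gc
  }
  g
}

#' L2 penalty on the displacement field
#'
#' Sum over all voxels of the squared displacement components (keeps the
#' field small; the counterpart of weight decay on the warp itself).
#'
#' @inheritParams smoothness_loss
#' @return non-negative scalar.
#' @export
l2_penalty <- function(field) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  sum(u^2)
}

#' Registration loss
#'
#' The composite training objective
#' `-MI(f, warp(m, field)) + lambda1 * smoothness + lambda2 * L2`,
#' evaluated over the entire volumes (no ROI masking during registration
#' training). Components are reported separately for logging.
#'
#' @param f,m fixed and moving volumes ([volume3d()] or arrays) with
#'   intensities; internally min-max normalised before the MI term.
#' @param field displacement field (voxel units).
#' @param config a [dlir_config()] supplying the lambdas and MI settings.
#' @return list with `value` and `components` (`sim`, `smooth`, `l2`).
#' @export
dlir_loss <- function(f, m, field, config = dlir_config()) {
  f_arr <- if (is_volume3d(f)) f$data else f
  m_arr <- if (is_volume3d(m)) m$data else m
  u <- if (inherits(field, "displacement_field")) field$u else field
  w <- warp_volume(m_arr, u)
  mi <- mutual_information(f_arr, w, bins = config$mi_bins, method = "soft",
                           kernel_width = config$mi_kernel_width)$mi
  red <- if (config$loss_reduction == "mean") prod(dim(u)[1:3]) else 1
  sm <- smoothness_loss(u) / red
  l2 <- l2_penalty(u) / red
  list(value = -mi + config$lambda1 * sm + config$lambda2 * l2,
       components = list(sim = -mi, smooth = sm, l2 = l2))
}

# loss + gradient w.r.t. the field; f and m must already be normalised to
# [0, 1] (the training path normalises once per case)
dlir_loss_grad <- function(fn_vec, m_arr, u, config) {
  wg <- warp_with_grad(m_arr, u)
  ms <- mi_soft(fn_vec, wg$value, config$mi_bins, config$mi_kernel_width,
                want_grad = TRUE)
  d <- dim(u)[1:3]
  red <- if (config$loss_reduction == "mean") prod(d) else 1
  dfield <- matrix(-ms$dmi_dw, nrow = length(fn_vec), ncol = 3) * wg$grad
  g <- array(dfield, c(d, 3)) +
    (config$lambda1 / red) * smoothness_grad(u) +
    (config$lambda2 / red) * 2 * u
  sm <- smoothness_loss(u) / red; l2 <- l2_penalty(u) / red
  list(value = -ms$mi + config$lambda1 * sm + config$lambda2 * l2,
       components = list(sim = -ms$mi, smooth = sm, l2 = l2),
       dfield = matrix(g, ncol = 3))
}

# ---- training and inference -----------------------------------------------

#' Fit the registration network on a cohort of image pairs
#'
#' Unsupervised training: for each case the moving and fixed volumes are
#' min-max normalised, concatenated (channel order m, f), passed through
#' the U-Net to predict a displacement field, and the network weights are
#' updated by Adam on the composite loss. Runs are reproducible under
#' `config$seed`.
#'
#' @param cases list of cases; each must carry `$fixed` and `$moving`
#'   [volume3d()] elements (e.g. [generate_case()] output).
#' @param config a [dlir_config()].
#' @param verbose print per-epoch mean loss.
#' @return a trained `dlir_model`; `$history` holds the per-epoch mean
#'   loss and components.
#' @export
dlir_fit <- function(cases, config = dlir_config(), verbose = FALSE) {
  if (length(cases) < 1L) stop("need at least one training case")
  shp <- dim(cases[[1]]$fixed$data)
  model <- dlir_build(config, shp)
  prepped <- lapply(cases, function(cs) {
    fn <- prep_intensities(cs$fixed)
    mn <- prep_intensities(cs$moving)
    if (is.null(fn) || is.null(mn)) stop("flat training volume")
    list(fn = fn, m_arr = array(mn, shp), x0 = cbind(mn, fn))
  })
  adam <- adam_init(model$layers)
  n <- length(prepped)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     sim = numeric(0), smooth = numeric(0), l2 = numeric(0))
  model <- with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      lr_ep <- config$learning_rate[min(ep, length(config$learning_rate))]
      ord <- sample.int(n)
      ep_loss <- ep_sim <- ep_sm <- ep_l2 <- 0
      acc <- NULL; acc_n <- 0L
      for (i in ord) {
        p <- prepped[[i]]
        fw <- net_forward(model, p$x0, cache = TRUE)
        u <- array(fw$field, c(shp, 3))
        lg <- dlir_loss_grad(p$fn, p$m_arr, u, config)
        if (!is.finite(lg$value))
          stop(sprintf("non-finite loss at epoch %d (sim %.4g, smooth %.4g, l2 %.4g)",
                       ep, lg$components$sim, lg$components$smooth,
                       lg$components$l2))
        grads <- net_backward(model, fw$cache, lg$dfield)
        acc <- grad_accumulate(acc, grads); acc_n <- acc_n + 1L
        if (acc_n >= config$batch_size) {
          upd <- adam_step(model$layers, clip_global_norm(acc,
                             config$max_grad_norm), adam, lr = lr_ep)
          model$layers <- upd$params; adam <- upd$state
          acc <- NULL; acc_n <- 0L
        }
        ep_loss <- ep_loss + lg$value
        ep_sim <- ep_sim + lg$components$sim
        ep_sm <- ep_sm + lg$components$smooth
        ep_l2 <- ep_l2 + lg$components$l2
      }
      if (acc_n > 0L) {
        upd <- adam_step(model$layers, clip_global_norm(acc,
                           config$max_grad_norm), adam, lr = lr_ep)
        model$layers <- upd$params; adam <- upd$state
      }
      hist[ep, ] <- c(ep, ep_loss / n, ep_sim / n, ep_sm / n, ep_l2 / n)
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f (sim %.5f)", ep,
                        ep_loss / n, ep_sim / n))
    }
    model
  })
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Register a moving to a fixed volume with a trained network
#'
#' Inference pass: predicts the displacement field for the pair and warps
#' the moving volume with it. Deterministic.
#'
#' @param model a `dlir_model`.
#' @param fixed,moving [volume3d()] volumes matching the model's input
#'   shape.
#' @return list with `field` (a [displacement_field()], voxel units) and
#'   `warped` (a [volume3d()]).
#' @export
register <- function(model, fixed, moving) {
  stopifnot(inherits(model, "dlir_model"))
  shp <- model$input_shape
  if (!all(dim(fixed$data) == shp) || !all(dim(moving$data) == shp))
    stop("volume shape does not match the model input shape")
  fn <- prep_intensities(fixed)
  mn <- prep_intensities(moving)
  if (is.null(fn) || is.null(mn)) stop("flat input volume")
  fw <- net_forward(model, cbind(mn, fn), cache = FALSE,
                    expansion = "trilinear")
  u <- array(fw$field, c(shp, 3))
  field <- displacement_field(u, spacing = fixed$spacing)
  list(field = field, warped = warp_volume(moving, field))
}

#' @export
predict.dlir_model <- function(object, fixed, moving, ...) {
  register(object, fixed, moving)
}

#' @export
plot.dlir_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "mean training loss", main = "Registration training", ...)
  invisible(x)
}

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
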