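#' Configuration of the adaptive-strategy classifier
#'
#' The classifier reuses the registration network's encoder, frozen, as a
#' feature extractor on the ROI-masked image pair, and trains only a small
#' fully connected head: bridge (flattened deepest features by default) ->
#' FC(`fc_hidden`) with LeakyReLU -> FC(1) -> sigmoid, optimised with Adam
#' on binary cross-entropy. Defaults follow the published recipe
#' (learning rate 1e-5, 300 epochs, batch size 2, decision threshold
#' 0.64); `fc_hidden` and the bridge are implementation choices documented
#' in the methods vignette.
#'
#' @param fc_hidden width of the first FC layer.
#' @param learning_rate,epochs,batch_size Adam recipe for the head.
#' @param decision_threshold probability above which ATS is chosen
#'   (strictly greater; a tie yields ATP).
#' @param bridge `"flatten"` (all deepest-feature cells, the default:
#'   strategy-relevant deformation is localised around the target, and
#'   averaging over the mostly-empty ROI-masked feature grid dilutes it)
#'   or `"gap"` (global average pooling, one value per channel;
#'   shape-robust and far fewer parameters).
#' @param weight_decay L2 penalty on the FC weight matrices added to the
#'   training gradient (decoupled, AdamW-style); regularises the head on
#'   small cohorts.
#' @param seed integer seed for head initialisation and batch order.
#' @return list of class `dlsp_config`.
#' @export
dlsp_config <- function(fc_hidden = 64L, learning_rate = 1e-5,
                        epochs = 300L, batch_size = 2L,
                        decision_threshold = 0.64,
                        bridge = c("flatten", "gap"), weight_decay = 0,
                        seed = 1L) {
  bridge <- match.arg(bridge)
  if (weight_decay < 0) stop("'weight_decay' must be >= 0")
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stop("'decision_threshold' must be in (0, 1)")
  if (epochs < 1) stop("'epochs' must be at least 1")
  structure(list(fc_hidden = as.integer(fc_hidden),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 decision_threshold = decision_threshold, bridge = bridge,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "dlsp_config")
}

#' Build a strategy classifier from a registration model
#'
#' Copies the registration encoder (kept bit-identical and never updated)
#' and attaches a freshly initialised fully connected head. The deepest
#' encoder features are bridged to the head by global average pooling
#' (one value per channel) or flattening, per the config.
#'
#' @param reg_model a `dlir_model` (trained or initialised).
#' @param config a [dlsp_config()].
#' @return object of class `dlsp_model` (untrained head).
#' @export
dlsp_build <- function(reg_model, config = dlsp_config()) {
  stopifnot(inherits(reg_model, "dlir_model"), inherits(config, "dlsp_config"))
  deep_shape <- encoder_output_shape(reg_model$input_shape,
                                     reg_model$config$n_levels)
  n_ch <- reg_model$enc_channels[reg_model$config$n_levels]
  feat_dim <- if (config$bridge == "gap") n_ch else prod(deep_shape) * n_ch
  head <- with_seed(config$seed, list(
    W1 = matrix(stats::rnorm(feat_dim * config$fc_hidden,
                             sd = sqrt(2 / feat_dim)),
                feat_dim, config$fc_hidden),
    b1 = numeric(config$fc_hidden),
    W2 = matrix(stats::rnorm(config$fc_hidden, sd = sqrt(2 / config$fc_hidden)),
                config$fc_hidden, 1),
    b2 = 0))
  structure(list(encoder = reg_model$layers$enc,
                 enc_config = reg_model$config,
                 input_shape = reg_model$input_shape,
                 enc_channels = reg_model$enc_channels,
                 deep_shape = deep_shape, feat_dim = feat_dim,
                 head = head, config = config,
                 feat_center = rep(0, feat_dim), feat_scale = rep(1, feat_dim),
                 trained = FALSE, history = NULL),
            class = "dlsp_model")
}

#' @export
print.dlsp_model <- function(x, ...) {
  cat(sprintf("<dlsp_model> frozen %d-level encoder + FC(%d) head (%s bridge)%s\n",
              x$enc_config$n_levels, x$config$fc_hidden, x$config$bridge,
              if (x$trained) ", trained" else ", untrained head"))
  cat(sprintf("  decision threshold %.2f (p > threshold => ATS)\n",
              x$config$decision_threshold))
  invisible(x)
}

#' @export
summary.dlsp_model <- function(object, ...) {
  h <- object$head
  n_train <- length(h$W1) + length(h$b1) + length(h$W2) + length(h$b2)
  n_frozen <- sum(vapply(object$encoder,
                         function(l) length(l$W) + length(l$b), 0))
  out <- list(trainable_parameters = n_train,
              frozen_parameters = n_frozen,
              feat_dim = object$feat_dim, trained = object$trained,
              threshold = object$config$decision_threshold)
  cat(sprintf("dlsp_model: %d trainable head parameters, %d frozen encoder parameters\n",
              n_train, n_frozen))
  invisible(out)
}

#' ROI-mask an image pair for classification
#'
#' Builds the classifier's 2-channel input: each channel is min-max
#' normalised using only in-ROI intensities and then multiplied voxelwise
#' by the binary ROI, so voxels outside the ROI are exactly zero and
#' contribute nothing to the encoder features (perturbing them cannot
#' change the prediction).
#'
#' @param moving,fixed [volume3d()] volumes on a common grid (channel
#'   order m, f, matching the registration network input).
#' @param roi binary ROI ([expand_mask()] output, mask volume, or array);
#'   must be non-empty.
#' @return `n_voxels x 2` input matrix.
#' @export
apply_roi <- function(moving, fixed, roi) {
  m_arr <- if (is_volume3d(moving)) moving$data else moving
  f_arr <- if (is_volume3d(fixed)) fixed$data else fixed
  rv <- as.numeric(mask_data(roi))
  if (!all(dim(m_arr) == dim(f_arr)) || length(rv) != length(m_arr))
    stop("moving, fixed and ROI shapes differ")
  if (sum(rv) == 0) stop("empty ROI")
  ch <- function(v, ct_like) {
    if (ct_like) v <- pmin(pmax(v, -150), 250)  # soft-tissue window
    vin <- v[rv == 1]
    r <- range(vin)
    vn <- if (r[2] - r[1] <= 0) as.numeric(v != 0) else (v - r[1]) / (r[2] - r[1])
    vn * rv
  }
  cbind(ch(as.numeric(m_arr),
           is_volume3d(moving) && moving$modality == "CT-like"),
        ch(as.numeric(f_arr),
           is_volume3d(fixed) && fixed$modality == "CT-like"))
}

# pooled (standardised) feature vector of one case
dlsp_features <- function(model, moving, fixed, roi) {
  x <- apply_roi(moving, fixed, roi)
  stub <- list(config = model$enc_config, input_shape = model$input_shape,
               layers = list(enc = model$encoder))
  ef <- encoder_forward(stub, x)
  if (model$config$bridge == "gap") colMeans(ef$features)
  else as.numeric(ef$features)
}

head_forward <- function(head, z, alpha = 0.2) {
  a1 <- drop(z %*% head$W1) + head$b1
  h1 <- ifelse(a1 > 0, a1, alpha * a1)
  logit <- sum(h1 * head$W2) + head$b2
  p <- 1 / (1 + exp(-logit))
  list(p = p, a1 = a1, h1 = h1)
}

#' Binary cross-entropy
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` over cases, probabilities
#' clipped away from 0 and 1.
#'
#' @param labels labels (`"ATP"`/`"ATS"` or 0/1, 1 = ATS).
#' @param probs predicted probabilities.
#' @param eps clipping bound.
#' @return non-negative scalar.
#' @export
bce_loss <- function(labels, probs, eps = 1e-7) {
  y <- as_binary_labels(labels)
  if (length(y) != length(probs)) stop("lengths differ")
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the strategy classifier head
#'
#' Extracts the frozen-encoder feature vector of every case once (the
#' encoder never changes, so features are fixed), standardises features
#' with the training-set mean and deviation, and optimises the FC head by
#' Adam on binary cross-entropy. The encoder is asserted bit-identical
#' after training. Deterministic under `config$seed`.
#'
#' @param classifier a `dlsp_model` from [dlsp_build()].
#' @param cases list of `synthetic_case` (need `$moving`, `$fixed`,
#'   `$roi_mask`, `$label`); apply the patient-level train/test split
#'   upstream.
#' @param config optional [dlsp_config()] overriding the classifier's.
#' @param verbose print per-epoch BCE.
#' @return the trained `dlsp_model` with `$history` (per-epoch mean BCE).
#' @export
dlsp_fit <- function(classifier, cases, config = NULL, verbose = FALSE) {
  stopifnot(inherits(classifier, "dlsp_model"))
  if (!is.null(config)) classifier$config <- config
  cfg <- classifier$config
  y <- as_binary_labels(vapply(cases, `[[`, "", "label"))
  if (length(unique(y)) < 2)
    warning("single-class training set: downstream AUC will be undefined")
  enc_before <- classifier$encoder
  Z <- t(vapply(cases, function(cs)
    dlsp_features(classifier, cs$moving, cs$fixed, cs$roi_mask),
    numeric(classifier$feat_dim)))
  classifier <- dlsp_fit_features(classifier, Z, y, verbose = verbose)
  stopifnot(identical(enc_before, classifier$encoder))  # frozen invariant
  classifier
}

# head training on a precomputed feature matrix (the encoder is frozen, so
# features are constants of the optimisation)
dlsp_fit_features <- function(classifier, Z, y, verbose = FALSE) {
  cfg <- classifier$config
  ctr <- colMeans(Z)
  scl <- apply(Z, 2, stats::sd); scl[scl < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, ctr), 2, scl, "/")
  classifier$feat_center <- ctr; classifier$feat_scale <- scl
  head <- classifier$head
  adam <- adam_init(head)
  n <- nrow(Z)
  wd <- cfg$weight_decay %||% 0
  hist <- data.frame(epoch = integer(0), bce = numeric(0))
  head <- with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_probs <- numeric(n)
      for (b in batches) {
        g <- list(W1 = head$W1 * 0, b1 = head$b1 * 0,
                  W2 = head$W2 * 0, b2 = 0)
        for (i in b) {
          z <- Zs[i, ]
          fwd <- head_forward(head, z)
          ep_probs[i] <- fwd$p
          dlogit <- (fwd$p - y[i]) / length(b)   # dBCE/dlogit (mean over batch)
          dh1 <- drop(head$W2) * dlogit
          da1 <- dh1 * ifelse(fwd$a1 > 0, 1, 0.2)
          g$W1 <- g$W1 + outer(z, da1)
          g$b1 <- g$b1 + da1
          g$W2 <- g$W2 + matrix(fwd$h1 * dlogit, ncol = 1)
          g$b2 <- g$b2 + dlogit
        }
        if (wd > 0) {
          g$W1 <- g$W1 + wd * head$W1
          g$W2 <- g$W2 + wd * head$W2
        }
        upd <- adam_step(head, g, adam, lr = cfg$learning_rate)
        head <- upd$params; adam <- upd$state
      }
      hist[ep, ] <- c(ep, bce_loss(y, ep_probs))
      if (verbose) message(sprintf("epoch %3d  BCE %.5f", ep, hist$bce[ep]))
    }
    head
  })
  classifier$head <- head
  classifier$trained <- TRUE
  classifier$history <- hist
  classifier
}

#' Predict the adaptive strategy for cases
#'
#' Produces the ATS probability for each case and applies the strict
#' decision rule: ATS iff the probability is greater than the threshold
#' (a probability exactly at the threshold yields ATP). Deterministic.
#'
#' @param object a trained `dlsp_model`.
#' @param cases one `synthetic_case` or a list of them (alternatively a
#'   list of `list(moving, fixed, roi_mask)` triples).
#' @param threshold decision threshold; defaults to the config's.
#' @param ... unused.
#' @return `data.frame(patient_id, fraction_index, probability, label,
#'   threshold_used)`.
#' @export
predict.dlsp_model <- function(object, cases,
                               threshold = object$config$decision_threshold,
                               ...) {
  if (inherits(cases, "synthetic_case") ||
      (!is.null(cases$moving) && !is.null(cases$fixed)))
    cases <- list(cases)
  rows <- lapply(cases, function(cs) {
    z <- dlsp_features(object, cs$moving, cs$fixed, cs$roi_mask)
    zs <- (z - object$feat_center) / object$feat_scale
    p <- head_forward(object$head, zs)$p
    data.frame(patient_id = if (!is.null(cs$patient_id)) cs$patient_id else NA,
               fraction_index = if (!is.null(cs$fraction_index))
                 cs$fraction_index else NA,
               probability = p,
               label = if (p > threshold) "ATS" else "ATP",
               threshold_used = threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
plot.dlsp_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  plot(x$history$epoch, x$history$bce, type = "l", xlab = "epoch",
       ylab = "training BCE", main = "Strategy-classifier training", ...)
  invisible(x)
}
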