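tiny_dlir <- function() {
  if (is.null(.fixture_env$tiny_dlir)) {
    cfg <- dlir_config(n_levels = 2L, base_channels = 4L, seed = 41L)
    .fixture_env$tiny_dlir <- dlir_build(cfg, c(16, 16, 16))
  }
  .fixture_env$tiny_dlir
}

tiny_dlsp_cohort <- function() {
  if (is.null(.fixture_env$tiny_dlsp_cohort))
    .fixture_env$tiny_dlsp_cohort <-
      generate_cohort(tiny_spec(seed = 43L), 4, 2, ats_fraction_target = 0.5)
  .fixture_env$tiny_dlsp_cohort
}

test_that("the classifier head outputs probabilities and only FC parameters train", {
  clf <- dlsp_build(tiny_dlir(), dlsp_config(fc_hidden = 8L, bridge = "gap",
                                             seed = 2L))
  cs <- tiny_case(seed = 43L)
  pred <- predict(clf, cs)
  expect_gt(pred$probability, 0)
  expect_lt(pred$probability, 1)

  info <- summary(clf)
  # GAP bridge: deepest channels (8) -> FC(8) -> FC(1)
  expect_equal(info$trainable_parameters, 8 * 8 + 8 + 8 + 1)
  expect_equal(info$frozen_parameters,
               sum(vapply(tiny_dlir()$layers$enc,
                          function(l) length(l$W) + length(l$b), 0)))

  # flatten bridge dimension: deepest 4^3 cells x 8 channels
  clf_f <- dlsp_build(tiny_dlir(), dlsp_config(fc_hidden = 8L,
                                               bridge = "flatten", seed = 2L))
  expect_equal(clf_f$feat_dim, 4 * 4 * 4 * 8)
  expect_equal(summary(clf_f)$trainable_parameters, 512 * 8 + 8 + 8 + 1)
})

test_that("binary cross-entropy matches direct evaluation and the brute force mean", {
  expect_equal(bce_loss(1, 1), 0, tolerance = 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.1)), -log(0.9), tolerance = 1e-12)
  expect_error(bce_loss(c(1, 0), 0.5), "lengths")

  set.seed(44)
  y <- rbinom(40, 1, 0.5); p <- runif(40)
  brute <- mean(vapply(seq_along(y), function(i)
    -(y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i])), 0))
  expect_equal(bce_loss(y, p), brute, tolerance = 1e-12)
})

test_that("ROI masking zeroes outside voxels and makes predictions invariant to them", {
  cs <- tiny_case(seed = 43L)
  x <- apply_roi(cs$moving, cs$fixed, cs$roi_mask)
  rv <- as.numeric(cs$roi_mask$mask$data)
  expect_true(all(x[rv == 0, ] == 0))

  ones <- volume3d(array(1, dim(cs$fixed$data)), cs$fixed$spacing,
                   modality = "mask")
  x1 <- apply_roi(cs$moving, cs$fixed, ones)
  expect_equal(x1[, 2], (as.numeric(cs$fixed$data) - min(cs$fixed$data)) /
                 diff(range(cs$fixed$data)), tolerance = 1e-12)

  zeros <- volume3d(array(0, dim(cs$fixed$data)), cs$fixed$spacing,
                    modality = "mask")
  expect_error(apply_roi(cs$moving, cs$fixed, zeros), "empty ROI")

  clf <- dlsp_build(tiny_dlir(), dlsp_config(fc_hidden = 8L, seed = 2L))
  p0 <- predict(clf, cs)$probability
  # perturb both images only outside the ROI
  out <- cs
  noise <- array(rnorm(length(out$fixed$data), sd = 50),
                 dim(out$fixed$data)) * (1 - cs$roi_mask$mask$data)
  out$fixed <- volume3d(out$fixed$data + noise, out$fixed$spacing,
                        modality = "MR-like")
  out$moving <- volume3d(out$moving$data + 2 * noise, out$moving$spacing,
                         modality = "CT-like")
  expect_identical(predict(clf, out)$probability, p0)
})

test_that("head training lowers BCE, is seeded, and never touches the encoder", {
  cohort <- tiny_dlsp_cohort()
  clf <- dlsp_build(tiny_dlir(), dlsp_config(fc_hidden = 8L,
                                             learning_rate = 5e-2,
                                             epochs = 60L, seed = 3L))
  enc_before <- clf$encoder
  fit <- dlsp_fit(clf, cohort)
  expect_identical(fit$encoder, enc_before)        # bitwise frozen
  expect_lt(fit$history$bce[nrow(fit$history)], fit$history$bce[1])

  fit2 <- dlsp_fit(dlsp_build(tiny_dlir(),
                              dlsp_config(fc_hidden = 8L,
                                          learning_rate = 5e-2,
                                          epochs = 60L, seed = 3L)), cohort)
  expect_identical(fit$head, fit2$head)            # seeded determinism

  single <- cohort[vapply(cohort, `[[`, "", "label") == "ATS"]
  expect_warning(dlsp_fit(dlsp_build(tiny_dlir(),
                                     dlsp_config(fc_hidden = 8L, epochs = 1L,
                                                 seed = 3L)),
                          single), "single-class")
})

test_that("the decision rule is strictly greater-than with ties going to ATP", {
  cohort <- tiny_dlsp_cohort()
  clf <- dlsp_build(tiny_dlir(), dlsp_config(fc_hidden = 8L, seed = 2L))
  p <- predict(clf, cohort[[1]])$probability
  expect_identical(predict(clf, cohort[[1]], threshold = p)$label, "ATP")
  expect_identical(predict(clf, cohort[[1]],
                           threshold = p - 1e-9)$label, "ATS")
  # default threshold is the published operating point
  expect_equal(clf$config$decision_threshold, 0.64)
  pr <- predict(clf, cohort[1:4])
  expect_identical(pr$label, ifelse(pr$probability > 0.64, "ATS", "ATP"))
})
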