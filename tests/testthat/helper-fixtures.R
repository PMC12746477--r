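# Shared fixtures. Small phantoms keep unit tests fast; the desk-scale
# registration model used by the end-to-end checks is trained once and
# memoised for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

# a small fast phantom: 16^3 voxels, 12 mm spacing (192 mm extent)
tiny_spec <- function(seed = 11L, ...) {
  phantom_spec(grid_shape = c(16, 16, 16), voxel_spacing = c(12, 12, 12),
               deformation_smoothness = 40, roi_margin_mm = 40,
               seed = seed, ...)
}

tiny_case <- function(seed = 11L, ...) {
  key <- paste0("case_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_case(tiny_spec(seed = seed, ...))
  .fixture_env[[key]]
}

# desk-scale training conditions for the end-to-end recovery checks:
# 64 x 64 x 32 voxel grid (3 x 3 x 6 mm), 24 training + 8 held-out
# fractions, the published network shape, per-voxel ("mean") loss
# reduction, stride-4 control-grid field with block-basis training, and a
# short stepped-Adam schedule (see the methods vignette)
desk_cohort <- function() {
  if (is.null(.fixture_env$desk_cohort)) {
    spec <- phantom_spec(seed = 42L)
    .fixture_env$desk_cohort <- generate_cohort(spec, n_patients = 16,
                                                fractions_per_patient = 2,
                                                ats_fraction_target = 0.6)
  }
  .fixture_env$desk_cohort
}

desk_dlir_config <- function() {
  dlir_config(learning_rate = c(rep(3e-3, 30), rep(1e-3, 15)),
              epochs = 45L, mi_bins = 32L, lambda1 = 1, lambda2 = 0.02,
              field_stride = 4L, field_expansion = "nearest",
              loss_reduction = "mean", seed = 7L)
}

desk_dlir_model <- function() {
  if (is.null(.fixture_env$desk_model)) {
    cohort <- desk_cohort()
    .fixture_env$desk_model <- dlir_fit(cohort[1:24], desk_dlir_config())
  }
  .fixture_env$desk_model
}

# nearest-neighbour mask warping for Dice/HD evaluation of registration
warp_mask <- function(mask, field) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  d <- dim(mask$data)
  g <- cbind(rep.int(seq_len(d[1]), d[2] * d[3]),
             rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
             rep(seq_len(d[3]), each = d[1] * d[2]))
  coords <- round(g + matrix(u, nrow = nrow(g)))
  i1 <- pmin(pmax(coords[, 1], 1), d[1])
  i2 <- pmin(pmax(coords[, 2], 1), d[2])
  i3 <- pmin(pmax(coords[, 3], 1), d[3])
  out <- array(mask$data[i1 + (i2 - 1) * d[1] + (i3 - 1) * d[1] * d[2]], d)
  volume3d(out, mask$spacing, mask$origin, modality = "mask")
}

# brute-force O(n^2) Mann-Whitney AUC oracle (ties count 1/2)
auc_oracle <- function(labels, probs) {
  y <- as.integer(labels == 1 | labels == "ATS")
  pos <- probs[y == 1]; neg <- probs[y == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}
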