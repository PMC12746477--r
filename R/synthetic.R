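#' Specification of a synthetic deformable phantom
#'
#' Parameters of the paired-volume generator: a pelvic-like arrangement of
#' smooth ellipsoids (body, bladder-like, prostate-like, rectum-like blobs,
#' plus lateral bone for modality contrast) is rendered through a
#' piecewise-linear "CT" transfer function to give the reference (moving)
#' image, deformed by a Gaussian-correlated random displacement field, and
#' re-rendered through a saturating nonlinear "MR" transfer function plus
#' noise to give the daily (fixed) image. The geometric ground-truth rule
#' labels a fraction ATS when the mean displacement magnitude inside the
#' PTV + margin region of interest exceeds `label_threshold`.
#'
#' @param grid_shape integer length-3, voxels (each >= 8).
#' @param voxel_spacing mm per voxel.
#' @param deformation_amplitude peak displacement magnitude, mm.
#' @param deformation_smoothness Gaussian correlation length of the random
#'   field, mm (must exceed the voxel spacing).
#' @param texture_amplitude amplitude of the smooth intra-tissue texture
#'   added to the anatomy scalar before rendering (fraction of the [0,1]
#'   anatomy scale). The texture deforms together with the anatomy, so it
#'   is the shared structure both modalities see; without it the phantom
#'   would be piecewise constant and mutual information would be blind to
#'   misalignment inside homogeneous regions.
#' @param texture_smoothness Gaussian correlation length of the texture
#'   (mm).
#' @param noise_sigma additive Gaussian noise on the MR-like image
#'   (intensity units of its 0-100 scale).
#' @param label_threshold mean in-ROI displacement (mm) above which a case
#'   is labelled ATS.
#' @param roi_margin_mm isotropic expansion of the PTV surrogate forming
#'   the ROI mask.
#' @param seed integer seed; all case randomness derives from it.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32),
                         voxel_spacing = c(3, 3, 6),
                         deformation_amplitude = 8,
                         deformation_smoothness = 30,
                         texture_amplitude = 0.08,
                         texture_smoothness = 15,
                         noise_sigma = 2,
                         label_threshold = 3,
                         roi_margin_mm = 50,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("'grid_shape' must be 3 integers, each at least 8")
  if (any(voxel_spacing <= 0)) stop("'voxel_spacing' must be positive")
  if (deformation_amplitude < 0) stop("'deformation_amplitude' must be >= 0")
  if (deformation_smoothness <= max(voxel_spacing))
    stop("'deformation_smoothness' must exceed the voxel spacing (the field must be resolvable)")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (texture_amplitude < 0) stop("'texture_amplitude' must be >= 0")
  if (label_threshold <= 0) stop("'label_threshold' must be positive")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing = as.numeric(voxel_spacing),
                 deformation_amplitude = deformation_amplitude,
                 deformation_smoothness = deformation_smoothness,
                 texture_amplitude = texture_amplitude,
                 texture_smoothness = texture_smoothness,
                 noise_sigma = noise_sigma,
                 label_threshold = label_threshold,
                 roi_margin_mm = roi_margin_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# ---- anatomy --------------------------------------------------------------

# separable Gaussian smoothing (sigma in voxels per axis, zero padding)
gaussian_smooth <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[min(ax, length(sigma_vox))]
    if (s <= 0 || d[ax] == 1L) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s); k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    M <- matrix(aperm(a, perm), nrow = d[ax])
    n <- d[ax]
    out <- matrix(0, n, ncol(M))
    for (j in -r:r) {
      w <- k[j + r + 1L]
      rows <- max(1L, 1L - j):min(n, n - j)
      out[rows, ] <- out[rows, ] + w * M[rows + j, , drop = FALSE]
    }
    a <- aperm(array(out, d[perm]), order(perm))
  }
  a
}

# mm coordinates of every voxel, centred on the grid
centered_mm_grid <- function(shape, spacing) {
  g <- coord_grid(shape)
  ctr <- (shape + 1) / 2
  cbind((g[, 1] - ctr[1]) * spacing[1],
        (g[, 2] - ctr[2]) * spacing[2],
        (g[, 3] - ctr[3]) * spacing[3])
}

in_ellipsoid <- function(xyz, center, radii) {
  ((xyz[, 1] - center[1]) / radii[1])^2 +
  ((xyz[, 2] - center[2]) / radii[2])^2 +
  ((xyz[, 3] - center[3]) / radii[3])^2 <= 1
}

# tissue-class anatomy; class codes: 0 air, 1 body, 2 bladder, 3 rectum,
# 4 prostate, 5 bone. Scalar "anatomy" value per class is monotone so both
# transfer functions can be monotone in it.
CLASS_VALUES <- c(air = 0, body = 0.55, bladder = 0.35, rectum = 0.45,
                  prostate = 0.65, bone = 0.95)

build_anatomy <- function(shape, spacing) {
  xyz <- centered_mm_grid(shape, spacing)
  half_extent <- (shape - 1) / 2 * spacing
  sc <- pmin(half_extent / 96, 1)  # shrink organs on grids smaller than ~192 mm
  cls <- integer(nrow(xyz))
  cls[in_ellipsoid(xyz, c(0, 0, 0) * sc,
                   c(0.88, 0.83, 0.94) * half_extent)] <- 1L
  cls[in_ellipsoid(xyz, c(-60, 5, -5) * sc, c(12, 12, 12) * sc)] <- 5L
  cls[in_ellipsoid(xyz, c(60, 5, -5) * sc, c(12, 12, 12) * sc)] <- 5L
  cls[in_ellipsoid(xyz, c(0, -35, 8) * sc, c(22, 18, 16) * sc)] <- 2L
  cls[in_ellipsoid(xyz, c(0, 32, -5) * sc, c(11, 11, 40) * sc)] <- 3L
  cls[in_ellipsoid(xyz, c(0, 0, -4) * sc, c(16, 14, 13) * sc)] <- 4L
  cls <- array(cls, shape)
  a <- array(CLASS_VALUES[cls + 1L], shape)
  a <- gaussian_smooth(a, rep(1, 3))
  list(class_map = cls, anatomy = a)
}

# transfer functions: piecewise-linear CT (HU-like, strong bone contrast)
# and saturating nonlinear MR (compressed high end) -- both monotone in the
# anatomy scalar, deliberately non-affinely related so that voxelwise
# intensity-difference similarity fails across the pair while mutual
# information does not.
ct_transfer <- function(a) {
  stats::approx(x = c(0, 0.35, 0.45, 0.55, 0.65, 0.95, 1),
                y = c(-1000, 0, 45, 70, 100, 1200, 1400),
                xout = pmin(pmax(a, 0), 1))$y
}

mr_transfer <- function(a) 100 * (1 - exp(-3 * pmin(pmax(a, 0), 1)))

# ---- random displacement fields -------------------------------------------

# smooth random vector field in mm: white noise filtered with a Gaussian of
# the given correlation length
smooth_random_field_mm <- function(shape, spacing, smoothness_mm) {
  u <- array(0, c(shape, 3))
  sig_vox <- smoothness_mm / spacing
  for (comp in 1:3) {
    noise <- array(stats::rnorm(prod(shape)), shape)
    u[, , , comp] <- gaussian_smooth(noise, sig_vox)
  }
  u
}

case_seed <- function(seed, patient_id, fraction_index) {
  h <- sum(utf8ToInt(as.character(patient_id)) *
           seq_along(utf8ToInt(as.character(patient_id))))
  (abs(seed) * 10007 + h * 101 + as.integer(fraction_index)) %% 2147483629
}

# anatomy + ROI are deterministic per (shape, spacing, margin, texture
# settings, seed); cache them — they are shared by every fraction
.anatomy_cache <- new.env(parent = emptyenv())

anatomy_and_roi <- function(shape, spacing, roi_margin_mm,
                            texture_amplitude = 0, texture_smoothness = 15,
                            seed = 0L) {
  key <- paste(c(shape, signif(spacing, 10), signif(roi_margin_mm, 10),
                 signif(texture_amplitude, 10),
                 signif(texture_smoothness, 10),
                 if (texture_amplitude > 0) seed else 0L),
               collapse = "_")
  hit <- .anatomy_cache[[key]]
  if (!is.null(hit)) return(hit)
  an <- build_anatomy(shape, spacing)
  if (texture_amplitude > 0) {
    tex <- with_seed(seed * 31L %% 2147483629L + 17L, {
      noise <- array(stats::rnorm(prod(shape)), shape)
      gaussian_smooth(noise, texture_smoothness / spacing)
    })
    tex <- tex / max(stats::sd(tex), 1e-12) * texture_amplitude
    an$anatomy <- pmin(pmax(an$anatomy + tex * (an$class_map >= 1L), 0), 1)
  }
  prostate <- as_mask(array(an$class_map == 4L, shape), spacing)
  ptv <- expand_mask(prostate, 3, name = "prostate-like")  # CTV + 3 mm
  roi <- expand_mask(ptv$mask, roi_margin_mm, name = "ptv-surrogate")
  out <- list(anatomy = an, roi = roi)
  .anatomy_cache[[key]] <- out
  out
}

#' Generate one synthetic treatment fraction
#'
#' Builds a paired multimodal case: a CT-like reference (moving) image of
#' the base anatomy, a smooth random displacement field scaled to
#' `deformation_amplitude` peak magnitude, and an MR-like daily (fixed)
#' image of the deformed anatomy with additive noise. The stored field
#' satisfies the registration convention `fixed(x) ~ moving(x + u(x))`, so
#' warping the moving image with the true field reproduces the fixed
#' anatomy. Structure masks are provided on both grids; the label is ATS
#' iff the mean in-ROI displacement magnitude exceeds the spec's
#' `label_threshold`. Identical `(spec, patient_id, fraction_index)` give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id identifier string.
#' @param fraction_index integer.
#' @param target_mean_roi_mm optional: rescale the field so the mean
#'   in-ROI displacement magnitude equals this value exactly (used by
#'   [generate_cohort()] to steer labels); overrides the peak-amplitude
#'   scaling.
#' @return list of class `synthetic_case` with elements `fixed`, `moving`
#'   ([volume3d()]), `true_field` ([displacement_field()]), `structures`
#'   (masks on the fixed grid), `structures_moving`, `roi_mask`,
#'   `dvh_atp`, `dvh_ats`, `label` ("ATP"/"ATS"), `patient_id`,
#'   `fraction_index`, `mean_roi_disp_mm`.
#' @export
generate_case <- function(spec, patient_id = "P001", fraction_index = 1L,
                          target_mean_roi_mm = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape; spacing <- spec$voxel_spacing
  ar <- anatomy_and_roi(shape, spacing, spec$roi_margin_mm,
                        spec$texture_amplitude, spec$texture_smoothness,
                        spec$seed)
  an <- ar$anatomy; roi <- ar$roi
  roi_idx <- which(roi$mask$data == 1)
  with_seed(case_seed(spec$seed, patient_id, fraction_index), {
    zero_field <- is.null(target_mean_roi_mm) &&
      spec$deformation_amplitude == 0
    if (zero_field) {
      u_mm <- array(0, c(shape, 3))
    } else {
      u_mm <- smooth_random_field_mm(shape, spacing,
                                     spec$deformation_smoothness)
      mag <- sqrt(u_mm[, , , 1]^2 + u_mm[, , , 2]^2 + u_mm[, , , 3]^2)
      if (is.null(target_mean_roi_mm)) {
        u_mm <- u_mm * (spec$deformation_amplitude / max(mag))
      } else {
        u_mm <- u_mm * (target_mean_roi_mm / mean(mag[roi_idx]))
      }
    }
    u_vox <- u_mm
    for (d in 1:3) u_vox[, , , d] <- u_mm[, , , d] / spacing[d]
    check_amplitude(u_vox, an$class_map, shape)
    true_field <- displacement_field(u_vox, spacing = spacing)
    moving <- volume3d(array(ct_transfer(an$anatomy), shape), spacing,
                       modality = "CT-like")
    fixed_anat <- if (zero_field) an$anatomy else
      warp_volume(an$anatomy, u_vox)
    noise <- if (spec$noise_sigma > 0)
      array(stats::rnorm(prod(shape), sd = spec$noise_sigma), shape)
    else 0
    fixed <- volume3d(array(mr_transfer(fixed_anat), shape) + noise,
                      spacing, modality = "MR-like")
    cls_fixed <- if (zero_field) an$class_map else
      warp_nearest(an$class_map, u_vox)
    structures <- list(
      "prostate-like" = as_mask(array(cls_fixed == 4L, shape), spacing),
      "bladder-like"  = as_mask(array(cls_fixed == 2L, shape), spacing),
      "rectum-like"   = as_mask(array(cls_fixed == 3L, shape), spacing))
    structures_moving <- list(
      "prostate-like" = as_mask(array(an$class_map == 4L, shape), spacing),
      "bladder-like"  = as_mask(array(an$class_map == 2L, shape), spacing),
      "rectum-like"   = as_mask(array(an$class_map == 3L, shape), spacing))
    mean_disp <- mean(field_magnitude_mm(true_field)[roi_idx])
    label <- if (mean_disp > spec$label_threshold) "ATS" else "ATP"
    dvh <- generate_dvh_tables(true_field, roi,
                               label_threshold = spec$label_threshold)
    structure(list(fixed = fixed, moving = moving, true_field = true_field,
                   structures = structures,
                   structures_moving = structures_moving,
                   roi_mask = roi, dvh_atp = dvh$atp, dvh_ats = dvh$ats,
                   label = label, patient_id = patient_id,
                   fraction_index = as.integer(fraction_index),
                   mean_roi_disp_mm = mean_disp, spec = spec),
              class = "synthetic_case")
  })
}

# error out, rather than silently clipping, when the deformation would pull
# delineated-structure voxels from outside the grid
check_amplitude <- function(u_vox, class_map, shape) {
  if (all(u_vox == 0)) return(invisible())
  idx <- which(class_map %in% c(2L, 3L, 4L))
  g <- arrayInd(idx, shape)
  n <- prod(shape)
  cs <- g + cbind(u_vox[idx], u_vox[idx + n], u_vox[idx + 2 * n])
  outside <- cs[, 1] < 1 | cs[, 1] > shape[1] |
             cs[, 2] < 1 | cs[, 2] > shape[2] |
             cs[, 3] < 1 | cs[, 3] > shape[3]
  if (any(outside))
    stop(sprintf(paste0("deformation amplitude too large: %d structure ",
                        "voxels would sample outside the grid (structures ",
                        "leave the field of view)"), sum(outside)))
  invisible()
}

# nearest-neighbour warp of a label map
warp_nearest <- function(lab, u_vox) {
  d <- dim(lab)
  g <- coord_grid(d)
  coords <- round(g + matrix(u_vox, nrow = nrow(g)))
  i1 <- pmin(pmax(coords[, 1], 1), d[1])
  i2 <- pmin(pmax(coords[, 2], 1), d[2])
  i3 <- pmin(pmax(coords[, 3], 1), d[3])
  array(lab[i1 + (i2 - 1) * d[1] + (i3 - 1) * d[1] * d[2]], d)
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %s fraction %d: label %s, mean in-ROI |u| %.2f mm\n",
              x$patient_id, x$fraction_index, x$label, x$mean_roi_disp_mm))
  invisible(x)
}

#' Generate a synthetic treatment cohort
#'
#' Draws `n_patients * fractions_per_patient` fractions. Each fraction's
#' intended label is Bernoulli(`ats_fraction_target`); its deformation is
#' then scaled so the mean in-ROI displacement falls in a regime well
#' below (ATP: U(0.15, 0.7) x threshold) or above (ATS: U(1.5, 3) x
#' threshold) the labelling threshold, so realized labels match the draw
#' and their proportion approaches the target. Patient identifiers are
#' distinct, supporting leakage-free patient-level train/test splits.
#'
#' @param spec a [phantom_spec()].
#' @param n_patients at least 2.
#' @param fractions_per_patient at least 1.
#' @param ats_fraction_target target ATS proportion in [0, 1].
#' @return list of [generate_case()] results.
#' @export
generate_cohort <- function(spec, n_patients, fractions_per_patient,
                            ats_fraction_target = 0.77) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_patients < 2) stop("'n_patients' must be at least 2")
  if (fractions_per_patient < 1) stop("'fractions_per_patient' must be at least 1")
  if (ats_fraction_target < 0 || ats_fraction_target > 1)
    stop("'ats_fraction_target' must be in [0, 1]")
  n <- n_patients * fractions_per_patient
  tau <- spec$label_threshold
  draws <- with_seed(spec$seed + 777L, {
    # stratified assignment: the realized ATS count is the rounded target,
    # placed uniformly at random across patients and fractions
    n_ats <- round(ats_fraction_target * n)
    is_ats <- sample(rep(c(TRUE, FALSE), c(n_ats, n - n_ats)))
    mu <- ifelse(is_ats, stats::runif(n, 1.5 * tau, 3 * tau),
                 stats::runif(n, 0.15 * tau, 0.7 * tau))
    list(mu = mu)
  })
  cases <- vector("list", n)
  k <- 1L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (fr in seq_len(fractions_per_patient)) {
      cases[[k]] <- generate_case(spec, pid, fr,
                                  target_mean_roi_mm = draws$mu[k])
      k <- k + 1L
    }
  }
  cases
}

# ---- DVH tables -----------------------------------------------------------

#' Synthetic DVH metric tables for a fraction
#'
#' Emits the pair of plan-evaluation tables the dosimetric labeler
#' consumes. The ATS table always satisfies every default criterion
#' strictly. The ATP table degrades monotonically with the mean in-ROI
#' displacement: at or below the labelling threshold every metric is
#' within its tolerance, above it the rectum D_max criterion (tolerance
#' 0 Gy) is violated, so the dosimetric label agrees with the geometric
#' one. A small jitter (drawn from the current RNG stream) keeps values
#' from being exactly reproducible across metrics without ever crossing a
#' criterion boundary.
#'
#' @param field the case's true [displacement_field()].
#' @param roi the ROI mask ([expand_mask()] output or binary volume).
#' @param label_threshold labelling threshold in mm.
#' @return list with `atp` and `ats` DVH tables
#'   (`data.frame(structure, metric, value, unit)`).
#' @export
generate_dvh_tables <- function(field, roi, label_threshold) {
  mag <- field_magnitude_mm(field)
  idx <- which(mask_data(roi) == 1)
  if (length(idx) == 0) stop("empty ROI")
  r <- mean(mag[idx]) / label_threshold
  ex <- max(r - 1, 0)  # excess over the threshold
  jit <- function() max(min(stats::rnorm(1, 0, 0.03), 0.1), -0.1)
  clamp_pct <- function(x) min(max(x, 0), 100)
  atp <- dvh_table(
    ctv4000_v40  = clamp_pct(97 - 2 * min(r, 1) - 4 * ex + jit()),
    ptv_v3625    = clamp_pct(97.5 - 2 * min(r, 1) - 3 * ex + jit()),
    ptv_v3440    = clamp_pct(99.5 - 1.2 * min(r, 1) - 3 * ex + jit()),
    rectum_dmax  = if (r <= 1) 37 + 2 * r + jit() else 40.3 + 3 * ex + jit(),
    rectum_v38   = max(0.05 + 0.03 * min(r, 1) + 0.4 * ex + jit() / 10, 0),
    rectum_v36   = max(0.5 + 0.6 * min(r, 1) + 1 * ex + jit(), 0),
    rectum_v29   = clamp_pct(14 + 4.5 * min(r, 1) + 6 * ex + jit()),
    bladder_v37  = max(5.5 + 3 * min(r, 1) + 4 * ex + jit(), 0),
    bladder_v181 = clamp_pct(33 + 10 * min(r, 1) + 12 * ex + jit()),
    femur_r      = clamp_pct(1.2 + 2 * min(r, 1) + 2.5 * ex + jit()),
    femur_l      = clamp_pct(1.2 + 2 * min(r, 1) + 2.5 * ex + jit()),
    urethra_d50  = 38.5 + 1.8 * min(r, 1) + 2.5 * ex + jit())
  ats <- dvh_table(
    ctv4000_v40 = 97.5 + jit(), ptv_v3625 = 97.8 + jit(),
    ptv_v3440 = 99.3 + jit() / 3, rectum_dmax = 36.5 + jit(),
    rectum_v38 = 0.03 + jit() / 10, rectum_v36 = 0.45 + jit() / 3,
    rectum_v29 = 13 + jit(), bladder_v37 = 6.5 + jit(),
    bladder_v181 = 35 + jit(), femur_r = 1.5 + jit(), femur_l = 1.5 + jit(),
    urethra_d50 = 38.8 + jit())
  list(atp = atp, ats = ats)
}

dvh_table <- function(ctv4000_v40, ptv_v3625, ptv_v3440, rectum_dmax,
                      rectum_v38, rectum_v36, rectum_v29, bladder_v37,
                      bladder_v181, femur_r, femur_l, urethra_d50) {
  data.frame(
    structure = c("CTV4000", "PTV", "PTV", "Rectum", "Rectum", "Rectum",
                  "Rectum", "Bladder", "Bladder", "Femur R", "Femur L",
                  "Urethra"),
    metric = c("V40Gy", "V36.25Gy", "V34.40Gy", "Dmax", "V38Gy", "V36Gy",
               "V29Gy", "V37Gy", "V18.1Gy", "V14.5Gy", "V14.5Gy", "D50%"),
    value = c(ctv4000_v40, ptv_v3625, ptv_v3440, rectum_dmax, rectum_v38,
              rectum_v36, rectum_v29, bladder_v37, bladder_v181, femur_r,
              femur_l, urethra_d50),
    unit = c("%", "%", "%", "Gy", "cc", "cc", "%", "cc", "%", "%", "%",
             "Gy"),
    stringsAsFactors = FALSE)
}

# ---- on-disk cohort layout ------------------------------------------------

#' Write a case (and a cohort manifest) to disk
#'
#' One fraction becomes NIfTI volumes (fixed, moving, per-structure masks,
#' ROI, 4D true field in voxel units), the two DVH tables as CSV, and a
#' JSON sidecar with the label, identifiers and generator settings.
#' `write_cohort()` writes every case plus a manifest CSV
#' (`patient_id, fraction_index, label, paths`).
#'
#' @param case a `synthetic_case`.
#' @param dir output directory (created if missing).
#' @return the case/manifest directory, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "synthetic_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, sprintf("%s_fx%02d", case$patient_id,
                                 case$fraction_index))
  write_volume(case$fixed, paste0(stem, "_fixed.nii.gz"))
  write_volume(case$moving, paste0(stem, "_moving.nii.gz"))
  write_volume(case$true_field, paste0(stem, "_field.nii.gz"))
  write_volume(case$roi_mask$mask, paste0(stem, "_roi.nii.gz"))
  for (nm in names(case$structures))
    write_volume(case$structures[[nm]],
                 paste0(stem, "_", gsub("[^A-Za-z0-9]", "", nm), ".nii.gz"))
  utils::write.csv(case$dvh_atp, paste0(stem, "_dvh_atp.csv"),
                   row.names = FALSE)
  utils::write.csv(case$dvh_ats, paste0(stem, "_dvh_ats.csv"),
                   row.names = FALSE)
  side <- list(patient_id = case$patient_id,
               fraction_index = case$fraction_index, label = case$label,
               mean_roi_disp_mm = case$mean_roi_disp_mm,
               spec = unclass(case$spec))
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_case
#' @param cases list of `synthetic_case`.
#' @export
write_cohort <- function(cases, dir) {
  for (cs in cases) write_case(cs, dir)
  manifest <- data.frame(
    patient_id = vapply(cases, `[[`, "", "patient_id"),
    fraction_index = vapply(cases, `[[`, 1L, "fraction_index"),
    label = vapply(cases, `[[`, "", "label"),
    fixed = vapply(cases, function(cs)
      sprintf("%s_fx%02d_fixed.nii.gz", cs$patient_id, cs$fraction_index), ""),
    moving = vapply(cases, function(cs)
      sprintf("%s_fx%02d_moving.nii.gz", cs$patient_id, cs$fraction_index), ""),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
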