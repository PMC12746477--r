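test_that("phantom-spec invariants are enforced", {
  expect_error(phantom_spec(grid_shape = c(4, 16, 16)), "at least 8")
  expect_error(phantom_spec(deformation_smoothness = 2,
                            voxel_spacing = c(3, 3, 6)), "resolvable")
  expect_error(phantom_spec(label_threshold = 0), "positive")
  expect_error(phantom_spec(deformation_amplitude = -1), ">= 0")
})

test_that("case generation is bit-for-bit deterministic", {
  a <- generate_case(tiny_spec(), "P007", 3)
  b <- generate_case(tiny_spec(), "P007", 3)
  expect_identical(a$fixed$data, b$fixed$data)
  expect_identical(a$moving$data, b$moving$data)
  expect_identical(a$true_field$u, b$true_field$u)
  expect_identical(a$label, b$label)
  expect_identical(a$dvh_atp, b$dvh_atp)
  # different fraction gives different randomness
  c2 <- generate_case(tiny_spec(), "P007", 4)
  expect_false(identical(a$true_field$u, c2$true_field$u))
})

test_that("zero deformation gives an identity field, ATP label and clean MR render", {
  spec0 <- tiny_spec(noise_sigma = 0, deformation_amplitude = 0)
  cs <- generate_case(spec0, "P001", 1)
  expect_true(all(cs$true_field$u == 0))
  expect_identical(cs$label, "ATP")
  # fixed is exactly the MR rendering of the undeformed anatomy
  an <- mrgadapt:::anatomy_and_roi(spec0$grid_shape, spec0$voxel_spacing,
                                   spec0$roi_margin_mm,
                                   spec0$texture_amplitude,
                                   spec0$texture_smoothness,
                                   spec0$seed)$anatomy$anatomy
  expect_equal(cs$fixed$data,
               array(mrgadapt:::mr_transfer(an), spec0$grid_shape))
  # identical structure masks on both grids
  expect_identical(cs$structures[["prostate-like"]]$data,
                   cs$structures_moving[["prostate-like"]]$data)
})

test_that("the stored label always matches the geometric rule on the stored field", {
  spec <- phantom_spec(deformation_amplitude = 8, label_threshold = 2,
                       deformation_smoothness = 15)
  cs <- generate_case(spec, "P001", 1)
  mag <- field_magnitude_mm(cs$true_field)
  m <- mean(mag[cs$roi_mask$mask$data == 1])
  expect_gt(m, 2)                      # recomputed from the returned field
  expect_identical(cs$label, "ATS")

  cohort <- generate_cohort(tiny_spec(seed = 21L), 3, 3,
                            ats_fraction_target = 0.5)
  for (cs in cohort) {
    mag <- field_magnitude_mm(cs$true_field)
    m <- mean(mag[cs$roi_mask$mask$data == 1])
    expect_identical(cs$label,
                     if (m > cs$spec$label_threshold) "ATS" else "ATP")
    expect_equal(m, cs$mean_roi_disp_mm)
  }
})

test_that("structure masks are non-empty, disjoint and share the grid", {
  cs <- tiny_case()
  shp <- dim(cs$fixed$data)
  total <- array(0, shp)
  for (s in cs$structures) {
    expect_equal(dim(s$data), shp)
    expect_gt(sum(s$data), 0)
    total <- total + s$data
  }
  expect_true(all(total <= 1))                 # mutually disjoint
  expect_equal(dim(cs$true_field$u)[1:3], shp)
  # ROI contains the prostate surrogate
  expect_true(all(cs$roi_mask$mask$data >=
                  cs$structures_moving[["prostate-like"]]$data))
})

test_that("cohort generation respects counts, splitting ids and the ATS target", {
  spec <- tiny_spec(seed = 22L)
  cohort <- generate_cohort(spec, 4, 5, ats_fraction_target = 0.5)
  expect_length(cohort, 20)
  ids <- vapply(cohort, `[[`, "", "patient_id")
  expect_length(unique(ids), 4)
  expect_true(all(table(ids) == 5))

  all_ats <- generate_cohort(spec, 2, 2, ats_fraction_target = 1)
  expect_true(all(vapply(all_ats, `[[`, "", "label") == "ATS"))

  expect_error(generate_cohort(spec, 1, 5), "at least 2")
  expect_error(generate_cohort(spec, 2, 5, ats_fraction_target = 1.2),
               "\\[0, 1\\]")

  # 36 patients x 5 fractions gives the clinical cohort size
  big <- generate_cohort(spec, 36, 5, ats_fraction_target = 0.77)
  expect_length(big, 180)
  expect_length(unique(vapply(big, `[[`, "", "patient_id")), 36)
  prop <- mean(vapply(big, `[[`, "", "label") == "ATS")
  expect_gt(prop, 0.6); expect_lt(prop, 0.9)
})

test_that("oversized deformations error instead of silently clipping", {
  spec <- phantom_spec(deformation_amplitude = 150,
                       deformation_smoothness = 60)
  expect_error(generate_case(spec, "P001", 1), "outside the grid")
})

test_that("the modality gap defeats intensity similarity but not MI", {
  spec0 <- tiny_spec(deformation_amplitude = 0)
  cs <- generate_case(spec0, "P001", 1)
  r <- cor(as.numeric(cs$fixed$data), as.numeric(cs$moving$data))
  expect_lt(r, 0.999)   # CT and MR renderings are not affinely related
  mi_pair <- mutual_information(cs$fixed, cs$moving, bins = 16)$mi
  perm <- cs$moving$data
  set.seed(23); perm[] <- sample(perm)
  mi_perm <- mutual_information(cs$fixed, perm, bins = 16)$mi
  expect_gt(mi_pair, 10 * mi_perm)
})

test_that("the random field is smooth at the requested correlation length", {
  spec <- phantom_spec(deformation_amplitude = 8, deformation_smoothness = 30)
  cs <- generate_case(spec, "P001", 1)
  u <- cs$true_field$u
  peak <- max(field_magnitude_mm(cs$true_field))
  worst <- 0
  for (cmp in 1:3) for (ax in 1:3) {
    dif <- mrgadapt:::forward_diff(u[, , , cmp] * spec$voxel_spacing[cmp], ax)
    worst <- max(worst, max(abs(dif)) / spec$voxel_spacing[ax])
  }
  # max per-mm gradient bounded by amplitude / correlation length x constant
  expect_lt(worst, 5 * peak / spec$deformation_smoothness)
})

test_that("DVH tables reproduce the dosimetric label and ATS always passes", {
  spec <- tiny_spec(seed = 24L)
  roi <- mrgadapt:::anatomy_and_roi(spec$grid_shape, spec$voxel_spacing,
                                    spec$roi_margin_mm)$roi
  for (target in c(0.5, 2.9, 4.5, 9)) {
    cs <- generate_case(spec, "P001", 1, target_mean_roi_mm = target)
    ev_atp <- evaluate_plan(cs$dvh_atp)
    ev_ats <- evaluate_plan(cs$dvh_ats)
    expect_true(ev_ats$acceptable)
    expect_identical(ev_atp$acceptable, cs$label == "ATP")
    expect_identical(determine_strategy(cs$dvh_atp, cs$dvh_ats)$label,
                     cs$label)
  }
  # zero deformation: every ATP metric within tolerance
  cs0 <- generate_case(tiny_spec(seed = 24L, deformation_amplitude = 0),
                       "P001", 1)
  expect_true(evaluate_plan(cs0$dvh_atp)$acceptable)
})

test_that("cases round-trip to NIfTI + sidecar + manifest on disk", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(tiny_spec(seed = 25L), 2, 2)
  write_cohort(cohort, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  stem <- file.path(dir, "P001_fx01")
  fx <- read_volume(paste0(stem, "_fixed.nii.gz"), modality = "MR-like")
  expect_equal(fx$data, cohort[[1]]$fixed$data, tolerance = 1e-12)
  fld <- read_volume(paste0(stem, "_field.nii.gz"))
  expect_equal(fld$u, cohort[[1]]$true_field$u, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(stem, ".json"))
  expect_identical(side$label, cohort[[1]]$label)
  expect_true(file.exists(paste0(stem, "_dvh_atp.csv")))
})
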