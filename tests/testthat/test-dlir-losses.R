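test_that("the spatial transformer warps exactly at grid points and shifts", {
  set.seed(4)
  a <- array(rnorm(10 * 8 * 6), c(10, 8, 6))
  u0 <- array(0, c(10, 8, 6, 3))
  expect_identical(warp_volume(a, u0), a)  # zero field is the exact identity

  u1 <- u0; u1[, , , 1] <- 1               # integer shift, border clamped
  w <- warp_volume(a, u1)
  expect_equal(w[1:9, , ], a[2:10, , ])
  expect_equal(w[10, , ], a[10, , ])

  ramp <- array(rep(1:10, 8 * 6), c(10, 8, 6))  # m(x) = x, half-voxel shift
  uh <- u0; uh[, , , 1] <- 0.5
  wh <- warp_volume(ramp, uh)
  expect_equal(wh[1:9, , ], ramp[1:9, , ] + 0.5, tolerance = 1e-12)

  expect_error(warp_volume(a, array(0, c(4, 4, 4, 3))), "shape")
})

test_that("hard-binned mutual information matches closed forms", {
  f <- array(rep(c(0, 1), each = 500), c(10, 10, 10))
  r <- mutual_information(f, f, bins = 8, method = "hard")
  expect_equal(r$mi, log(2), tolerance = 1e-12)
  expect_equal(sum(r$dist$joint), 1, tolerance = 1e-9)
  expect_equal(rowSums(r$dist$joint), r$dist$marginal_f)
  expect_equal(colSums(r$dist$joint), r$dist$marginal_w)

  w_const <- array(3.7, c(10, 10, 10))
  expect_equal(mutual_information(f, w_const, bins = 8)$mi, 0)

  # permutation independence: large volume, 16 bins, MI near zero
  set.seed(5)
  big <- array(runif(50^3), c(50, 50, 50))
  perm <- big; perm[] <- sample(big)
  expect_lt(mutual_information(big, perm, bins = 16)$mi, 0.05)

  # masked variant restricts the voxel population
  msk <- array(0, c(10, 10, 10)); msk[1:5, , ] <- 1
  rm_ <- mutual_information(f, f, bins = 8, mask = msk)
  expect_equal(rm_$mi, log(2), tolerance = 1e-12)
  expect_error(mutual_information(f, f, mask = array(0, c(10, 10, 10))),
               "empty mask")
})

test_that("MI obeys its bounds and the soft estimator approaches the hard one", {
  set.seed(6)
  for (i in 1:5) {
    f <- array(runif(12^3), c(12, 12, 12))
    w <- array(runif(12^3), c(12, 12, 12))
    rh <- mutual_information(f, w, bins = 8, method = "hard")
    hf <- -sum(ifelse(rh$dist$marginal_f > 0,
                      rh$dist$marginal_f * log(rh$dist$marginal_f), 0))
    hw <- -sum(ifelse(rh$dist$marginal_w > 0,
                      rh$dist$marginal_w * log(rh$dist$marginal_w), 0))
    expect_gte(rh$mi, 0)
    expect_lte(rh$mi, min(hf, hw) + 1e-9)
    rself <- mutual_information(f, f, bins = 8, method = "hard")
    hself <- -sum(ifelse(rself$dist$marginal_f > 0,
                         rself$dist$marginal_f * log(rself$dist$marginal_f),
                         0))
    expect_equal(rself$mi, hself, tolerance = 1e-12)
  }

  # soft-binned estimate approaches the hard-binned one as the Parzen
  # kernel narrows (monotone over three widths on a fixed pair)
  set.seed(7)
  f <- array(runif(16^3), c(16, 16, 16))
  w <- 0.6 * f + 0.4 * array(runif(16^3), c(16, 16, 16))
  hard <- mutual_information(f, w, bins = 16, method = "hard")$mi
  gaps <- vapply(c(2, 1, 0.4) / 16, function(s)
    abs(mutual_information(f, w, bins = 16, method = "soft",
                           kernel_width = s)$mi - hard), 0)
  expect_true(all(diff(gaps) < 0))
})

test_that("smoothness and L2 penalties match nested-loop oracles", {
  set.seed(8)
  u <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  brute_sm <- 0
  for (cmp in 1:3) for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    if (i < 8) brute_sm <- brute_sm + (u[i + 1, j, k, cmp] - u[i, j, k, cmp])^2
    if (j < 8) brute_sm <- brute_sm + (u[i, j + 1, k, cmp] - u[i, j, k, cmp])^2
    if (k < 8) brute_sm <- brute_sm + (u[i, j, k + 1, cmp] - u[i, j, k, cmp])^2
  }
  expect_equal(smoothness_loss(u), brute_sm, tolerance = 1e-6)
  expect_equal(l2_penalty(u), sum(u^2), tolerance = 1e-6)

  expect_equal(smoothness_loss(array(2.5, c(5, 5, 5, 3))), 0)
  expect_equal(l2_penalty(array(0, c(5, 5, 5, 3))), 0)

  # u = (a * x, 0, 0): gradient a at every contributing difference term
  a <- 0.7
  ux <- array(0, c(6, 6, 6, 3))
  ux[, , , 1] <- rep(a * (1:6), 36)
  expect_equal(smoothness_loss(ux), a^2 * 5 * 36, tolerance = 1e-10)

  # unit x-displacement on N voxels has L2 penalty N
  u1 <- array(0, c(6, 6, 6, 3)); u1[, , , 1] <- 1
  expect_equal(l2_penalty(u1), 216)

  # absolute homogeneity of degree 2
  for (cc in c(2.5, -1.3)) {
    expect_equal(smoothness_loss(cc * u), cc^2 * smoothness_loss(u),
                 tolerance = 1e-9)
    expect_equal(l2_penalty(cc * u), cc^2 * l2_penalty(u), tolerance = 1e-9)
  }
})

test_that("the composite loss assembles its components with the default weights", {
  set.seed(9)
  shp <- c(8, 8, 8)
  f <- array(runif(512), shp)
  m <- array(runif(512), shp)
  u <- array(rnorm(512 * 3, sd = 0.3), c(shp, 3))
  cfg <- dlir_config(mi_bins = 8)
  expect_equal(cfg$lambda1, 1e-2)
  expect_equal(cfg$lambda2, 1e-5)

  r <- dlir_loss(f, m, u, cfg)
  w <- warp_volume(m, u)
  mi <- mutual_information(f, w, bins = 8, method = "soft")$mi
  expect_equal(r$value,
               -mi + 1e-2 * smoothness_loss(u) + 1e-5 * l2_penalty(u),
               tolerance = 1e-9)
  expect_equal(r$components$sim, -mi, tolerance = 1e-12)

  cfg0 <- dlir_config(mi_bins = 8, lambda1 = 0, lambda2 = 0)
  expect_equal(dlir_loss(f, m, u, cfg0)$value, -mi, tolerance = 1e-9)

  # zero field with m = f reduces to -MI(f, f)
  z <- array(0, c(shp, 3))
  mi_ff <- mutual_information(f, f, bins = 8, method = "soft")$mi
  expect_equal(dlir_loss(f, f, z, cfg0)$value, -mi_ff, tolerance = 1e-12)
})

test_that("analytic field gradients agree with numerical differentiation", {
  set.seed(10)
  shp <- c(8, 8, 8)
  f <- array(runif(512), shp)
  m <- array(runif(512), shp)
  fn <- as.numeric(f); mn <- m  # already in [0, 1]
  cfg <- dlir_config(mi_bins = 8)
  u <- array(rnorm(512 * 3, sd = 0.3), c(shp, 3))
  lg <- mrgadapt:::dlir_loss_grad(fn, mn, u, cfg)
  h <- 1e-5
  for (t in 1:6) {
    i <- sample(2:7, 1); j <- sample(2:7, 1); k <- sample(2:7, 1)
    d <- sample(1:3, 1)
    up <- u; up[i, j, k, d] <- up[i, j, k, d] + h
    um <- u; um[i, j, k, d] <- um[i, j, k, d] - h
    num <- (mrgadapt:::dlir_loss_grad(fn, mn, up, cfg)$value -
            mrgadapt:::dlir_loss_grad(fn, mn, um, cfg)$value) / (2 * h)
    ana <- lg$dfield[i + (j - 1) * 8 + (k - 1) * 64, d]
    expect_lt(abs(num - ana) / max(abs(num), 1e-8), 1e-3)
  }
})
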