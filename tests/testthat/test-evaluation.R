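test_that("Dice handles identity, disjoint, partial overlap and emptiness", {
  a <- array(0, c(6, 6, 6)); a[2:3, 2:3, 2:3] <- 1     # 8 voxels
  b <- array(0, c(6, 6, 6)); b[2:3, 2:3, 3:4] <- 1     # 8 voxels, 4 shared
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, 1 - a), 0)
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  empty <- array(0, c(6, 6, 6))
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_equal(dice_coefficient(a, empty), 0)
  expect_error(dice_coefficient(a, array(0, c(5, 5, 5))), "shape")
})

test_that("Hausdorff distance respects physical spacing and symmetry", {
  a <- array(0, c(12, 12, 12)); a[3, 3, 3] <- 1
  b <- array(0, c(12, 12, 12)); b[8, 3, 3] <- 1
  expect_equal(hausdorff_distance(a, a, c(1, 1, 1)), 0)
  expect_equal(hausdorff_distance(a, b, c(1, 1, 1)), 5)
  expect_equal(hausdorff_distance(a, b, c(1, 1, 1)),
               hausdorff_distance(b, a, c(1, 1, 1)))

  c1 <- array(0, c(12, 12, 12)); c1[5, 5, 5] <- 1
  c2 <- array(0, c(12, 12, 12)); c2[5, 5, 6] <- 1    # one slice apart
  expect_equal(hausdorff_distance(c1, c2, c(1, 1, 3)), 3)

  # joint translation invariance
  a2 <- array(0, c(12, 12, 12)); a2[5, 4, 6] <- 1
  b2 <- array(0, c(12, 12, 12)); b2[10, 4, 6] <- 1
  expect_equal(hausdorff_distance(a2, b2, c(1, 1, 1)),
               hausdorff_distance(a, b, c(1, 1, 1)))
  expect_error(hausdorff_distance(a, array(0, c(12, 12, 12))), "empty")
})

test_that("trapezoidal AUC equals the pairwise-concordance oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0), c(0.4, 0.6))$auc, 0)
  expect_error(roc_auc(c(1, 1), c(0.4, 0.6)), "both classes")

  set.seed(51)
  for (i in 1:5) {
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    p <- round(runif(20), 2)          # rounding forces ties
    r <- roc_auc(y, p)
    expect_equal(r$auc, auc_oracle(y, p), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(y, plogis(5 * p - 2))$auc, r$auc,
                 tolerance = 1e-12)
    # the ROC curve starts at (0,0) and ends at (1,1)
    expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
    expect_equal(r$curve$fpr[nrow(r$curve)], 1)
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  }

  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(52)
    y <- rbinom(30, 1, 0.6); y[1:2] <- c(0, 1)
    p <- runif(30)
    expect_equal(roc_auc(y, p)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("confusion metrics follow their definitions, with degenerate warnings", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.2, 0.7, 0.1, 0.1, 0.2, 0.3, 0.1, 0.2)
  r <- confusion_at_threshold(y, p, 0.5)
  expect_equal(r$counts, list(TP = 2L, FP = 1L, TN = 6L, FN = 1L))
  expect_equal(r$metrics$f1, 4 / 6, tolerance = 1e-12)
  expect_equal(r$metrics$accuracy, 0.8)
  expect_equal(r$metrics$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(r$metrics$specificity, 6 / 7, tolerance = 1e-12)

  all_right <- confusion_at_threshold(c(1, 0), c(0.9, 0.1), 0.5)
  expect_equal(all_right$metrics$accuracy, 1)
  expect_equal(all_right$metrics$f1, 1)

  expect_warning(r0 <- confusion_at_threshold(c(0, 0), c(0.6, 0.2), 0.5),
                 "sensitivity undefined")
  expect_true(is.nan(r0$metrics$sensitivity))

  # accuracy is the prevalence-weighted mix of sensitivity and specificity
  set.seed(53)
  y2 <- rbinom(50, 1, 0.4); y2[1:2] <- c(0, 1)
  p2 <- runif(50)
  m <- confusion_at_threshold(y2, p2, 0.5)$metrics
  prev <- mean(y2)
  expect_equal(m$accuracy, prev * m$sensitivity + (1 - prev) * m$specificity,
               tolerance = 1e-12)
})

test_that("threshold selection lands between separated classes and is self-consistent", {
  y <- c(0, 0, 0, 1, 1, 1)
  p <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  for (crit in c("youden", "balance")) {
    th <- select_threshold(y, p, crit)
    expect_gt(th, 0.3); expect_lt(th, 0.7)
    m <- confusion_at_threshold(y, p, th)$metrics
    expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)
  }

  # symmetric overlapping scores: balance threshold near the midpoint
  y2 <- rep(c(0, 1), each = 5)
  p2 <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.4, 0.6, 0.7, 0.8, 0.9)
  thb <- select_threshold(y2, p2, "balance")
  mb <- confusion_at_threshold(y2, p2, thb)$metrics
  expect_equal(mb$sensitivity, mb$specificity, tolerance = 1e-12)
  expect_error(select_threshold(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("cohort aggregation reproduces the clinical fraction table", {
  rows <- rbind(
    data.frame(n_atp = rep(0, 17), n_ats = rep(5, 17)),
    data.frame(n_atp = rep(1, 9), n_ats = rep(4, 9)),
    data.frame(n_atp = rep(2, 4), n_ats = rep(3, 4)),
    data.frame(n_atp = rep(3, 2), n_ats = rep(2, 2)),
    data.frame(n_atp = rep(4, 1), n_ats = rep(1, 1)),
    data.frame(n_atp = rep(5, 3), n_ats = rep(0, 3)))
  s <- aggregate_cohort(rows)
  expect_equal(s$total, 180)
  expect_equal(s$total_atp, 42)
  expect_equal(s$total_ats, 138)
  expect_equal(s$pct_atp, 23)
  expect_equal(s$pct_ats, 77)
  expect_equal(s$prop_atp + s$prop_ats, 1)

  one <- aggregate_cohort(data.frame(n_atp = 0, n_ats = 5))
  expect_equal(one$pct_atp, 0); expect_equal(one$pct_ats, 100)
  expect_error(aggregate_cohort(data.frame(n_atp = 0, n_ats = 0)), "zero")
  expect_error(aggregate_cohort(data.frame(n_atp = numeric(0),
                                           n_ats = numeric(0))), "empty")
})
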