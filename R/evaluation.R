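#' Dice coefficient of two binary masks
#'
#' `2|a & b| / (|a| + |b|)`. Two empty masks are defined to have Dice 1
#' (identity of emptiness); one empty mask gives 0.
#'
#' @param a,b binary masks ([volume3d()] or arrays) of equal shape.
#' @return scalar in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  av <- mask_data(a) != 0; bv <- mask_data(b) != 0
  if (!all(dim(av) == dim(bv))) stop("mask shapes differ")
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(1)
  2 * sum(av & bv) / (sa + sb)
}

# surface voxels: mask voxels with at least one 6-neighbour outside the
# mask (grid border counts as outside)
surface_voxels <- function(m) {
  d <- dim(m)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    lo <- hi <- lapply(d, seq_len)
    lo[[ax]] <- c(1L, seq_len(d[ax] - 1L))   # neighbour at -1 (border clamps to self-out)
    hi[[ax]] <- c(2:d[ax], d[ax])
    nb_lo <- do.call(`[`, c(list(m), lo, drop = FALSE))
    nb_hi <- do.call(`[`, c(list(m), hi, drop = FALSE))
    interior <- interior & (nb_lo != 0) & (nb_hi != 0)
    # border slices have no outward neighbour: mark non-interior
    brd <- lapply(d, seq_len)
    brd[[ax]] <- c(1L, d[ax])
    interior <- do.call(`[<-`, c(list(interior), brd, list(FALSE)))
  }
  which(m != 0 & !interior)
}

#' Symmetric Hausdorff distance between two masks (mm)
#'
#' Maximum (100th percentile) symmetric Hausdorff distance between the
#' surface voxel sets of two non-empty binary masks, in physical units
#' (anisotropic spacing respected). `percentile` < 100 gives the robust
#' variant (e.g. HD95).
#'
#' @param a,b non-empty binary masks of equal shape.
#' @param spacing voxel spacing in mm (taken from `a` if it is a
#'   [volume3d()]).
#' @param percentile percentile of the directed surface distances
#'   (default 100 = classical Hausdorff).
#' @return distance in mm.
#' @export
hausdorff_distance <- function(a, b, spacing = NULL, percentile = 100) {
  if (is.null(spacing))
    spacing <- if (is_volume3d(a)) a$spacing else c(1, 1, 1)
  av <- mask_data(a); bv <- mask_data(b)
  if (!all(dim(av) == dim(bv))) stop("mask shapes differ")
  if (sum(av) == 0 || sum(bv) == 0) stop("empty mask")
  d <- dim(av)
  pa <- sweep(arrayInd(surface_voxels(av), d), 2, spacing, "*")
  pb <- sweep(arrayInd(surface_voxels(bv), d), 2, spacing, "*")
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  dir_ab <- sqrt(apply(d2, 1, min))
  dir_ba <- sqrt(apply(d2, 2, min))
  q <- function(x) if (percentile >= 100) max(x) else
    stats::quantile(x, percentile / 100, names = FALSE)
  max(q(dir_ab), q(dir_ba))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    y <- as.integer(as.character(labels) == "ATS")
  } else y <- as.integer(labels != 0)
  y
}

#' ROC curve and AUC
#'
#' Trapezoidal AUC over all threshold-induced (FPR, TPR) points, with the
#' ATS class (label 1) as positive. Ties in the scores contribute half a
#' concordance, so the value equals the Mann-Whitney pairwise statistic.
#'
#' @param labels case labels (`"ATP"`/`"ATS"`, or 0/1 with 1 = positive).
#' @param probs predicted probabilities/scores.
#' @return list with `auc` and `curve`
#'   (`data.frame(threshold, fpr, tpr)`).
#' @export
roc_auc <- function(labels, probs) {
  y <- as_binary_labels(labels)
  if (length(y) != length(probs)) stop("lengths differ")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs both classes present")
  ord <- order(probs, decreasing = TRUE)
  ys <- y[ord]; ps <- probs[ord]
  grp <- cumsum(!duplicated(ps))
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, ps[last]), fpr = fpr,
                          tpr = tpr))
}

#' Confusion counts and summary metrics at a decision threshold
#'
#' Applies the strict decision rule (predicted ATS iff probability is
#' strictly greater than the threshold) and reports the confusion counts
#' with accuracy, sensitivity, specificity and F1 (`2TP/(2TP+FP+FN)`),
#' ATS being the positive class. A metric with an empty denominator is
#' returned as `NaN` with a warning.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold.
#' @return list with `counts` (`TP`, `FP`, `TN`, `FN`) and `metrics`
#'   (`accuracy`, `sensitivity`, `specificity`, `f1`).
#' @export
confusion_at_threshold <- function(labels, probs, threshold = 0.64) {
  y <- as_binary_labels(labels)
  if (length(y) == 0) stop("empty input")
  pred <- as.integer(probs > threshold)
  TP <- sum(pred == 1 & y == 1); FP <- sum(pred == 1 & y == 0)
  TN <- sum(pred == 0 & y == 0); FN <- sum(pred == 0 & y == 1)
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (empty denominator)"); NaN }
    else num / den
  }
  metrics <- list(
    accuracy = (TP + TN) / length(y),
    sensitivity = safe_div(TP, TP + FN, "sensitivity"),
    specificity = safe_div(TN, TN + FP, "specificity"),
    f1 = safe_div(2 * TP, 2 * TP + FP + FN, "F1"))
  list(counts = list(TP = TP, FP = FP, TN = TN, FN = FN),
       metrics = metrics)
}

#' Select a decision threshold from scores
#'
#' Searches the midpoints of the sorted unique scores. `"youden"`
#' maximises TPR - FPR; `"balance"` minimises |sensitivity -
#' specificity| (the operating-point style used to pick a threshold that
#' balances accuracy, specificity and sensitivity). Ties break toward the
#' larger threshold.
#'
#' @inheritParams roc_auc
#' @param criterion `"youden"` or `"balance"`.
#' @return the selected threshold.
#' @export
select_threshold <- function(labels, probs, criterion = c("youden", "balance")) {
  criterion <- match.arg(criterion)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("threshold selection needs both classes")
  u <- sort(unique(probs))
  if (length(u) < 2) return(u[1])
  cand <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
  score <- vapply(cand, function(th) {
    cm <- suppressWarnings(confusion_at_threshold(y, probs, th))
    sen <- cm$metrics$sensitivity; spc <- cm$metrics$specificity
    if (criterion == "youden") sen + spc - 1 else -abs(sen - spc)
  }, 0)
  best <- max(score)
  max(cand[score >= best - 1e-12])
}

#' Aggregate per-patient strategy counts
#'
#' Sums per-patient (ATP, ATS) fraction counts into cohort totals,
#' proportions and integer percentages (rounded half-up).
#'
#' @param per_patient_counts `data.frame` with one row per patient and
#'   columns `n_atp`, `n_ats`.
#' @return object of class `cohort_summary`: list with `per_patient`,
#'   `total_atp`, `total_ats`, `total`, `prop_atp`, `prop_ats`,
#'   `pct_atp`, `pct_ats`.
#' @export
aggregate_cohort <- function(per_patient_counts) {
  pc <- per_patient_counts
  if (is.null(pc) || nrow(pc) == 0) stop("empty input")
  if (!all(c("n_atp", "n_ats") %in% names(pc)))
    stop("need columns n_atp, n_ats")
  if (any(pc$n_atp < 0 | pc$n_ats < 0)) stop("counts must be non-negative")
  ta <- sum(pc$n_atp); ts <- sum(pc$n_ats); tot <- ta + ts
  if (tot == 0) stop("all counts are zero")
  half_up <- function(p) floor(p * 100 + 0.5)
  structure(list(per_patient = pc, total_atp = ta, total_ats = ts,
                 total = tot, prop_atp = ta / tot, prop_ats = ts / tot,
                 pct_atp = half_up(ta / tot), pct_ats = half_up(ts / tot)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d fractions of %d patients: ATP %d (%d%%) / ATS %d (%d%%)\n",
              x$total, nrow(x$per_patient), x$total_atp, x$pct_atp,
              x$total_ats, x$pct_ats))
  invisible(x)
}
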