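#' Read and write volumes as NIfTI
#'
#' Volumes travel as `.nii` / `.nii.gz`. Spacing is stored in `pixdim` and
#' the world origin in the qform translation. A 4D payload with three
#' components in the last axis is interpreted as a displacement field
#' (voxel units of the fixed grid); any other non-3D payload is an error,
#' as are NaN voxels.
#'
#' @param path file path.
#' @param modality modality tag to attach on read (NIfTI does not carry
#'   one); ignored for 4D fields.
#' @return `read_volume()` returns a [volume3d()] or, for 4D files, a
#'   [displacement_field()]. `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path, modality = "CT-like") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (any(is.na(img))) stop("volume contains NaN voxels: ", path)
  pd <- RNifti::pixdim(img)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  if (length(d) == 4L) {
    if (d[4] != 3L) stop("4D volume must have 3 components in the last axis: ", path)
    return(displacement_field(array(as.numeric(img), d), spacing = pd[1:3]))
  }
  if (length(d) != 3L) stop("expected a 3D (or 4D field) NIfTI payload: ", path)
  volume3d(array(as.numeric(img), d), spacing = pd[1:3], origin = origin,
           modality = modality)
}

#' @rdname read_volume
#' @param volume a [volume3d()] or [displacement_field()].
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "displacement_field")) {
    img <- RNifti::asNifti(volume$u)
    RNifti::pixdim(img) <- c(volume$spacing, 1)
  } else if (is_volume3d(volume)) {
    img <- RNifti::asNifti(volume$data)
    RNifti::pixdim(img) <- volume$spacing
    q <- diag(c(volume$spacing, 1))
    q[1:3, 4] <- volume$origin
    RNifti::qform(img) <- structure(q, code = 2L)
  } else stop("'volume' must be a volume3d or displacement_field")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a target grid
#'
#' Resamples about the grid centre so the physical extent is preserved:
#' the centre of the output grid coincides with the centre of the input
#' grid in world space. Images use trilinear interpolation; masks must use
#' nearest-neighbour so they stay binary.
#'
#' @param volume a [volume3d()].
#' @param target_shape integer length-3 (> 0).
#' @param target_spacing numeric length-3, mm (> 0).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A [volume3d()] of shape `target_shape`.
#' @export
resample_to_grid <- function(volume, target_shape, target_spacing,
                             interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_volume3d(volume))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("'target_shape' must be 3 positive integers")
  if (any(target_spacing <= 0)) stop("'target_spacing' must be positive")
  if (volume$modality == "mask" && interpolation != "nearest")
    stop("masks must be resampled with nearest-neighbour interpolation")
  din <- dim(volume$data)
  cin <- (din + 1) / 2
  cout <- (target_shape + 1) / 2
  g <- coord_grid(target_shape)
  coords <- cbind(
    cin[1] + (g[, 1] - cout[1]) * target_spacing[1] / volume$spacing[1],
    cin[2] + (g[, 2] - cout[2]) * target_spacing[2] / volume$spacing[2],
    cin[3] + (g[, 3] - cout[3]) * target_spacing[3] / volume$spacing[3])
  vals <- if (interpolation == "trilinear") {
    sample_trilinear(volume$data, coords)
  } else {
    idx <- cbind(pmin(pmax(round(coords[, 1]), 1), din[1]),
                 pmin(pmax(round(coords[, 2]), 1), din[2]),
                 pmin(pmax(round(coords[, 3]), 1), din[3]))
    volume$data[idx[, 1] + (idx[, 2] - 1) * din[1] +
                (idx[, 3] - 1) * din[1] * din[2]]
  }
  new_origin <- volume$origin + (cin - 1) * volume$spacing -
    (cout - 1) * target_spacing
  volume3d(array(vals, target_shape), spacing = as.numeric(target_spacing),
           origin = new_origin, modality = volume$modality)
}

#' Rigid (translation) pre-alignment of a moving to a fixed volume
#'
#' Stands in for the commercial pre-registration workflow upstream of the
#' network: translation-only alignment, either by matching intensity
#' centroids (default) or by a coarse exhaustive search over integer voxel
#' shifts maximising hard-binned mutual information. Voxel values are
#' untouched; only placement changes (resampling of the translated grid).
#'
#' @param moving,fixed [volume3d()] on a common grid.
#' @param method `"centroid"` or `"mi"`.
#' @param window half-width of the integer-shift search (voxels, `"mi"`
#'   method only).
#' @param bins histogram bins for the MI search.
#' @return list with `aligned` (translated moving volume) and
#'   `translation` (length-3, mm).
#' @export
rigid_prealign <- function(moving, fixed, method = c("centroid", "mi"),
                           window = 3L, bins = 16L) {
  method <- match.arg(method)
  stopifnot(is_volume3d(moving), is_volume3d(fixed))
  if (!all(dim(moving$data) == dim(fixed$data)))
    stop("moving and fixed must share a grid")
  w_m <- moving$data - min(moving$data)
  w_f <- fixed$data - min(fixed$data)
  if (sum(w_m) == 0 || sum(w_f) == 0)
    stop("flat image: intensity centroid undefined")
  if (method == "centroid") {
    g <- coord_grid(dim(moving$data))
    cm <- colSums(g * as.numeric(w_m)) / sum(w_m)
    cf <- colSums(g * as.numeric(w_f)) / sum(w_f)
    t_vox <- cf - cm
  } else {
    shifts <- expand.grid(dx = -window:window, dy = -window:window,
                          dz = -window:window)
    best <- -Inf; t_vox <- c(0, 0, 0)
    for (i in seq_len(nrow(shifts))) {
      s <- as.numeric(shifts[i, ])
      shifted <- shift_volume(moving$data, s)
      mi <- mutual_information(
        volume3d(shifted, fixed$spacing, modality = moving$modality),
        fixed, bins = bins)$mi
      if (mi > best) { best <- mi; t_vox <- s }
    }
  }
  aligned_data <- shift_volume(moving$data, t_vox)
  aligned <- volume3d(aligned_data, spacing = moving$spacing,
                      origin = moving$origin, modality = moving$modality)
  list(aligned = aligned, translation = vox_to_mm(t_vox, moving$spacing))
}

# translate a 3D array by t voxels (fractional allowed), border clamp
shift_volume <- function(data, t_vox) {
  d <- dim(data)
  g <- coord_grid(d)
  coords <- cbind(g[, 1] - t_vox[1], g[, 2] - t_vox[2], g[, 3] - t_vox[3])
  array(sample_trilinear(data, coords), d)
}

#' Exact Euclidean distance transform (squared), anisotropic
#'
#' Squared distance in mm from every voxel to the nearest nonzero voxel of
#' `mask`, respecting per-axis spacing. Computed by the exact separable
#' decomposition of the squared Euclidean metric (per-axis minimisation
#' over all shifts).
#'
#' @param mask 3D array (nonzero = object) or mask [volume3d()].
#' @param spacing voxel spacing in mm (taken from the volume if given one).
#' @return 3D array of squared distances in mm^2.
#' @export
distance_transform_sq <- function(mask, spacing = c(1, 1, 1)) {
  if (is_volume3d(mask)) { spacing <- mask$spacing; mask <- mask$data }
  d <- dim(mask)
  D2 <- array(0, d)
  D2[mask == 0] <- Inf
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    perm <- c(ax, setdiff(1:3, ax))
    M <- matrix(aperm(D2, perm), nrow = d[ax])
    n <- d[ax]; s <- spacing[ax]
    out <- M
    for (delta in seq_len(n - 1L)) {
      w <- (delta * s)^2
      if (w > suppressWarnings(max(out[is.finite(out)], 0)) &&
          all(is.finite(out))) break
      out[(delta + 1):n, ] <- pmin(out[(delta + 1):n, ],
                                   M[1:(n - delta), ] + w)
      out[1:(n - delta), ] <- pmin(out[1:(n - delta), ],
                                   M[(delta + 1):n, ] + w)
    }
    D2 <- aperm(array(out, d[perm]), order(perm))
  }
  D2
}

#' Expand a structure mask by a physical margin
#'
#' Morphological dilation by a Euclidean ball of radius `margin_mm` in
#' physical units (anisotropic spacing respected), the operation used to
#' build the PTV + margin region-of-interest mask. The output always
#' contains the input, and expansion is monotone in the margin.
#'
#' @param structure binary mask [volume3d()] (non-empty).
#' @param margin_mm non-negative margin in mm.
#' @param name name of the source structure (bookkeeping).
#' @return An object of class `roi_mask`: list with `mask` (binary
#'   [volume3d()]), `source_structure`, `margin_mm`.
#' @export
expand_mask <- function(structure, margin_mm, name = "structure") {
  stopifnot(is_volume3d(structure))
  if (sum(structure$data) == 0) stop("empty structure mask")
  if (margin_mm < 0) stop("'margin_mm' must be non-negative")
  if (margin_mm == 0) {
    out <- structure$data
  } else {
    d2 <- distance_transform_sq(structure$data, structure$spacing)
    out <- (d2 <= margin_mm^2 + 1e-9) * 1
  }
  structure(list(mask = volume3d(out, structure$spacing, structure$origin,
                                 modality = "mask"),
                 source_structure = name, margin_mm = margin_mm),
            class = "roi_mask")
}

# accept a roi_mask, a mask volume3d, or a bare binary array
mask_data <- function(m) {
  if (inherits(m, "roi_mask")) return(m$mask$data)
  if (is_volume3d(m)) return(m$data)
  m
}
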