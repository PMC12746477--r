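#' 3D image volume with physical geometry
#'
#' The basic carrier for images, masks and displacement-field components: a
#' 3D numeric array plus voxel spacing (mm), a world origin (mm) and a
#' modality tag. Displacement fields are stored separately as 4D arrays (see
#' [displacement_field()]); everything scalar travels as a `volume3d`.
#'
#' Coordinate conventions used throughout the package: voxel indices are
#' 1-based in R code; displacement fields are expressed in voxel units of the
#' fixed grid; all physical quantities (spacing, margins, Hausdorff
#' distances) are millimetres. [mm_to_vox()] and [vox_to_mm()] own the
#' conversion.
#'
#' @param data 3D numeric array. Masks must contain only 0 and 1.
#' @param spacing numeric length-3, voxel spacing in mm (> 0).
#' @param origin numeric length-3, world coordinate of voxel (1,1,1) in mm.
#' @param modality one of `"CT-like"`, `"MR-like"`, `"mask"`,
#'   `"field-component"`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     modality = c("CT-like", "MR-like", "mask", "field-component")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(!is.finite(data)))
    stop("volume contains non-finite voxels")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)")
  if (length(origin) != 3L)
    stop("'origin' must have length 3")
  if (modality == "mask" && !all(data %in% c(0, 1)))
    stop("mask volumes may contain only 0 and 1")
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = modality),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %s  %d x %d x %d voxels  spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%g, %g, %g) mm\n",
              min(x$data), max(x$data), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

is_volume3d <- function(x) inherits(x, "volume3d")

as_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  volume3d((data != 0) * 1, spacing, origin, modality = "mask")
}

#' Displacement field over a fixed grid
#'
#' A per-voxel 3-vector field u stored as a 4D array `[i, j, k, component]`,
#' in voxel units of the fixed grid. The convention follows the registration
#' model: the field maps fixed-image coordinates x to moving-image
#' coordinates x + u(x).
#'
#' @param u 4D numeric array with last dimension 3 (voxel units).
#' @param spacing voxel spacing of the fixed grid in mm.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing = c(1, 1, 1)) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("'u' must be a 4D array with 3 components in the last axis")
  if (any(!is.finite(u))) stop("displacement field contains non-finite values")
  structure(list(u = u, spacing = as.numeric(spacing)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$u)
  mg <- field_magnitude_mm(x)
  cat(sprintf("<displacement_field> %d x %d x %d, |u| mean %.3f mm, max %.3f mm\n",
              d[1], d[2], d[3], mean(mg), max(mg)))
  invisible(x)
}

#' Per-voxel displacement magnitude in millimetres
#'
#' Converts the stored voxel-unit components to mm through the grid spacing
#' and returns the Euclidean magnitude as a 3D array.
#'
#' @param field a [displacement_field()].
#' @return 3D array of |u| in mm.
#' @export
field_magnitude_mm <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  s <- field$spacing
  sqrt((field$u[, , , 1] * s[1])^2 +
       (field$u[, , , 2] * s[2])^2 +
       (field$u[, , , 3] * s[3])^2)
}

#' Millimetre / voxel conversions
#'
#' The single owner of the mm-to-voxel conversion: lengths in mm divide by
#' the per-axis spacing, voxel lengths multiply by it.
#'
#' @param x numeric vector of per-axis lengths.
#' @param spacing voxel spacing in mm.
#' @return converted numeric vector.
#' @export
mm_to_vox <- function(x, spacing) x / spacing

#' @rdname mm_to_vox
#' @export
vox_to_mm <- function(x, spacing) x * spacing

# Trilinear sampling of a 3D array at fractional voxel coordinates
# (1-based), border-clamped. coords: n x 3 matrix. Returns values, and
# optionally the spatial gradient d(value)/d(coord) (n x 3), which is the
# derivative used to backpropagate through the spatial transformer.
sample_trilinear <- function(data, coords, gradient = FALSE) {
  d <- dim(data)
  c1 <- pmin(pmax(coords[, 1], 1), d[1])
  c2 <- pmin(pmax(coords[, 2], 1), d[2])
  c3 <- pmin(pmax(coords[, 3], 1), d[3])
  f1 <- pmin(floor(c1), d[1] - 1L); f2 <- pmin(floor(c2), d[2] - 1L)
  f3 <- pmin(floor(c3), d[3] - 1L)
  if (d[1] == 1L) f1 <- rep(1, length(c1))
  if (d[2] == 1L) f2 <- rep(1, length(c2))
  if (d[3] == 1L) f3 <- rep(1, length(c3))
  t1 <- c1 - f1; t2 <- c2 - f2; t3 <- c3 - f3
  n1 <- d[1]; n12 <- d[1] * d[2]
  o1 <- as.integer(d[1] > 1L); o2 <- as.integer(d[2] > 1L)
  o3 <- as.integer(d[3] > 1L)
  base <- f1 + (f2 - 1) * n1 + (f3 - 1) * n12
  v000 <- data[base]
  v100 <- data[base + o1]
  v010 <- data[base + o2 * n1]
  v110 <- data[base + o1 + o2 * n1]
  v001 <- data[base + o3 * n12]
  v101 <- data[base + o1 + o3 * n12]
  v011 <- data[base + o2 * n1 + o3 * n12]
  v111 <- data[base + o1 + o2 * n1 + o3 * n12]
  w00 <- v000 * (1 - t1) + v100 * t1
  w10 <- v010 * (1 - t1) + v110 * t1
  w01 <- v001 * (1 - t1) + v101 * t1
  w11 <- v011 * (1 - t1) + v111 * t1
  w0 <- w00 * (1 - t2) + w10 * t2
  w1 <- w01 * (1 - t2) + w11 * t2
  val <- w0 * (1 - t3) + w1 * t3
  if (!gradient) return(val)
  # clamped samples have zero gradient along the clamped axis
  in1 <- (coords[, 1] > 1) & (coords[, 1] < d[1])
  in2 <- (coords[, 2] > 1) & (coords[, 2] < d[2])
  in3 <- (coords[, 3] > 1) & (coords[, 3] < d[3])
  g00 <- v100 - v000; g10 <- v110 - v010
  g01 <- v101 - v001; g11 <- v111 - v011
  d1 <- ((g00 * (1 - t2) + g10 * t2) * (1 - t3) +
         (g01 * (1 - t2) + g11 * t2) * t3) * in1
  d2 <- ((w10 - w00) * (1 - t3) + (w11 - w01) * t3) * in2
  d3 <- (w1 - w0) * in3
  list(value = val, grad = cbind(d1, d2, d3))
}

# full identity coordinate grid of a shape, n x 3 (1-based voxel coords)
coord_grid <- function(shape) {
  cbind(rep.int(seq_len(shape[1]), shape[2] * shape[3]),
        rep.int(rep(seq_len(shape[2]), each = shape[1]), shape[3]),
        rep(seq_len(shape[3]), each = shape[1] * shape[2]))
}
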