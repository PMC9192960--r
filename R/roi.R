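#' Spherical seed regions in MNI space
#'
#' `roi_set()` builds a set of spherical regions of interest from a tibble of
#' labels and MNI millimetre centers; `default_rois()` returns the 11 seeds of
#' the decision-making circuitry analysed by the package: ventrolateral
#' prefrontal cortex (vlPFC) and frontopolar cortex (FPC) for the arbitration
#' system, supplementary motor area (SMA) and posterolateral putamen for the
#' habitual system, and caudate and orbitofrontal cortex (OFC) for the
#' goal-directed system. Two separate left-putamen seeds (A and B) are kept as
#' distinct regions. All radii default to 5 mm.
#'
#' @param rois A data frame with columns `label`, `x`, `y`, `z` (MNI mm) and
#'   optionally `radius` (mm).
#' @param radius Default radius (mm) used where the table has none.
#' @return A tibble of class `roi_set` with columns `label, x, y, z, radius`.
#' @export
#' @examples
#' default_rois()
roi_set <- function(rois, radius = 5) {
  rois <- as_tibble(rois)
  stopifnot(all(c("label", "x", "y", "z") %in% names(rois)))
  if (!"radius" %in% names(rois)) rois$radius <- radius
  if (any(rois$radius <= 0)) stop("radii must be > 0.", call. = FALSE)
  if (anyDuplicated(rois$label)) stop("ROI labels must be unique.", call. = FALSE)
  structure(rois[, c("label", "x", "y", "z", "radius")],
            class = c("roi_set", class(rois)))
}

#' @rdname roi_set
#' @export
default_rois <- function(radius = 5) {
  roi_set(tibble(
    label = c("L_vlPFC", "R_vlPFC", "R_FPC",
              "L_putamen_A", "L_putamen_B", "R_putamen",
              "L_SMA", "R_SMA", "L_caudate", "R_caudate", "OFC"),
    x = c(-54, 48, 15, -27, -36, 33, -9, 9, -9, 9, -3),
    y = c(38, 35, 56, -19, -22, -10, 8, 8, 15, 15, 38),
    z = c(3, -2, 25, 4, -8, 1, 55, 55, 3, 3, -11)
  ), radius = radius)
}

#' Convert between millimetre and voxel coordinates
#'
#' Standard NIfTI affine mapping: `mm = affine %*% c(voxel, 1)` with 0-based
#' voxel indices. `mm_to_voxel()` applies the inverse affine with no rounding.
#'
#' @param affine 4x4 voxel-to-mm matrix (must be invertible).
#' @param coord Length-3 coordinate, or an n x 3 matrix.
#' @return Continuous coordinate(s) in the other frame, same shape as input.
#' @export
mm_to_voxel <- function(affine, coord) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps) {
    stop("affine is singular.", call. = FALSE)
  }
  apply_affine(solve(affine), coord)
}

#' @rdname mm_to_voxel
#' @export
voxel_to_mm <- function(affine, coord) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  apply_affine(affine, coord)
}

apply_affine <- function(A, coord) {
  single <- is.null(dim(coord))
  m <- if (single) matrix(coord, 1, 3) else as.matrix(coord)
  out <- t(A %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  if (single) as.vector(out) else out
}

#' Voxel mask of a sphere
#'
#' All voxels whose center lies within Euclidean distance `radius_mm` of
#' `center_mm` (inclusive). Inclusion is by voxel-center distance, not
#' partial-volume weighting.
#'
#' @param affine 4x4 voxel-to-mm matrix.
#' @param dim Length-3 integer image dimensions.
#' @param center_mm Sphere center in mm.
#' @param radius_mm Sphere radius in mm, > 0.
#' @return Integer matrix, one row per voxel (0-based `i, j, k` columns).
#'   Empty (with a warning) if the sphere misses the image.
#' @export
#' @examples
#' aff <- diag(c(2, 2, 2, 1))
#' nrow(sphere_mask(aff, c(20, 20, 20), c(20, 20, 20), 5))  # 81 on a 2 mm grid
sphere_mask <- function(affine, dim, center_mm, radius_mm) {
  assert_scalar_num(radius_mm, "radius_mm", positive = TRUE)
  stopifnot(length(dim) == 3)
  vc <- mm_to_voxel(affine, center_mm)
  # conservative per-axis voxel size bound for the search box
  vox_sizes <- sqrt(colSums(affine[1:3, 1:3]^2))
  halfwidth <- ceiling(radius_mm / vox_sizes) + 1
  rng <- lapply(1:3, function(a) {
    seq(max(0, floor(vc[a] - halfwidth[a])),
        min(dim[a] - 1, ceiling(vc[a] + halfwidth[a])))
  })
  if (any(lengths(rng) == 0)) {
    warning("sphere lies entirely outside the image.")
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "k"))))
  }
  grid <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  mm <- voxel_to_mm(affine, grid)
  d2 <- rowSums(sweep(mm, 2, center_mm, "-")^2)
  keep <- d2 <= radius_mm^2
  if (!any(keep)) warning("sphere lies entirely outside the image.")
  out <- grid[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  colnames(out) <- c("i", "j", "k")
  out
}

#' Extract mean ROI time series from a 4D image
#'
#' For each ROI, the spatial mean over its sphere mask is computed per volume;
#' each ROI series is then standardized (zero mean, unit variance) before
#' modelling, which the coefficient scale of the connectivity model assumes.
#'
#' @param image 4D array or RNifti image (x, y, z, time).
#' @param rois A [roi_set()].
#' @param affine 4x4 voxel-to-mm matrix; taken from the NIfTI header when
#'   `image` is an RNifti image.
#' @param tr Repetition time (s); taken from the header when available.
#' @param standardize Standardize each ROI series (default TRUE; recorded in
#'   the result's `standardized` attribute).
#' @return A [bold_ts()] (time x ROI) with attributes `mask_sizes` and
#'   `standardized`.
#' @export
extract_roi_timeseries <- function(image, rois, affine = NULL, tr = NULL,
                                   standardize = TRUE) {
  rois <- roi_set(rois)
  if (inherits(image, "niftiImage")) {
    if (is.null(affine)) affine <- structure(RNifti::xform(image),
                                             dimnames = NULL)
    if (is.null(tr)) {
      pd <- RNifti::pixdim(image)
      tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
    }
    image <- as.array(image)
  }
  stopifnot(length(dim(image)) == 4)
  if (is.null(affine)) stop("`affine` is required for array input.", call. = FALSE)
  if (is.null(tr)) tr <- 1
  dims <- dim(image)
  n_vol <- dims[4]
  vol_mat <- matrix(image, prod(dims[1:3]), n_vol)
  out <- matrix(NA_real_, n_vol, nrow(rois))
  sizes <- integer(nrow(rois))
  for (r in seq_len(nrow(rois))) {
    mask <- sphere_mask(affine, dims[1:3],
                        c(rois$x[r], rois$y[r], rois$z[r]), rois$radius[r])
    if (nrow(mask) == 0) {
      stop(sprintf("ROI '%s' has an empty mask.", rois$label[r]), call. = FALSE)
    }
    sizes[r] <- nrow(mask)
    lin <- 1L + mask[, 1] + dims[1] * (mask[, 2] + dims[2] * mask[, 3])
    out[, r] <- colMeans(vol_mat[lin, , drop = FALSE])
  }
  if (standardize) out <- standardize_columns(out)
  res <- bold_ts(out, tr = tr, regions = rois$label)
  attr(res, "mask_sizes") <- setNames(sizes, rois$label)
  attr(res, "standardized") <- standardize
  res
}

#' Embed region signals as spherical blobs in a synthetic 4D NIfTI
#'
#' Writes a compact 2 mm grid covering the default seed coordinates and fills
#' each ROI's sphere with its region's signal (constant within the blob per
#' volume), leaving background at zero plus optional noise. Used to exercise
#' the image-extraction path end-to-end with known ground truth.
#'
#' @param series A [neural_ts()] or [bold_ts()] with one column per ROI.
#' @param rois A [roi_set()] with as many rows as `series` has columns.
#' @param path Output `.nii` path (uncompressed unless the suffix is `.nii.gz`).
#' @param noise_sd Background (and blob) additive Gaussian noise SD, default 0.
#' @param margin_mm Margin around the seed bounding box, default 8.
#' @param seed Seed for the noise.
#' @return Invisibly, a list with `path`, `affine` and `dim`.
#' @export
write_synthetic_nifti <- function(series, rois, path, noise_sd = 0,
                                  margin_mm = 8, seed = NULL) {
  rois <- roi_set(rois)
  vals <- series$values
  stopifnot(ncol(vals) == nrow(rois))
  lo <- c(min(rois$x), min(rois$y), min(rois$z)) - max(rois$radius) - margin_mm
  hi <- c(max(rois$x), max(rois$y), max(rois$z)) + max(rois$radius) + margin_mm
  dims <- as.integer(ceiling((hi - lo) / 2) + 1)
  affine <- diag(c(2, 2, 2, 1))
  affine[1:3, 4] <- lo
  n_vol <- nrow(vals)
  img <- with_local_seed(seed, {
    if (noise_sd > 0) {
      array(rnorm(prod(dims) * n_vol, sd = noise_sd), dim = c(dims, n_vol))
    } else {
      array(0, dim = c(dims, n_vol))
    }
  })
  for (r in seq_len(nrow(rois))) {
    mask <- sphere_mask(affine, dims, c(rois$x[r], rois$y[r], rois$z[r]),
                        rois$radius[r])
    lin <- 1L + mask[, 1] + dims[1] * (mask[, 2] + dims[2] * mask[, 3])
    n_vox <- prod(dims)
    for (v in seq_len(n_vol)) {
      img[lin + (v - 1L) * n_vox] <- img[lin + (v - 1L) * n_vox] + vals[v, r]
    }
  }
  tr <- if (inherits(series, "bold_ts")) series$tr else series$dt
  nim <- RNifti::asNifti(img)
  RNifti::pixdim(nim) <- c(2, 2, 2, tr)
  nim <- RNifti::`sform<-`(nim, structure(affine, code = 2L))
  RNifti::writeNifti(nim, path)
  invisible(list(path = path, affine = affine, dim = dims, tr = tr))
}
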