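#' Axis-aligned voxel grid
#'
#' A `voxel_grid` describes a 3D lattice shared by all maps and masks in an
#' analysis: the number of voxels per axis, the voxel spacing in mm, and the
#' world position (mm) of the centre of voxel `(0, 0, 0)`.  Voxel indices are
#' 0-based; the centre of voxel `(i, j, k)` lies at
#' `origin + c(i, j, k) * spacing`.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3 (or a scalar, recycled), voxel
#'   spacing in mm (each > 0).
#' @param origin numeric vector of length 3, world coordinates (mm) of the
#'   centre of the first voxel.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  origin <- as.numeric(rep_len(origin, 3L))
  if (any(shape < 1L)) stop("all shape entries must be >= 1")
  if (any(spacing <= 0)) stop("all spacings must be > 0")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param grid a [voxel_grid()].
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_equal(a, b)) stop("volumes are not on the same voxel grid")
  invisible(TRUE)
}

#' World coordinates of voxel centres
#'
#' @param grid a [voxel_grid()].
#' @param axis axis number (1, 2 or 3).
#' @return Numeric vector of voxel-centre coordinates (mm) along `axis`.
#' @export
voxel_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Scalar field on a voxel grid
#'
#' Wraps a dense 3D numeric array together with its [voxel_grid()] and a unit
#' label.  Used for activity (Bq/voxel), absorbed dose (Gy), temperature
#' (degrees C) and Arrhenius damage (dimensionless) fields.
#'
#' @param values numeric 3D array (or vector reshaped to `grid$shape`).
#' @param grid a [voxel_grid()].
#' @param units unit label, e.g. `"Gy"`, `"Bq"`, `"degC"`, `""`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, grid, units = "") {
  v <- array(as.numeric(values), dim = grid$shape)
  if (length(v) != prod(grid$shape))
    stop("value count does not match the grid shape")
  if (any(!is.finite(v))) stop("scalar map contains non-finite values")
  structure(list(values = v, grid = grid, units = units),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<scalar_map> [%s] range %.4g .. %.4g on\n  ",
              x$units, rng[1], rng[2]))
  print(x$grid)
  invisible(x)
}

#' Binary mask on a voxel grid
#'
#' @param membership logical 3D array (or vector reshaped to `grid$shape`).
#' @param grid a [voxel_grid()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(membership, grid) {
  m <- array(as.logical(membership), dim = grid$shape)
  if (length(m) != prod(grid$shape))
    stop("membership count does not match the grid shape")
  if (any(is.na(m))) stop("mask contains undefined entries")
  structure(list(membership = m, grid = grid), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d / %d voxels set (%.2f cm^3) on\n  ",
              sum(x$membership), length(x$membership), mask_volume(x)))
  print(x$grid)
  invisible(x)
}

#' Mask volume in cm^3
#'
#' Number of set voxels times the voxel volume, converted from mm^3 to cm^3.
#'
#' @param mask a [label_mask()].
#' @return Volume in cm^3.
#' @export
mask_volume <- function(mask) {
  sum(mask$membership) * voxel_volume(mask$grid) / 1000
}

#' Mask set algebra
#'
#' Per-voxel boolean union, intersection and difference of two masks on the
#' same grid.
#'
#' @param a,b [label_mask()] objects on a common grid.
#' @return A [label_mask()].
#' @export
mask_union <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid)
  label_mask(a$membership | b$membership, a$grid)
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid)
  label_mask(a$membership & b$membership, a$grid)
}

#' @rdname mask_union
#' @export
mask_difference <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid)
  label_mask(a$membership & !b$membership, a$grid)
}

#' Write a map or mask to NIfTI-1
#'
#' Masks are stored as 8-bit 0/1 volumes; scalar maps as 32-bit float.  The
#' affine is diagonal (axis-aligned) with the grid spacing and origin.
#'
#' @param x a [scalar_map()] or [label_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "label_mask")) {
    arr <- array(as.integer(x$membership), dim = x$grid$shape)
    grid <- x$grid
    dt <- "uint8"
  } else if (inherits(x, "scalar_map")) {
    arr <- x$values
    grid <- x$grid
    dt <- "double"
  } else stop("x must be a scalar_map or label_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a NIfTI-1 volume as a map or mask
#'
#' Only axis-aligned affines are accepted (the voxel lattice must follow the
#' scanner axes); an oblique affine is rejected with a message naming the
#' offending axes.  When `type = "mask"` the voxel values are binarized at
#' `> 0.5`.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param type `"map"` for a [scalar_map()], `"mask"` for a [label_mask()].
#' @param units unit label attached when reading a map.
#' @return A [scalar_map()] or [label_mask()].
#' @export
read_volume <- function(path, type = c("map", "mask"), units = "") {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  offdiag <- abs(rot) * (1 - diag(3))
  if (any(offdiag > 1e-4 * max(abs(diag(rot))))) {
    bad <- which(apply(offdiag, 2, max) > 1e-4 * max(abs(diag(rot))))
    stop("non-axis-aligned affine on axes ", paste(bad, collapse = ", "),
         "; only axis-aligned grids are supported")
  }
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D volume")
  spacing <- abs(diag(rot))
  origin <- aff[1:3, 4]
  # normalise flipped axes to a positive-step grid
  for (a in 1:3) {
    if (diag(rot)[a] < 0) {
      arr <- flip_axis(arr, a)
      origin[a] <- origin[a] + diag(rot)[a] * (dim(arr)[a] - 1)
    }
  }
  grid <- voxel_grid(dim(arr), spacing, origin)
  if (type == "mask") label_mask(arr > 0.5, grid)
  else scalar_map(arr, grid, units = units)
}

flip_axis <- function(arr, axis) {
  idx <- lapply(dim(arr), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(arr), idx))
}

#' Rebin a fine field to a coarse mask
#'
#' Downsamples a fine-grid scalar field (e.g. an Arrhenius damage map from
#' the ablation simulation) onto a coarse dose grid as a binary mask.  Each
#' fine voxel is assigned to the coarse voxel containing its centre; a coarse
#' voxel is set when the fraction of its covering fine voxels whose value is
#' `>= value_threshold` reaches `occupancy`.  Coarse voxels not covered by
#' the fine grid are left unset.
#'
#' @param fine a [scalar_map()] (or [label_mask()]) on the fine grid.
#' @param coarse_grid the target [voxel_grid()]; spacing must be >= the fine
#'   spacing.
#' @param value_threshold fine-voxel value at or above which a fine voxel
#'   counts as "on" (for masks any value in (0,1) works; default 0.5).
#' @param occupancy minimum fraction of covering fine voxels that must be on
#'   (default 0.5).
#' @return A [label_mask()] on `coarse_grid`.
#' @export
rebin_fine_to_coarse <- function(fine, coarse_grid, value_threshold = 0.5,
                                 occupancy = 0.5) {
  if (inherits(fine, "label_mask"))
    fine <- scalar_map(fine$membership * 1.0, fine$grid)
  fg <- fine$grid
  if (any(fg$spacing > coarse_grid$spacing + 1e-9))
    stop("fine spacing must be <= coarse spacing on every axis")
  # coarse cell index (1-based) of each fine voxel centre, per axis
  ax_index <- function(a) {
    centers <- voxel_centers(fg, a)
    lo <- coarse_grid$origin[a] - coarse_grid$spacing[a] / 2
    idx <- floor((centers - lo) / coarse_grid$spacing[a]) + 1
    idx[idx < 1 | idx > coarse_grid$shape[a]] <- NA_integer_
    as.integer(idx)
  }
  ix <- ax_index(1); iy <- ax_index(2); iz <- ax_index(3)
  nxc <- coarse_grid$shape
  IX <- ix[slice.index(fine$values, 1)]
  IY <- iy[slice.index(fine$values, 2)]
  IZ <- iz[slice.index(fine$values, 3)]
  keep <- !is.na(IX) & !is.na(IY) & !is.na(IZ)
  if (!any(keep))
    stop("grids do not overlap: no fine voxel falls inside the coarse grid ",
         "extent")
  lin <- (IX[keep] - 1) + nxc[1] * ((IY[keep] - 1) + nxc[2] * (IZ[keep] - 1)) + 1
  on <- as.numeric(fine$values[keep] >= value_threshold)
  ncell <- prod(nxc)
  cover <- tabulate(lin, nbins = ncell)
  hits <- unname(tapply_sum(lin, on, ncell))
  frac <- ifelse(cover > 0, hits / cover, 0)
  label_mask(array(cover > 0 & frac >= occupancy, dim = nxc), coarse_grid)
}

tapply_sum <- function(index, values, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(values, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
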