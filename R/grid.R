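#' Regular voxel grid
#'
#' A regular, axis-aligned 3D voxel grid. World coordinates are in mm, voxel
#' indices are 0-based, and the axis order is (x, y, z) throughout the
#' package. `origin` is the world coordinate of the *center* of voxel
#' (0, 0, 0); no orientation matrix is carried (identity assumed), since all
#' volumes handled here are synthetic phantoms or derived fields.
#'
#' @param shape integer triple, number of voxels per axis (each >= 1).
#' @param spacing numeric triple, voxel spacing in mm (each > 0). A scalar is
#'   recycled to all three axes.
#' @param origin numeric triple, world coordinate (mm) of the center of voxel
#'   index (0, 0, 0).
#' @return An object of class `rfa_grid`.
#' @export
rfa_grid <- function(shape, spacing = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  origin <- as.numeric(rep_len(origin, 3L))
  if (any(shape < 1L)) stop("grid shape must be >= 1 along every axis")
  if (any(spacing <= 0)) stop("grid spacing must be > 0 along every axis")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "rfa_grid")
}

#' @export
print.rfa_grid <- function(x, ...) {
  cat(sprintf("rfa_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

grid_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-12))
}

#' Number of voxels in a grid
#' @param grid an `rfa_grid`.
#' @return integer voxel count.
#' @export
grid_nvox <- function(grid) prod(grid$shape)

#' Voxel volume in m^3
#'
#' Spacing is stored in mm; physical (SI) computations need m^3.
#' @param grid an `rfa_grid`.
#' @return scalar voxel volume in cubic meters.
#' @export
voxel_volume_m3 <- function(grid) prod(grid$spacing) * 1e-9

#' World coordinates of all voxel centers
#'
#' @param grid an `rfa_grid`.
#' @return An n-by-3 matrix of voxel-center coordinates (mm), in array order
#'   (x fastest, then y, then z), matching `as.vector` on a field array.
#' @export
voxel_centers <- function(grid) {
  ax <- lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a]
  })
  cbind(
    rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
    rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
    rep(ax[[3]], each = grid$shape[1] * grid$shape[2])
  )
}

# Per-axis voxel-center coordinate vectors (mm).
grid_axes <- function(grid) {
  lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a]
  })
}

# TRUE if the world point (mm triple) lies within the grid's bounding box
# (outer voxel edges).
point_in_grid <- function(grid, p) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  all(p >= lo) && all(p <= hi)
}

#' Binary mask on a voxel grid
#'
#' @param grid an `rfa_grid`.
#' @param values logical 3D array with `dim(values) == grid$shape`. A scalar
#'   `TRUE`/`FALSE` is expanded to the full grid.
#' @return An object of class `rfa_mask`.
#' @export
rfa_mask <- function(grid, values = FALSE) {
  if (length(values) == 1L) values <- array(as.logical(values), dim = grid$shape)
  values <- as.logical(values)
  dim(values) <- NULL
  if (length(values) != grid_nvox(grid)) {
    stop("mask values do not match the grid shape")
  }
  dim(values) <- grid$shape
  structure(list(grid = grid, values = values), class = "rfa_mask")
}

#' @export
print.rfa_mask <- function(x, ...) {
  cat(sprintf("rfa_mask: %d / %d voxels set (%.2f ml)\n",
              sum(x$values), grid_nvox(x$grid), mask_volume_ml(x)))
  invisible(x)
}

#' Mask volume in milliliters
#' @param mask an `rfa_mask`.
#' @return volume in ml (= cm^3).
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$values) * prod(mask$grid$spacing) / 1000
}

mask_and <- function(a, b) rfa_mask(a$grid, a$values & b$values)
mask_or <- function(a, b) rfa_mask(a$grid, a$values | b$values)
mask_subset <- function(a, b) !any(a$values & !b$values) # a subseteq b

#' Write a volume or mask as NIfTI
#'
#' Masks are written as uint8, scalar fields as float32. The grid's spacing
#' and origin are recorded in the NIfTI header (identity orientation).
#'
#' @param x an `rfa_mask`, or a numeric 3D array.
#' @param grid the `rfa_grid` (taken from the mask if `x` is one).
#' @param path output path, conventionally ending in `.nii.gz`.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "rfa_mask")) {
    grid <- x$grid
    arr <- array(as.integer(x$values), dim = grid$shape)
    dt <- "uint8"
  } else {
    if (is.null(grid)) stop("grid must be given when writing a raw array")
    arr <- x
    dt <- "float"
  }
  attr(arr, "pixdim") <- grid$spacing
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = dt), path, datatype = dt)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume()]
#'
#' @param path NIfTI file path.
#' @param as_mask logical; if `TRUE`, return an `rfa_mask` (values != 0).
#' @param origin world origin (mm) to attach; NIfTI files written by this
#'   package do not carry the phantom origin, which lives in the run config.
#' @return an `rfa_mask` or a list `(grid, values)`.
#' @export
read_volume <- function(path, as_mask = FALSE, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
  attributes(arr) <- list(dim = dim(arr)) # drop NIfTI bookkeeping
  grid <- rfa_grid(dim(arr), RNifti::pixdim(img)[1:3], origin)
  if (as_mask) rfa_mask(grid, arr != 0) else list(grid = grid, values = arr)
}
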