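#' Default tissue properties for the bioheat model
#'
#' Per-tissue-class scalar properties for the Pennes equation. Values are
#' implementation defaults drawn from standard hepatic bioheat literature
#' and are fully configurable; `rho` is density (kg/m^3), `c` specific heat
#' capacity (J/(kg K)), `k` thermal conductivity (W/(m K)), `omega_b` blood
#' mass perfusion rate (kg/(m^3 s)). `c_b` and `T_b` are blood heat capacity
#' (J/(kg K)) and arterial blood temperature (deg C), shared by all classes.
#'
#' @param healthy,tumor,vessel named lists overriding per-class defaults
#'   (`rho`, `c`, `k`, `omega_b`).
#' @param c_b blood specific heat capacity, J/(kg K).
#' @param T_b arterial blood temperature, deg C.
#' @return a `tissue_properties` list.
#' @export
tissue_properties <- function(healthy = list(), tumor = list(), vessel = list(),
                              c_b = 3600, T_b = 37) {
  def <- list(
    healthy = list(rho = 1060, c = 3600, k = 0.512, omega_b = 2.0),
    tumor   = list(rho = 1045, c = 3760, k = 0.550, omega_b = 0.6),
    vessel  = list(rho = 1060, c = 3600, k = 0.512, omega_b = 0)
  )
  ov <- list(healthy = healthy, tumor = tumor, vessel = vessel)
  for (cl in names(def)) {
    for (f in names(ov[[cl]])) {
      if (!f %in% names(def[[cl]])) stop("unknown tissue property: ", f)
      def[[cl]][[f]] <- as.numeric(ov[[cl]][[f]])
    }
    vals <- unlist(def[[cl]])
    if (any(vals[c("rho", "c", "k")] <= 0)) {
      stop("tissue density, heat capacity and conductivity must be > 0")
    }
    if (def[[cl]]$omega_b < 0) stop("perfusion must be >= 0")
  }
  if (c_b <= 0) stop("blood heat capacity must be > 0")
  structure(c(def, list(c_b = as.numeric(c_b), T_b = as.numeric(T_b))),
            class = "tissue_properties")
}

#' Spherical tumor mask
#'
#' A voxel belongs to the mask iff its *center* lies within `radius` mm of
#' `center` (voxel-center-in-shape rule; no partial-volume weighting).
#'
#' @param grid an `rfa_grid`.
#' @param center mm triple, must lie inside the grid bounds.
#' @param radius mm, >= 0.
#' @return an `rfa_mask`.
#' @export
make_tumor_mask <- function(grid, center, radius) {
  center <- as.numeric(center)
  if (radius < 0) stop("tumor radius must be >= 0")
  if (!point_in_grid(grid, center)) {
    stop("tumor center lies outside the grid bounds: invalid phantom spec")
  }
  ax <- grid_axes(grid)
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  rfa_mask(grid, d2 <= radius^2 + 1e-12)
}

#' Cylindrical vessel mask
#'
#' Capped cylinder: a voxel belongs iff its center lies within `radius` mm
#' of the segment `p0`--`p1`.
#'
#' @param grid an `rfa_grid`.
#' @param p0,p1 segment endpoints, mm triples, `p0 != p1`.
#' @param radius mm, > 0.
#' @return an `rfa_mask`.
#' @export
make_vessel_mask <- function(grid, p0, p1, radius) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (all(p0 == p1)) stop("vessel endpoints must differ")
  if (radius <= 0) stop("vessel radius must be > 0")
  ctr <- voxel_centers(grid)
  d <- point_segment_distance(ctr, p0, p1)
  rfa_mask(grid, array(d <= radius + 1e-12, dim = grid$shape))
}

# Distance from each row of the n-by-3 matrix `p` to segment a--b (mm).
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
          (p[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((p[, 1] - (a[1] + t * ab[1]))^2 +
         (p[, 2] - (a[2] + t * ab[2]))^2 +
         (p[, 3] - (a[3] + t * ab[3]))^2)
}

#' Assemble a synthetic patient phantom
#'
#' Combines a liver region of interest, tumor and vessel masks and realizes
#' per-voxel property fields. Where shapes overlap, the precedence is
#' vessel > tumor > healthy, so that vessels always act as heat sinks; in
#' particular the stored tumor mask has vessel voxels removed, giving the
#' construction invariants `tumor` inside `liver_roi` and
#' `vessels intersect tumor = empty set`.
#'
#' @param grid an `rfa_grid`.
#' @param tumor an `rfa_mask` (tumor before precedence).
#' @param vessels an `rfa_mask` or `NULL`.
#' @param liver_roi an `rfa_mask`; defaults to the full grid.
#' @param properties a [tissue_properties()] object.
#' @return an object of class `rfa_phantom` with per-voxel fields
#'   `rho`, `c`, `k`, `omega_b` (arrays) and a `label` array
#'   (0 = outside/healthy background, 1 = healthy ROI, 2 = tumor, 3 = vessel).
#' @export
rfa_phantom <- function(grid, tumor, vessels = NULL, liver_roi = NULL,
                        properties = tissue_properties()) {
  if (is.null(liver_roi)) liver_roi <- rfa_mask(grid, TRUE)
  if (is.null(vessels)) vessels <- rfa_mask(grid, FALSE)
  for (m in list(tumor, vessels, liver_roi)) {
    if (!grid_equal(m$grid, grid)) stop("all masks must share the phantom grid")
  }
  tum <- tumor$values & liver_roi$values & !vessels$values
  ves <- vessels$values
  label <- array(0L, dim = grid$shape)
  label[liver_roi$values] <- 1L
  label[tum] <- 2L
  label[ves] <- 3L

  fld <- function(f) {
    a <- array(properties$healthy[[f]], dim = grid$shape)
    a[tum] <- properties$tumor[[f]]
    a[ves] <- properties$vessel[[f]]
    a
  }
  structure(list(
    grid = grid,
    liver_roi = liver_roi,
    tumor = rfa_mask(grid, tum),
    vessels = rfa_mask(grid, ves),
    label = label,
    rho = fld("rho"), c = fld("c"), k = fld("k"), omega_b = fld("omega_b"),
    c_b = properties$c_b, T_b = properties$T_b,
    properties = properties
  ), class = "rfa_phantom")
}

#' @export
print.rfa_phantom <- function(x, ...) {
  cat(sprintf(
    "rfa_phantom: %d x %d x %d @ (%g, %g, %g) mm | ROI %.1f ml, tumor %.2f ml, vessels %.2f ml\n",
    x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
    x$grid$spacing[1], x$grid$spacing[2], x$grid$spacing[3],
    mask_volume_ml(x$liver_roi), mask_volume_ml(x$tumor),
    mask_volume_ml(x$vessels)))
  invisible(x)
}

#' Centroid of a mask
#' @param mask a non-empty `rfa_mask`.
#' @return mm triple: the mean of the voxel centers in the mask.
#' @export
mask_centroid <- function(mask) {
  if (!any(mask$values)) stop("cannot take the centroid of an empty mask")
  ctr <- voxel_centers(mask$grid)
  colMeans(ctr[as.vector(mask$values), , drop = FALSE])
}

#' Restrict the simulation domain to a sphere around the tumor
#'
#' Heat deposition decays quickly with distance from the probe, so the
#' simulation domain is limited to a sphere around the tumor (default
#' radius 60 mm). Only the liver ROI is restricted; solver and metrics
#' operate inside the ROI only.
#'
#' @param phantom an `rfa_phantom`.
#' @param center mm triple; defaults to the tumor-mask centroid.
#' @param radius mm, > 0; default 60.
#' @return a new `rfa_phantom` with the restricted ROI.
#' @export
crop_domain <- function(phantom, center = NULL, radius = 60) {
  if (radius <= 0) stop("crop radius must be > 0")
  if (is.null(center)) {
    if (!any(phantom$tumor$values)) {
      stop("empty tumor mask: an explicit crop center is required")
    }
    center <- mask_centroid(phantom$tumor)
  }
  sphere <- make_tumor_mask_unchecked(phantom$grid, center, radius)
  roi <- rfa_mask(phantom$grid, phantom$liver_roi$values & sphere)
  rfa_phantom(phantom$grid, phantom$tumor, phantom$vessels, roi,
              phantom$properties)
}

# Sphere membership without the in-grid center check (crop centers may
# legitimately sit anywhere).
make_tumor_mask_unchecked <- function(grid, center, radius) {
  ax <- grid_axes(grid)
  d2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, `+`),
              (ax[[3]] - center[3])^2, `+`)
  d2 <= radius^2 + 1e-12
}

#' Synthetic paired landmarks
#'
#' Emulates manual picking of matching landmarks in two needle images: each
#' source point is mapped through a known rigid transform and perturbed with
#' i.i.d. Gaussian noise. Used to exercise the rigid registration.
#'
#' @param points n-by-3 matrix (or list of triples), n >= 3, in mm.
#' @param transform an [rigid_transform()].
#' @param noise_sd mm standard deviation of the added Gaussian noise.
#' @param seed integer seed; fixed seed gives identical output.
#' @return list with `source` and `target` n-by-3 matrices.
#' @export
make_landmark_pairs <- function(points, transform = rigid_transform(),
                                noise_sd = 0, seed = 1L) {
  if (is.list(points) && !is.matrix(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("at least 3 landmark points are required")
  tgt <- apply_transform(transform, points)
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    tgt <- tgt + matrix(rng$rnorm(length(tgt), sd = noise_sd), ncol = 3)
  }
  list(source = points, target = tgt)
}

# Isolated seeded RNG: draws come from a private RNG stream so that package
# calls never disturb (or depend on) the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  use <- function(fn) {
    function(...) {
      prev <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(prev)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", prev, globalenv())
      })
      fn(...)
    }
  }
  list(rnorm = use(stats::rnorm), runif = use(stats::runif),
       sample_int = use(sample.int))
}

#' Write landmark points as CSV
#'
#' CSV columns are `name,x,y,z` with coordinates in mm.
#' @param points n-by-3 matrix of points (mm).
#' @param path output CSV path.
#' @param names optional point names; defaults to `L1..Ln`.
#' @return the path, invisibly.
#' @export
write_landmarks <- function(points, path, names = NULL) {
  points <- as.matrix(points)
  if (is.null(names)) names <- paste0("L", seq_len(nrow(points)))
  utils::write.csv(
    data.frame(name = names, x = points[, 1], y = points[, 2], z = points[, 3]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmark points from CSV
#' @param path CSV with header `name,x,y,z` (mm).
#' @return n-by-3 matrix with rownames from the `name` column.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) stop("landmark CSV must have columns name,x,y,z")
  m <- as.matrix(df[, need])
  rownames(m) <- if ("name" %in% names(df)) df$name else NULL
  m
}

#' Build a phantom from a declarative specification
#'
#' The specification mirrors the YAML `phantom:` config section: grid shape,
#' spacing and origin; a spherical tumor; zero or more cylindrical vessels;
#' an optional spherical liver ROI before domain cropping; tissue property
#' overrides; and the domain-restriction radius (default 60 mm).
#'
#' @param spec a named list (see Details) or a YAML file path.
#' @return an `rfa_phantom`, domain-cropped.
#' @export
phantom_from_spec <- function(spec) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  g <- spec$grid
  if (is.null(g)) stop("phantom spec needs a 'grid' section")
  grid <- rfa_grid(g$shape, if (is.null(g$spacing)) 1 else g$spacing,
                   if (is.null(g$origin)) c(0, 0, 0) else g$origin)
  if (is.null(spec$tumor)) stop("phantom spec needs a 'tumor' section")
  tumor <- make_tumor_mask(grid, spec$tumor$center, spec$tumor$radius)
  vessels <- rfa_mask(grid, FALSE)
  for (v in spec$vessels) {
    vessels <- mask_or(vessels, make_vessel_mask(grid, v$p0, v$p1, v$radius))
  }
  roi <- NULL
  if (!is.null(spec$liver)) {
    roi <- rfa_mask(grid, make_tumor_mask_unchecked(
      grid, spec$liver$center, spec$liver$radius))
  }
  props <- do.call(tissue_properties, if (is.null(spec$properties)) list()
                   else spec$properties)
  ph <- rfa_phantom(grid, tumor, vessels, roi, props)
  crop_r <- if (is.null(spec$crop_radius)) 60 else spec$crop_radius
  crop_domain(ph, radius = crop_r)
}

#' Default demonstration phantom
#'
#' A 64^3, 2 mm isotropic phantom: 12.5 mm spherical tumor at the grid
#' center with a 3 mm vessel passing 16 mm lateral to it, domain-cropped to
#' the default 60 mm sphere. Used by the examples, the acceptance script and
#' the command-line `phantom` subcommand when no spec is given.
#'
#' @param shape grid shape (default 64^3).
#' @param spacing voxel spacing in mm (default 2).
#' @param tumor_radius tumor radius in mm (default 12.5).
#' @return an `rfa_phantom`.
#' @export
default_phantom <- function(shape = c(64, 64, 64), spacing = 2,
                            tumor_radius = 12.5) {
  grid <- rfa_grid(shape, spacing)
  ctr <- (grid$shape - 1) * grid$spacing / 2
  tumor <- make_tumor_mask(grid, ctr, tumor_radius)
  ves <- make_vessel_mask(grid, ctr + c(16, 0, -60), ctr + c(16, 0, 60), 3)
  crop_domain(rfa_phantom(grid, tumor, ves))
}
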