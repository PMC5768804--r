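#' Parameters of the three-state cell-death model
#'
#' Per-voxel kinetics Alive <-> Vulnerable -> Dead with a
#' temperature-dependent forward rate
#' `k_f(T, A) = k_f_bar * exp(T / T_k) * (1 - A)` and a constant recovery
#' rate `k_b`; Dead is absorbing. Defaults follow the published
#' parameterization of the three-state thermal cell-death model
#' (O'Neill-type kinetics); all values are configurable.
#'
#' @param k_f_bar forward rate scale, 1/s.
#' @param k_b recovery rate Vulnerable -> Alive, 1/s.
#' @param T_k exponential temperature scale, deg C.
#' @param death_threshold lesion threshold on the Dead fraction, in (0, 1).
#' @return a `cell_death_params` list.
#' @export
cell_death_params <- function(k_f_bar = 3.33e-3, k_b = 7.77e-3, T_k = 40.5,
                              death_threshold = 0.8) {
  if (k_f_bar < 0 || k_b < 0 || T_k <= 0) {
    stop("cell-death rates must be >= 0 and T_k > 0")
  }
  if (death_threshold <= 0 || death_threshold >= 1) {
    stop("death threshold must lie strictly between 0 and 1")
  }
  structure(list(k_f_bar = k_f_bar, k_b = k_b, T_k = T_k,
                 death_threshold = death_threshold),
            class = "cell_death_params")
}

# Right-hand side of the three-state kinetics; A, V, T are conformable
# numeric vectors/arrays. Returns list(dA, dV) — D follows from conservation.
cell_death_rhs <- function(A, V, T, params) {
  k_f <- params$k_f_bar * exp(T / params$T_k) * (1 - A)
  list(dA = -k_f * A + params$k_b * V,
       dV = k_f * A - params$k_b * V - k_f * V)
}

#' Advance the cell-death kinetics by one time step
#'
#' One classical 4th-order Runge-Kutta step of the three-state kinetics at
#' frozen temperature (the bioheat/death operator splitting holds `T`
#' constant over `dt`). States are clamped to `[0, 1]` and renormalized to
#' `A + V + D = 1`; inputs violating conservation beyond `tol` are rejected.
#'
#' @param A,V,D state fraction fields (arrays or vectors, conformable).
#' @param T temperature field, deg C.
#' @param dt time step, s, > 0.
#' @param params a [cell_death_params()] object.
#' @param tol conservation tolerance on the input state.
#' @return list with updated `A`, `V`, `D`.
#' @export
step_cell_death <- function(A, V, D, T, dt, params = cell_death_params(),
                            tol = 1e-6) {
  if (dt <= 0) stop("dt must be > 0")
  if (min(A, V, D) < -tol || max(abs(A + V + D - 1)) > tol) {
    stop("invalid cell state: fractions must be >= 0 and sum to 1")
  }
  k1 <- cell_death_rhs(A, V, T, params)
  k2 <- cell_death_rhs(A + dt / 2 * k1$dA, V + dt / 2 * k1$dV, T, params)
  k3 <- cell_death_rhs(A + dt / 2 * k2$dA, V + dt / 2 * k2$dV, T, params)
  k4 <- cell_death_rhs(A + dt * k3$dA, V + dt * k3$dV, T, params)
  A2 <- A + dt / 6 * (k1$dA + 2 * k2$dA + 2 * k3$dA + k4$dA)
  V2 <- V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
  A2 <- pmin(pmax(A2, 0), 1)
  V2 <- pmin(pmax(V2, 0), 1)
  over <- A2 + V2 > 1
  if (any(over)) {
    s <- A2[over] + V2[over]
    A2[over] <- A2[over] / s
    V2[over] <- V2[over] / s
  }
  list(A = A2, V = V2, D = 1 - A2 - V2)
}

#' Triangulated surface
#'
#' @param vertices n-by-3 matrix of vertex coordinates (world mm).
#' @param faces m-by-3 integer matrix of 1-based vertex indices.
#' @return an object of class `rfa_surface`.
#' @export
rfa_surface <- function(vertices, faces) {
  structure(list(vertices = vertices, faces = faces), class = "rfa_surface")
}

#' @export
print.rfa_surface <- function(x, ...) {
  cat(sprintf("rfa_surface: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Iso-surface of a scalar field
#'
#' Marching-tetrahedra triangulation of the level set `field == iso`;
#' vertices in world mm.
#' @param field 3D numeric array on `grid`.
#' @param grid an `rfa_grid`.
#' @param iso iso-value.
#' @return an `rfa_surface` (possibly with 0 triangles).
#' @export
iso_surface <- function(field, grid, iso) {
  res <- cpp_marching_tetrahedra(as.numeric(field), grid$shape, grid$spacing,
                                 grid$origin, iso)
  rfa_surface(res$vertices, res$faces + 1L)
}

#' Surface of a binary mask
#'
#' Iso-surface of the 0/1 indicator at level 0.5 — a tessellation of the
#' mask boundary lying halfway between inside and outside voxel centers.
#' @param mask an `rfa_mask`.
#' @return an `rfa_surface`.
#' @export
mask_surface <- function(mask) {
  iso_surface(array(as.numeric(mask$values), dim = mask$grid$shape),
              mask$grid, 0.5)
}

#' Extract the predicted coagulation zone
#'
#' The lesion is the set of ROI voxels whose Dead fraction has reached the
#' death threshold; its surface is the iso-surface of the (ROI-restricted)
#' Dead field at that threshold.
#'
#' @param D Dead-fraction field (3D array on the ROI grid), values in `[0,1]`.
#' @param roi an `rfa_mask` restricting the domain.
#' @param death_threshold threshold on D, in (0, 1); default from
#'   [cell_death_params()].
#' @return list with `mask` (an `rfa_mask`) and `surface` (an `rfa_surface`);
#'   both empty when no voxel reaches the threshold.
#' @export
extract_lesion <- function(D, roi, death_threshold = 0.8) {
  if (min(D) < -1e-9 || max(D) > 1 + 1e-9) stop("D must lie in [0, 1]")
  vals <- array(as.numeric(D), dim = roi$grid$shape)
  vals[!roi$values] <- 0
  mask <- rfa_mask(roi$grid, vals >= death_threshold)
  surf <- iso_surface(vals, roi$grid, death_threshold)
  list(mask = mask, surface = surf)
}

#' Write a surface as STL
#'
#' ASCII STL; normals are written as facet geometric normals.
#' @param surface an `rfa_surface`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stl <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid lesion", con)
  v <- surface$vertices
  f <- surface$faces
  if (nrow(f)) {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    c_ <- v[f[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- c_ - a
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    txt <- vapply(seq_len(nrow(f)), function(i) {
      paste0(sprintf(" facet normal %.9g %.9g %.9g\n  outer loop\n",
                     nrm[i, 1], nrm[i, 2], nrm[i, 3]),
             sprintf("   vertex %.9g %.9g %.9g\n", a[i, 1], a[i, 2], a[i, 3]),
             sprintf("   vertex %.9g %.9g %.9g\n", b[i, 1], b[i, 2], b[i, 3]),
             sprintf("   vertex %.9g %.9g %.9g\n  endloop\n endfacet",
                     c_[i, 1], c_[i, 2], c_[i, 3]))
    }, character(1))
    writeLines(txt, con)
  }
  writeLines("endsolid lesion", con)
  invisible(path)
}

#' Read an ASCII STL surface
#' @param path STL file path.
#' @return an `rfa_surface` (triangle soup).
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl)) return(rfa_surface(matrix(0, 0, 3), matrix(0L, 0, 3)))
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  nf <- nrow(nums) / 3
  rfa_surface(nums, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}
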