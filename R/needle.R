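#' RFA needle geometry
#'
#' A probe is described by its tip, a trocar point along the shaft, and —
#' for umbrella-shaped (RITA-style) models — the deployed prong tips.
#' Prong positions for arbitrary deployments are reconstructed from a
#' reference geometry by linear interpolation (or extrapolation) from the
#' tip, optionally rotated about the trocar--tip axis.
#'
#' @name needle_geometry
NULL

new_needle <- function(tip, shaft_point, prongs, reference_prongs = NULL,
                       rotation_deg = 0, extension_fraction = 1) {
  tip <- as.numeric(tip); shaft_point <- as.numeric(shaft_point)
  if (all(tip == shaft_point)) stop("needle tip and shaft point must differ")
  structure(list(
    tip = tip, shaft_point = shaft_point,
    prongs = prongs, reference_prongs = reference_prongs,
    rotation_deg = as.numeric(rotation_deg),
    extension_fraction = as.numeric(extension_fraction)
  ), class = "rfa_needle")
}

#' @export
print.rfa_needle <- function(x, ...) {
  kind <- if (length(x$prongs)) sprintf("umbrella (%d prongs, extension %.2f)",
                                        length(x$prongs), x$extension_fraction)
          else "simple"
  cat(sprintf("rfa_needle: %s, tip (%g, %g, %g) mm\n", kind,
              x$tip[1], x$tip[2], x$tip[3]))
  invisible(x)
}

#' Unit direction of the needle shaft
#'
#' Points from the trocar (shaft point) towards the tip.
#' @param needle an `rfa_needle`.
#' @return unit mm triple `normalize(tip - shaft_point)`.
#' @export
needle_direction <- function(needle) {
  d <- needle$tip - needle$shaft_point
  d / sqrt(sum(d^2))
}

#' Simple (single-electrode) needle
#'
#' @param tip mm triple: the needle tip (conventionally placed at or near
#'   the tumor).
#' @param shaft_point mm triple: the trocar point, any point along the
#'   shaft; must differ from the tip.
#' @return an `rfa_needle` with no prongs.
#' @export
make_simple_needle <- function(tip, shaft_point) {
  new_needle(tip, shaft_point, prongs = list())
}

#' Umbrella-shaped needle with reconstructed prongs
#'
#' Prong tips at deployment `extension_fraction` are reconstructed from a
#' reference geometry (e.g. picked in a needle image at full deployment):
#' `prong_i = tip + f * R_axis(rotation_deg) (ref_i - tip)`, where `R_axis`
#' rotates about the shaft (trocar--tip) axis through the tip. `f = 1`
#' reproduces the reference, `f = 0` collapses all prongs onto the tip, and
#' `f > 1` extrapolates beyond the imaged deployment.
#'
#' @param tip,shaft_point as in [make_simple_needle()].
#' @param reference_prongs non-empty list of mm triples (or n-by-3 matrix):
#'   prong tips of the reference geometry. Default: a symmetric 9-prong
#'   RITA-style umbrella opening back towards the shaft.
#' @param rotation_deg rotation about the shaft axis, degrees.
#' @param extension_fraction deployment fraction, >= 0.
#' @return an `rfa_needle` with reconstructed `prongs`.
#' @export
make_umbrella_needle <- function(tip, shaft_point,
                                 reference_prongs = NULL,
                                 rotation_deg = 0, extension_fraction = 1) {
  tip <- as.numeric(tip); shaft_point <- as.numeric(shaft_point)
  if (is.null(reference_prongs)) {
    reference_prongs <- default_umbrella_prongs(tip, shaft_point)
  }
  if (is.matrix(reference_prongs)) {
    reference_prongs <- lapply(seq_len(nrow(reference_prongs)),
                               function(i) reference_prongs[i, ])
  }
  if (length(reference_prongs) == 0L) {
    stop("umbrella needle requires a non-empty reference prong list")
  }
  if (extension_fraction < 0) stop("extension fraction must be >= 0")
  ndl <- new_needle(tip, shaft_point, prongs = list(),
                    reference_prongs = lapply(reference_prongs, as.numeric),
                    rotation_deg = rotation_deg,
                    extension_fraction = extension_fraction)
  ndl$prongs <- reconstruct_prongs(ndl)
  ndl
}

# prong_i = tip + f * R_axis(theta) (ref_i - tip)
reconstruct_prongs <- function(needle) {
  ax <- needle$tip - needle$shaft_point
  R <- rotation_about_axis(ax, needle$rotation_deg)
  lapply(needle$reference_prongs, function(p) {
    needle$tip + needle$extension_fraction * as.vector(R %*% (p - needle$tip))
  })
}

#' Change the deployment of an umbrella needle
#'
#' Re-derives the prong tips for a new extension fraction (and optionally a
#' new axial rotation) from the stored reference geometry.
#' @param needle an umbrella `rfa_needle`.
#' @param extension_fraction new deployment fraction, >= 0.
#' @param rotation_deg new axial rotation (default: keep current).
#' @return the updated `rfa_needle`.
#' @export
set_extension <- function(needle, extension_fraction,
                          rotation_deg = needle$rotation_deg) {
  if (is.null(needle$reference_prongs) || !length(needle$reference_prongs)) {
    return(needle) # simple needles have no deployment
  }
  make_umbrella_needle(needle$tip, needle$shaft_point, needle$reference_prongs,
                       rotation_deg, extension_fraction)
}

# Symmetric RITA-style reference umbrella: 9 prongs fanning back from the
# tip towards the shaft, 15 mm long at full deployment, 60 deg half-angle.
default_umbrella_prongs <- function(tip, shaft_point, n_prongs = 9,
                                    length_mm = 15, half_angle_deg = 60) {
  axis <- (tip - shaft_point) / sqrt(sum((tip - shaft_point)^2))
  # orthonormal frame around the shaft axis
  seed_v <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed_v - sum(seed_v * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  alpha <- half_angle_deg * pi / 180
  lapply(seq_len(n_prongs), function(i) {
    phi <- 2 * pi * (i - 1) / n_prongs
    dirv <- -cos(alpha) * axis +
      sin(alpha) * (cos(phi) * e1 + sin(phi) * e2)
    tip + length_mm * dirv
  })
}

#' Default needle placement for a phantom
#'
#' Places the default 9-prong umbrella needle so that the centroid of its
#' heat-source points (tip plus prong tips) coincides with the tumor
#' centroid — the prongs of an umbrella probe open back towards the shaft,
#' so the tip itself sits slightly deep of the tumor center.
#'
#' @param phantom an `rfa_phantom` with a non-empty tumor.
#' @param approach unit-ish direction from which the needle is inserted
#'   (shaft side); default from above, `(0, 0, 1)`.
#' @param prong_length full-deployment prong length, mm.
#' @return an `rfa_needle`.
#' @export
default_needle <- function(phantom, approach = c(0, 0, 1), prong_length = 15) {
  ctr <- mask_centroid(phantom$tumor)
  zhat <- approach / sqrt(sum(approach^2))
  # source centroid sits (n/(n+1)) * length * cos(half-angle) towards the
  # shaft from the tip; compensate so it lands on the tumor centroid
  n_prongs <- 9
  offset <- n_prongs / (n_prongs + 1) * prong_length * cos(60 * pi / 180)
  tip <- ctr - offset * zhat
  shaft <- tip + 60 * zhat
  make_umbrella_needle(tip, shaft,
                       default_umbrella_prongs(tip, shaft,
                                               length_mm = prong_length))
}

#' Randomly perturbed needle geometries
#'
#' Emulates uncertainty in needle placement and prong deployment: each
#' selected point is displaced by a vector drawn uniformly from the closed
#' ball of radius `r` (rejection sampling from the bounding cube), the rest
#' are left unchanged. Umbrella prongs are perturbed directly (not
#' re-derived from the reference), matching perturbation of individually
#' registered prong tips.
#'
#' @param needle an `rfa_needle`.
#' @param r perturbation radius in mm, >= 0.
#' @param n number of perturbed geometries to draw, >= 1.
#' @param which_points character subset of `c("tip", "shaft", "prongs")`;
#'   defaults to all points.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a list of `n` perturbed `rfa_needle` objects.
#' @export
perturb_needle <- function(needle, r, n = 1L,
                           which_points = c("tip", "shaft", "prongs"),
                           seed = 1L) {
  if (r < 0) stop("perturbation radius must be >= 0")
  if (n < 1L) stop("need n >= 1 perturbed geometries")
  which_points <- match.arg(which_points, several.ok = TRUE)
  rng <- local_rng(seed)
  lapply(seq_len(n), function(i) {
    out <- needle
    if ("tip" %in% which_points) out$tip <- out$tip + runif_ball(rng, r)
    if ("shaft" %in% which_points) {
      out$shaft_point <- out$shaft_point + runif_ball(rng, r)
    }
    if ("prongs" %in% which_points && length(out$prongs)) {
      out$prongs <- lapply(out$prongs, function(p) p + runif_ball(rng, r))
    }
    if (all(out$tip == out$shaft_point)) {
      # degenerate draw (possible only for r >= half the shaft length)
      out$shaft_point <- out$shaft_point + c(0, 0, 1e-9)
    }
    out
  })
}

# Uniform draw from the closed ball of radius r (rejection from the cube).
runif_ball <- function(rng, r) {
  if (r == 0) return(c(0, 0, 0))
  repeat {
    v <- rng$runif(3, -1, 1)
    if (sum(v^2) <= 1) return(r * v)
  }
}

#' Discrete heat-source points of a needle
#'
#' The Gaussian power deposition is centered on these points. A simple
#' needle deposits all power at its tip; an umbrella needle splits power
#' equally across the tip and the deployed prong tips (the per-prong power
#' split is not a device-published quantity; equal weights are the
#' symmetric default and can be overridden).
#'
#' @param needle an `rfa_needle`.
#' @param weights optional non-negative weights, one per source point
#'   (tip first, then prongs); normalized to sum to 1.
#' @return list with `points` (n-by-3 matrix, mm) and `weights` (sum 1).
#' @export
source_points <- function(needle, weights = NULL) {
  pts <- rbind(matrix(needle$tip, 1, 3),
               if (length(needle$prongs)) do.call(rbind, needle$prongs))
  if (is.null(weights)) weights <- rep(1, nrow(pts))
  if (length(weights) != nrow(pts) || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative, one per source point, not all zero")
  }
  list(points = pts, weights = weights / sum(weights))
}

#' Build a needle from a declarative specification
#'
#' Mirrors the YAML `needle:` config section: `model` (simple | umbrella),
#' `tip`, `shaft_point`, optional `reference_prongs`, `rotation_deg`,
#' `extension_fraction`.
#' @param spec named list or YAML file path.
#' @return an `rfa_needle`.
#' @export
needle_from_spec <- function(spec) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  model <- if (is.null(spec$model)) "umbrella" else spec$model
  if (identical(model, "simple")) {
    make_simple_needle(unlist(spec$tip), unlist(spec$shaft_point))
  } else if (identical(model, "umbrella")) {
    ref <- spec$reference_prongs
    if (!is.null(ref)) ref <- lapply(ref, unlist)
    make_umbrella_needle(
      unlist(spec$tip), unlist(spec$shaft_point), ref,
      rotation_deg = if (is.null(spec$rotation_deg)) 0 else spec$rotation_deg,
      extension_fraction = if (is.null(spec$extension_fraction)) 1
                           else spec$extension_fraction)
  } else {
    stop("unknown needle model: ", model)
  }
}
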