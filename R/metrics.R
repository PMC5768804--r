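#' Volumetric overlap metrics between two masks
#'
#' With voxel counts `a = |test|`, `b = |reference|` and
#' `i = |test intersect reference|`:
#' Dice score `DSC = 200 i / (a + b)` (%), sensitivity `SN = 100 i / b` (%),
#' positive predictive value `PPV = 100 i / a` (%), and relative volume
#' difference `RVD = 100 |a - b| / b` (%; signed variant available).
#'
#' @param test,reference `rfa_mask` objects on the same grid (e.g. the
#'   simulated lesion vs the segmented real lesion, or lesion vs tumor).
#' @param signed_rvd if `TRUE`, return the directional
#'   `100 (a - b) / b` instead of its absolute value.
#' @return named list `dsc`, `rvd`, `sensitivity`, `ppv` (percent).
#' @export
overlap_metrics <- function(test, reference, signed_rvd = FALSE) {
  if (!grid_equal(test$grid, reference$grid)) {
    stop("masks must live on the same grid")
  }
  a <- sum(test$values)
  b <- sum(reference$values)
  i <- sum(test$values & reference$values)
  if (a == 0 && b == 0) stop("both masks are empty: overlap metrics undefined")
  if (b == 0) stop("reference mask is empty: SN and RVD undefined")
  rvd <- 100 * (a - b) / b
  list(dsc = 200 * i / (a + b),
       rvd = if (signed_rvd) rvd else abs(rvd),
       sensitivity = 100 * i / b,
       ppv = if (a > 0) 100 * i / a else 0)
}

#' Symmetric surface distances between two triangulated surfaces
#'
#' Vertex-to-nearest-triangle distances in both directions; the absolute
#' average error (AAE) is the mean over the pooled distance set, min/max
#' are taken over the same pooled set. Tessellation-robust: distances go to
#' triangle interiors, not just to opposing vertices.
#'
#' @param test,reference `rfa_surface` objects, both non-empty.
#' @param one_sided if `TRUE`, use only test-vertex-to-reference-surface
#'   distances.
#' @return named list `aae`, `min_dist`, `max_dist` (mm).
#' @export
surface_distances <- function(test, reference, one_sided = FALSE) {
  if (!nrow(test$faces) || !nrow(reference$faces)) {
    stop("surface distance requires two non-empty surfaces")
  }
  d <- cpp_points_to_mesh(test$vertices, reference$vertices,
                          reference$faces - 1L)
  if (!one_sided) {
    d <- c(d, cpp_points_to_mesh(reference$vertices, test$vertices,
                                 test$faces - 1L))
  }
  list(aae = mean(d), min_dist = min(d), max_dist = max(d))
}

#' Treatment success rule
#'
#' An intervention counts as successful iff `RVD < 20` \%, `SN > 80` \% and
#' `AAE < 3` mm — all inequalities strict, so the boundary values fail.
#'
#' @param rvd relative volume difference, percent.
#' @param sensitivity sensitivity, percent.
#' @param aae absolute average surface error, mm.
#' @return logical.
#' @export
success_check <- function(rvd, sensitivity, aae) {
  rvd < 20 && sensitivity > 80 && aae < 3
}

#' Full validation report comparing two lesions
#'
#' Combines [overlap_metrics()], [surface_distances()] and
#' [success_check()] into one report.
#'
#' @param test,reference `rfa_mask` objects on a common grid.
#' @param test_surface,reference_surface optional `rfa_surface`s; derived
#'   from the masks via [mask_surface()] when omitted.
#' @return a `metrics_report` list with fields `dsc`, `rvd`, `sensitivity`,
#'   `ppv` (percent), `aae`, `min_dist`, `max_dist` (mm) and `success`.
#' @export
metrics_report <- function(test, reference, test_surface = NULL,
                           reference_surface = NULL) {
  ov <- overlap_metrics(test, reference)
  if (is.null(test_surface)) test_surface <- mask_surface(test)
  if (is.null(reference_surface)) reference_surface <- mask_surface(reference)
  sd_ <- surface_distances(test_surface, reference_surface)
  structure(c(ov, sd_,
              list(success = success_check(ov$rvd, ov$sensitivity, sd_$aae))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("metrics_report: DSC %.2f%%, RVD %.2f%%, SN %.2f%%, PPV %.2f%%, ",
           "AAE %.2f mm (min %.2f, max %.2f) -> %s\n"),
    x$dsc, x$rvd, x$sensitivity, x$ppv, x$aae, x$min_dist, x$max_dist,
    if (x$success) "SUCCESS" else "NOT successful"))
  invisible(x)
}

#' Write a metrics report as JSON
#' @param report a `metrics_report`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Safety-margin classification of lesion-surface points
#'
#' An ablation should coagulate a safety rim (typically 5 mm) of healthy
#' tissue around the tumor. Each lesion-surface point is labelled by its
#' Euclidean distance to the tumor surface: `failed` below 4.5 mm,
#' `critical` between 4.5 and 5.5 mm (boundaries inclusive — the
#' conservative choice), `safe` above 5.5 mm.
#'
#' @param points n-by-3 matrix of lesion-surface points (mm), or an
#'   `rfa_surface` whose vertices are used.
#' @param tumor a non-empty `rfa_mask` (its surface is tessellated
#'   internally) or an `rfa_surface`.
#' @param failed_below,safe_above band edges in mm (defaults 4.5 and 5.5).
#' @return data frame with columns `x, y, z, distance_mm, label`; `label`
#'   is a factor with levels `failed`, `critical`, `safe`.
#' @export
safety_margin_classify <- function(points, tumor, failed_below = 4.5,
                                   safe_above = 5.5) {
  if (inherits(points, "rfa_surface")) points <- points$vertices
  points <- as.matrix(points)
  if (inherits(tumor, "rfa_mask")) {
    if (!any(tumor$values)) stop("tumor mask is empty")
    tumor <- mask_surface(tumor)
  }
  if (!nrow(tumor$faces)) stop("tumor surface is empty")
  d <- cpp_points_to_mesh(points, tumor$vertices, tumor$faces - 1L)
  label <- ifelse(d < failed_below, "failed",
                  ifelse(d > safe_above, "safe", "critical"))
  data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
             distance_mm = d,
             label = factor(label, levels = c("failed", "critical", "safe")))
}

#' Write safety-margin labels as CSV
#' @param labels data frame from [safety_margin_classify()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_margin_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
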