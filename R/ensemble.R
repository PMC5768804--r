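#' Varied-parameter specification for ensemble sampling
#'
#' Up to two parameters can be varied simultaneously; each contributes
#' `iterations` values, and the ensemble simulates the Cartesian product of
#' the two value lists (`it_p1 * it_p2` configurations). Scalar tissue
#' parameters are sampled over `range` either on a linear grid including
#' both endpoints (a single iteration takes the midpoint) or uniformly at
#' random; `needle` variation instead draws geometries perturbed uniformly
#' within a ball of radius `r` mm.
#'
#' @param name one of `"tissue_perfusion"`, `"tumor_perfusion"`,
#'   `"heat_capacity"`, `"thermal_conductivity"`, `"needle"`.
#' @param range length-2 numeric `(low, high)` in the parameter's units
#'   (ignored for `needle`).
#' @param iterations number of values, >= 1.
#' @param sampling `"linear"` or `"random"`.
#' @param r perturbation radius, mm (needle only).
#' @param seed integer seed for random sampling / perturbation draws.
#' @return a `parameter_spec` list.
#' @export
parameter_spec <- function(name, range = NULL, iterations = 1L,
                           sampling = c("linear", "random"), r = 1,
                           seed = 1L) {
  name <- match.arg(name, c("tissue_perfusion", "tumor_perfusion",
                            "heat_capacity", "thermal_conductivity", "needle"))
  sampling <- match.arg(sampling)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (name != "needle") {
    if (is.null(range) || length(range) != 2L) {
      stop("a (low, high) range is required for parameter ", name)
    }
    if (range[1] > range[2]) stop("range must satisfy low <= high")
  } else if (r < 0) {
    stop("needle perturbation radius must be >= 0")
  }
  structure(list(name = name, range = range,
                 iterations = as.integer(iterations), sampling = sampling,
                 r = r, seed = as.integer(seed)),
            class = "parameter_spec")
}

# Value list for one parameter spec. Needle values are perturbation draw
# indices; the geometries themselves are drawn in run_ensemble.
spec_values <- function(spec) {
  n <- spec$iterations
  if (spec$name == "needle") return(seq_len(n))
  if (spec$sampling == "linear") {
    if (n == 1L) return(mean(spec$range))
    seq(spec$range[1], spec$range[2], length.out = n)
  } else {
    rng <- local_rng(spec$seed)
    rng$runif(n, spec$range[1], spec$range[2])
  }
}

#' Build the ensemble configuration list
#'
#' Cartesian product of the value lists of one or two [parameter_spec()]s:
#' `it_p1 * it_p2` configurations, each a named list of parameter values.
#'
#' @param p1 a `parameter_spec`.
#' @param p2 an optional second `parameter_spec`; must vary a different
#'   parameter than `p1`.
#' @return list of configurations; each has one entry per varied parameter.
#' @export
build_configs <- function(p1, p2 = NULL) {
  if (!is.null(p2) && identical(p1$name, p2$name)) {
    stop("the two varied parameters must differ")
  }
  v1 <- spec_values(p1)
  if (is.null(p2)) {
    return(lapply(v1, function(a) stats::setNames(list(a), p1$name)))
  }
  v2 <- spec_values(p2)
  out <- vector("list", length(v1) * length(v2))
  i <- 0L
  for (b in v2) for (a in v1) {
    i <- i + 1L
    out[[i]] <- stats::setNames(list(a, b), c(p1$name, p2$name))
  }
  out
}

# Apply one configuration's scalar overrides to the phantom property fields.
# tissue_* act on their tissue class; heat capacity and conductivity act on
# all non-vessel tissue (vessels are Dirichlet heat sinks regardless).
apply_config <- function(phantom, config) {
  for (nm in names(config)) {
    val <- config[[nm]]
    switch(nm,
      tissue_perfusion = { phantom$omega_b[phantom$label == 1L] <- val },
      tumor_perfusion = { phantom$omega_b[phantom$label == 2L] <- val },
      heat_capacity = { phantom$c[phantom$label %in% c(1L, 2L)] <- val },
      thermal_conductivity = { phantom$k[phantom$label %in% c(1L, 2L)] <- val },
      needle = NULL,
      stop("unknown ensemble parameter: ", nm))
  }
  phantom
}

#' Simulate a parameter-space ensemble
#'
#' Runs one full protocol simulation per configuration, overriding the
#' named tissue parameter(s) or substituting a perturbed needle geometry.
#' Lesion order matches configuration order, and a fixed seed makes the
#' whole ensemble bit-reproducible.
#'
#' @param phantom an `rfa_phantom`.
#' @param needle an `rfa_needle` (the unperturbed base geometry).
#' @param protocol an `rfa_protocol`.
#' @param configs configuration list from [build_configs()].
#' @param base_params a [cell_death_params()].
#' @param needle_spec the `parameter_spec` describing needle variation, if
#'   one of the configured parameters is `needle` (provides `r` and `seed`).
#' @param dt,record_every passed to [run_protocol()].
#' @return an `rfa_ensemble` with `configs` and `lesions` filled; summary
#'   fields are added by [contour_boxplot()].
#' @export
run_ensemble <- function(phantom, needle, protocol, configs,
                         base_params = cell_death_params(),
                         needle_spec = NULL, dt = 2, record_every = 1e6L) {
  if (!length(configs)) stop("at least one configuration is required")
  uses_needle <- any(vapply(configs, function(cf) "needle" %in% names(cf),
                            logical(1)))
  variants <- NULL
  if (uses_needle) {
    if (is.null(needle_spec)) {
      stop("needle variation requires the needle parameter_spec")
    }
    variants <- perturb_needle(needle, needle_spec$r,
                               n = needle_spec$iterations,
                               seed = needle_spec$seed)
  }
  lesions <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    ph <- apply_config(phantom, cf)
    ndl <- if ("needle" %in% names(cf)) variants[[cf$needle]] else needle
    res <- run_protocol(ph, ndl, protocol, base_params, dt = dt,
                        record_every = record_every)
    lesions[[i]] <- res$lesion
  }
  structure(list(configs = configs, lesions = lesions,
                 depths = NULL, median_index = NULL,
                 band50 = NULL, envelope = NULL, outlier_indices = NULL),
            class = "rfa_ensemble")
}

#' Contour band depth of a lesion ensemble
#'
#' The depth of member `c` is the fraction of unordered pairs `(i, j)` of
#' *other* members for which
#' `lesion_i intersect lesion_j  subseteq  lesion_c  subseteq  lesion_i union lesion_j`.
#' This is the 2-subset band depth of contour boxplots, applied to voxel
#' masks.
#'
#' @param lesions list of `rfa_mask` on a common grid, >= 3 members.
#' @return numeric vector of depths in `[0, 1]`, one per member.
#' @export
band_depth <- function(lesions) {
  n <- length(lesions)
  if (n < 3L) stop("band depth requires at least 3 ensemble members")
  V <- vapply(lesions, function(m) as.vector(m$values),
              logical(grid_nvox(lesions[[1]]$grid)))
  pairs <- utils::combn(n, 2)
  depths <- numeric(n)
  for (c_ in seq_len(n)) {
    vc <- V[, c_]
    keep <- pairs[1, ] != c_ & pairs[2, ] != c_
    ps <- pairs[, keep, drop = FALSE]
    cnt <- 0L
    for (p in seq_len(ncol(ps))) {
      vi <- V[, ps[1, p]]; vj <- V[, ps[2, p]]
      if (!any(vi & vj & !vc) && !any(vc & !(vi | vj))) cnt <- cnt + 1L
    }
    depths[c_] <- cnt / ncol(ps)
  }
  depths
}

#' Contour-boxplot summary of a lesion ensemble
#'
#' Condenses the ensemble into a band-depth median, a central 50% band, a
#' non-outlying envelope and a list of outliers: the median is the deepest
#' member (ties broken by lowest index), outliers are members with depth
#' below `outlier_depth_threshold`, the 50% band is the
#' intersection/union of the deeper half of the non-outlying members, and
#' the envelope the intersection/union of all non-outlying members.
#'
#' @param ensemble an `rfa_ensemble` (or plain list of `rfa_mask`).
#' @param outlier_depth_threshold depth below which a member is an outlier
#'   (default 0.1).
#' @return the `rfa_ensemble` with `depths`, `median_index`, `band50`,
#'   `envelope` and `outlier_indices` filled.
#' @export
contour_boxplot <- function(ensemble, outlier_depth_threshold = 0.1) {
  lesions <- if (inherits(ensemble, "rfa_ensemble")) ensemble$lesions
             else ensemble
  depths <- band_depth(lesions)
  keep <- which(depths >= outlier_depth_threshold)
  if (!length(keep)) {
    stop("degenerate ensemble: every member is an outlier")
  }
  median_index <- which.max(depths) # which.max takes the lowest index on ties
  ord <- keep[order(depths[keep], decreasing = TRUE)]
  top <- ord[seq_len(ceiling(length(ord) / 2))]
  band_of <- function(ids) {
    inner <- Reduce(mask_and, lesions[ids])
    outer_ <- Reduce(mask_or, lesions[ids])
    list(inner = inner, outer = outer_)
  }
  out <- if (inherits(ensemble, "rfa_ensemble")) ensemble
         else structure(list(configs = NULL, lesions = lesions),
                        class = "rfa_ensemble")
  out$depths <- depths
  out$median_index <- median_index
  out$band50 <- band_of(top)
  out$envelope <- band_of(keep)
  out$outlier_indices <- setdiff(seq_along(lesions), keep)
  out
}

#' @export
print.rfa_ensemble <- function(x, ...) {
  cat(sprintf("rfa_ensemble: %d members", length(x$lesions)))
  if (!is.null(x$depths)) {
    cat(sprintf(", median member %d (depth %.3f), %d outliers",
                x$median_index, x$depths[x$median_index],
                length(x$outlier_indices)))
  }
  cat("\n")
  invisible(x)
}

#' Write the ensemble manifest and depths as CSV
#'
#' One row per member: configuration values, band depth, outlier flag and
#' the lesion file name (as written by the `ensemble` CLI subcommand).
#' @param ensemble a summarized `rfa_ensemble`.
#' @param path output CSV path.
#' @param lesion_files optional per-member file names.
#' @return the path, invisibly.
#' @export
write_ensemble_manifest <- function(ensemble, path, lesion_files = NULL) {
  n <- length(ensemble$lesions)
  cfg <- ensemble$configs
  df <- data.frame(member = seq_len(n))
  if (!is.null(cfg)) {
    for (nm in names(cfg[[1]])) {
      df[[nm]] <- vapply(cfg, function(x) as.numeric(x[[nm]]), numeric(1))
    }
  }
  df$lesion_volume_ml <- vapply(ensemble$lesions, mask_volume_ml, numeric(1))
  if (!is.null(ensemble$depths)) {
    df$depth <- ensemble$depths
    df$outlier <- seq_len(n) %in% ensemble$outlier_indices
  }
  if (!is.null(lesion_files)) df$lesion_file <- lesion_files
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
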