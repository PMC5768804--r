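#' Rigid transform
#'
#' A proper rigid-body transform `p -> R p + t` (no scaling, no reflection).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation mm triple.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix must have determinant +1 (no reflection)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation matrix for an angle (degrees) about a direction.
#' @param axis direction triple (need not be normalized).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as.numeric(axis)
  n <- sqrt(sum(u^2))
  if (n == 0) stop("rotation axis must be non-zero")
  u <- u / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param points n-by-3 matrix or a single triple (mm).
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, ncol = 3) else as.matrix(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (single) drop(out) else out
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% transform$translation))
}

#' Least-squares rigid registration of paired landmarks
#'
#' Closed-form solution of `argmin_{R,t} sum_i ||R s_i + t - t_i||^2` over
#' proper rotations (Kabsch/Procrustes via SVD of the cross-covariance).
#' When the raw optimum would be a reflection, the sign of the smallest
#' singular vector is flipped so that `det(R) = +1` always.
#'
#' @param source_points,target_points matched n-by-3 matrices (mm), n >= 3;
#'   source points must not be collinear.
#' @return a `rigid_transform` mapping source onto target.
#' @export
fit_rigid <- function(source_points, target_points) {
  S <- as.matrix(source_points); T_ <- as.matrix(target_points)
  if (nrow(S) != nrow(T_)) stop("landmark lists must have equal length")
  if (nrow(S) < 3L) stop("rigid fit is under-determined: need >= 3 landmark pairs")
  cs <- colMeans(S); ct <- colMeans(T_)
  Sc <- sweep(S, 2, cs); Tc <- sweep(T_, 2, ct)
  sv_src <- svd(Sc, nu = 0, nv = 0)$d
  if (sv_src[2] <= 1e-9 * max(sv_src[1], 1)) {
    stop("rigid fit is under-determined: landmarks are collinear")
  }
  H <- crossprod(Sc, Tc) # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

#' Root-mean-square landmark registration residual
#'
#' @param transform a `rigid_transform`.
#' @param source_points,target_points matched n-by-3 matrices (mm), n >= 1.
#' @return RMS of `||R s_i + t - t_i||` in mm.
#' @export
registration_error <- function(transform, source_points, target_points) {
  S <- as.matrix(source_points); T_ <- as.matrix(target_points)
  if (nrow(S) == 0L || nrow(T_) == 0L) stop("no landmark pairs given")
  r <- apply_transform(transform, S) - T_
  sqrt(mean(rowSums(r^2)))
}

#' Serialize a rigid transform as JSON
#'
#' Row-major rotation plus translation, readable by [read_transform()].
#' @param transform a `rigid_transform`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(rotation_row_major = as.vector(t(transform$rotation)),
         translation = transform$translation),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation_row_major, 3, 3, byrow = TRUE),
                  x$translation)
}
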