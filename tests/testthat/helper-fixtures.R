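# Shared fixtures and independent oracles. Everything is generated in code;
# sizes are kept small so the whole suite stays desk-scale.

# Small uniform phantom: 24^3 @ 2 mm, 6 mm tumor at the center, optional
# 2.5 mm vessel passing 10 mm lateral to it.
tiny_phantom <- function(shape = c(24, 24, 24), spacing = 2, tumor_r = 6,
                         with_vessel = FALSE, properties = tissue_properties()) {
  grid <- rfa_grid(shape, spacing)
  ctr <- (grid$shape - 1) * grid$spacing / 2
  tum <- make_tumor_mask(grid, ctr, tumor_r)
  ves <- if (with_vessel) {
    make_vessel_mask(grid, ctr + c(10, 0, -100), ctr + c(10, 0, 100), 2.5)
  }
  rfa_phantom(grid, tum, ves, properties = properties)
}

grid_center <- function(grid) (grid$shape - 1) * grid$spacing / 2

# 1-based index of the voxel whose center is nearest to a world point
# (independent re-statement of the package's source-voxel lookup).
nearest_voxel_pub <- function(grid, p) round((p - grid$origin) / grid$spacing) + 1

# Short heating protocol for solver-level tests (60 s heat + 20 s cooldown).
tiny_protocol <- function(power = 30, sigma = 4) {
  rfa_protocol(list(
    protocol_phase(60, "constant_power", power_W = power),
    protocol_phase(20, "cooldown")
  ), gaussian_sigma = sigma)
}

# Brute-force voxel-center scans (independent of the mask constructors).
brute_sphere_count <- function(grid, center, radius) {
  ctr <- voxel_centers(grid)
  d <- sqrt(rowSums(sweep(ctr, 2, center)^2))
  sum(d <= radius + 1e-12)
}

brute_cylinder_membership <- function(grid, p0, p1, radius) {
  ctr <- voxel_centers(grid)
  ab <- p1 - p0
  t <- pmin(pmax((sweep(ctr, 2, p0) %*% ab) / sum(ab^2), 0), 1)
  proj <- outer(as.vector(t), ab) + matrix(p0, nrow(ctr), 3, byrow = TRUE)
  sqrt(rowSums((ctr - proj)^2)) <= radius + 1e-12
}

# Independent rigid-registration oracle: Horn's closed-form quaternion
# method (eigenvector of the 4x4 cross-covariance form) — a different
# closed form than the SVD route used by the implementation.
horn_fit <- function(S, T_) {
  cs <- colMeans(S); ct <- colMeans(T_)
  Sc <- sweep(S, 2, cs); Tc <- sweep(T_, 2, ct)
  M <- crossprod(Sc, Tc)
  N <- matrix(0, 4, 4)
  N[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  N[1, 2] <- N[2, 1] <- M[2, 3] - M[3, 2]
  N[1, 3] <- N[3, 1] <- M[3, 1] - M[1, 3]
  N[1, 4] <- N[4, 1] <- M[1, 2] - M[2, 1]
  N[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  N[2, 3] <- N[3, 2] <- M[1, 2] + M[2, 1]
  N[2, 4] <- N[4, 2] <- M[3, 1] + M[1, 3]
  N[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  N[3, 4] <- N[4, 3] <- M[2, 3] + M[3, 2]
  N[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3)
  list(R = R, t = ct - as.vector(R %*% cs))
}

random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    if (sum(q^2) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3)
}

# Nested spherical masks m1 subset ... subset m_k on a small grid.
nested_masks <- function(radii, shape = c(16, 16, 16), spacing = 1) {
  grid <- rfa_grid(shape, spacing)
  ctr <- grid_center(grid)
  lapply(radii, function(r) make_tumor_mask(grid, ctr, r))
}

random_mask <- function(grid, p = 0.3) {
  rfa_mask(grid, array(stats::runif(grid_nvox(grid)) < p, dim = grid$shape))
}

# Fine-step adaptive reference integration of the three-state kinetics at
# constant temperature (independent of the package's RK4 stepper).
ode_oracle <- function(T_c, t_end, params = cell_death_params(),
                       y0 = c(A = 0.99, V = 0.01, D = 0)) {
  rhs <- function(t, y, p) {
    k_f <- p$k_f_bar * exp(T_c / p$T_k) * (1 - y[1])
    list(c(-k_f * y[1] + p$k_b * y[2],
           k_f * y[1] - p$k_b * y[2] - k_f * y[2],
           k_f * y[2]))
  }
  out <- deSolve::ode(y0, c(0, t_end), rhs, params, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  out[nrow(out), c("A", "V", "D")]
}
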