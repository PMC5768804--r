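test_that("gaussian power deposition integrates to the delivered power", {
  ph <- tiny_phantom()
  src <- c(22, 22, 22) # exactly a voxel center of the 2 mm lattice
  ndl <- make_simple_needle(src, src + c(0, 0, 30))
  sp <- source_points(ndl)

  zero <- gaussian_power(ph$grid, sp, 0, 3, ph$liver_roi)
  expect_true(all(zero$q == 0))

  pw <- gaussian_power(ph$grid, sp, 25, 3, ph$liver_roi)
  expect_true(all(pw$q >= 0))
  expect_equal(sum(pw$q) * voxel_volume_m3(ph$grid), 25, tolerance = 1e-9)

  # maximal at the source voxel and mirror-symmetric about it
  imax <- arrayInd(which.max(pw$q), ph$grid$shape)
  expect_equal(as.vector(imax), as.vector(nearest_voxel_pub(ph$grid, src)))
  i0 <- imax[1]
  expect_equal(pw$q[i0 + 3, imax[2], imax[3]], pw$q[i0 - 3, imax[2], imax[3]],
               tolerance = 1e-9)
  expect_equal(pw$q[i0, imax[2] + 4, imax[3]], pw$q[i0, imax[2], imax[3] + 4],
               tolerance = 1e-9)

  # all sources outside the ROI is an error
  far <- make_simple_needle(c(500, 0, 0), c(500, 0, 30))
  expect_error(gaussian_power(ph$grid, source_points(far), 10, 3, ph$liver_roi),
               "ROI")
})

test_that("two-source deposition equals direct kernel summation at probes", {
  ph <- tiny_phantom()
  grid <- ph$grid
  ctr <- grid_center(grid)
  s1 <- ctr + c(-5, 0, 0); s2 <- ctr + c(6, 2, -3)
  sp <- list(points = rbind(s1, s2), weights = c(0.5, 0.5))
  sigma <- 3; P <- 40
  pw <- gaussian_power(grid, sp, P, sigma, ph$liver_roi)

  # independent dense computation from raw voxel-center distances
  ctrs <- voxel_centers(grid)
  raw <- 0.5 * exp(-rowSums(sweep(ctrs, 2, s1)^2) / (2 * sigma^2)) +
         0.5 * exp(-rowSums(sweep(ctrs, 2, s2)^2) / (2 * sigma^2))
  raw[!as.vector(ph$liver_roi$values)] <- 0
  qref <- P * raw / (sum(raw) * voxel_volume_m3(grid))

  set.seed(2)
  probes <- sample(grid_nvox(grid), 10)
  expect_equal(as.vector(pw$q)[probes], qref[probes], tolerance = 1e-9)
})

test_that("body temperature with no source is a fixed point of both schemes", {
  ph <- tiny_phantom(with_vessel = TRUE)
  for (m in c("implicit", "explicit")) {
    st <- thermo_state(ph)
    for (i in 1:5) st <- step_temperature(st, 2, ph, NULL, method = m)
    expect_equal(max(abs(st$T - ph$T_b)), 0, tolerance = 1e-9)
  }
})

test_that("steady conduction between fixed ends is linear", {
  # 1D rod: ends outside the ROI act as Dirichlet plates at 37 and 47 degC
  grid <- rfa_grid(c(41, 1, 1), 1)
  roi <- array(TRUE, dim = grid$shape); roi[1, 1, 1] <- roi[41, 1, 1] <- FALSE
  props <- tissue_properties(healthy = list(omega_b = 0))
  ph <- rfa_phantom(grid, rfa_mask(grid, FALSE), liver_roi = rfa_mask(grid, roi),
                    properties = props)
  T0 <- array(37, dim = grid$shape); T0[41, 1, 1] <- 47
  st <- thermo_state(ph, T = T0)
  for (i in 1:30) st <- step_temperature(st, 1e6, ph, NULL, method = "implicit")
  expect_equal(st$T[21, 1, 1], 42, tolerance = 1e-6)
  profile <- st$T[, 1, 1]
  expect_equal(profile, seq(37, 47, length.out = 41), tolerance = 1e-6)
})

test_that("the explicit scheme rejects unstable steps and names the bound", {
  ph <- tiny_phantom()
  st <- thermo_state(ph)
  expect_error(step_temperature(st, 1000, ph, NULL, method = "explicit"),
               "stability bound")
})

test_that("heating respects the discrete maximum principle and vessel sinks", {
  ph <- tiny_phantom(with_vessel = TRUE)
  ndl <- default_needle(ph)
  res <- run_protocol(ph, ndl, tiny_protocol(), dt = 2)
  expect_gte(min(res$state$T), ph$T_b - 1e-9)
  # Dirichlet vessel voxels stay exactly at blood temperature
  expect_true(all(res$state$T[ph$vessels$values] == ph$T_b))
  expect_gt(max(res$state$T), 60)
})

test_that("the power controller implements the stated law", {
  heat <- protocol_phase(60, "temperature_controlled", power_W = 40,
                         target_temp_C = 90)
  cool <- protocol_phase(30, "cooldown")
  expect_equal(control_power(cool, 120), 0)
  expect_equal(control_power(heat, 20), 40)          # far below target
  expect_equal(control_power(heat, 95, band = 5), 0) # target + band
  expect_equal(control_power(heat, 92.5, band = 5), 20)
  expect_equal(control_power(protocol_phase(5, "constant_power", 33), 150), 33)
  expect_error(protocol_phase(10, "cooldown", power_W = 5), "cooldown")
})

test_that("protocols keep time and reduce to equilibrium without power", {
  ph <- tiny_phantom()
  ndl <- default_needle(ph)
  prot <- rfa_protocol(list(protocol_phase(60, "constant_power", 30),
                            protocol_phase(30, "cooldown")))
  res <- run_protocol(ph, ndl, prot, dt = 2)
  expect_equal(res$state$time, 90)

  off <- rfa_protocol(list(protocol_phase(60, "constant_power", 0)))
  res0 <- run_protocol(ph, ndl, off, dt = 2)
  expect_equal(max(abs(res0$state$T - ph$T_b)), 0, tolerance = 1e-9)
  expect_false(any(res0$lesion$values))
})

test_that("chained cycles equal one run with the concatenated phase list", {
  ph <- tiny_phantom()
  ndl <- default_needle(ph)
  ph1 <- protocol_phase(40, "constant_power", 30)
  ph2 <- protocol_phase(20, "cooldown")
  full <- run_protocol(ph, ndl, rfa_protocol(list(ph1, ph2)), dt = 2)
  c1 <- run_protocol(ph, ndl, rfa_protocol(list(ph1)), dt = 2)
  c2 <- run_protocol(ph, ndl, rfa_protocol(list(ph2)), dt = 2, init = c1)
  expect_equal(c2$state$time, full$state$time)
  expect_equal(max(abs(c2$state$T - full$state$T)), 0, tolerance = 1e-9)
  expect_equal(max(abs(c2$state$D - full$state$D)), 0, tolerance = 1e-9)
  expect_identical(c2$lesion$values, full$lesion$values)
})

test_that("implicit and explicit schemes agree at small dt", {
  ph <- tiny_phantom()
  ndl <- default_needle(ph)
  sp <- source_points(ndl)
  pw <- gaussian_power(ph$grid, sp, 30, 4, ph$liver_roi)
  sti <- thermo_state(ph); ste <- thermo_state(ph)
  for (i in 1:40) {
    sti <- step_temperature(sti, 0.5, ph, pw, method = "implicit")
    ste <- step_temperature(ste, 0.5, ph, pw, method = "explicit")
  }
  expect_lt(max(abs(sti$T - ste$T)) / max(ste$T - ph$T_b), 0.02)
})

test_that("halving the grid spacing moves the final peak by < 2%", {
  run_case <- function(shape, spacing) {
    grid <- rfa_grid(shape, spacing)
    ctr <- grid_center(grid)
    ph <- rfa_phantom(grid, make_tumor_mask(grid, ctr, 5))
    ndl <- make_simple_needle(ctr, ctr + c(0, 0, 200))
    prot <- rfa_protocol(list(protocol_phase(60, "constant_power", 20)),
                         gaussian_sigma = 6)
    max(run_protocol(ph, ndl, prot, dt = 1)$state$T)
  }
  coarse <- run_case(c(17, 17, 17), 4) # 64 mm box, 4 mm voxels
  fine <- run_case(c(33, 33, 33), 2)   # same box, 2 mm voxels
  expect_lt(abs(fine - coarse) / (fine - 37), 0.02)
})
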