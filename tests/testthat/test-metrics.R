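test_that("overlap metrics match brute-force voxel counting", {
  grid <- rfa_grid(c(20, 20, 20), 1)

  cube <- function(lo, hi) {
    v <- array(FALSE, grid$shape)
    v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    rfa_mask(grid, v)
  }

  a <- cube(c(1, 1, 1), c(10, 10, 10))
  m <- overlap_metrics(a, a)
  expect_equal(m$dsc, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$ppv, 100)
  expect_equal(m$rvd, 0)

  b <- cube(c(11, 11, 11), c(20, 20, 20))
  md <- overlap_metrics(a, b)
  expect_equal(md$dsc, 0)
  expect_equal(md$sensitivity, 0)
  expect_equal(md$ppv, 0)

  # 10-cube against itself shifted 5 voxels along x: i = 500
  shifted <- cube(c(6, 1, 1), c(15, 10, 10))
  ms <- overlap_metrics(shifted, a)
  expect_equal(sum(shifted$values & a$values), 500L)
  expect_equal(ms$dsc, 50)
  expect_equal(ms$sensitivity, 50)
  expect_equal(ms$ppv, 50)
  expect_equal(ms$rvd, 0)

  empty <- rfa_mask(grid, FALSE)
  expect_error(overlap_metrics(empty, empty), "undefined")
  expect_error(overlap_metrics(a, empty), "reference")

  # directional RVD option
  small <- cube(c(1, 1, 1), c(5, 10, 10))
  expect_equal(overlap_metrics(small, a, signed_rvd = TRUE)$rvd, -50)
  expect_equal(overlap_metrics(small, a)$rvd, 50)
})

test_that("overlap metrics verify their identities on random masks", {
  grid <- rfa_grid(c(12, 12, 12), 1)
  set.seed(23)
  for (i in 1:20) {
    A <- random_mask(grid, runif(1, 0.2, 0.7))
    B <- random_mask(grid, runif(1, 0.2, 0.7))
    if (!any(A$values) || !any(B$values)) next
    mab <- overlap_metrics(A, B)
    mba <- overlap_metrics(B, A)
    # SN(A,B) = PPV(B,A) duality
    expect_equal(mab$sensitivity, mba$ppv)
    expect_equal(mab$ppv, mba$sensitivity)
    # DSC against independent brute-force counts
    va <- as.vector(A$values); vb <- as.vector(B$values)
    expect_equal(mab$dsc, 200 * sum(va & vb) / (sum(va) + sum(vb)))
    expect_equal(mab$dsc, mba$dsc)
  }
})

test_that("overlap metrics are invariant under joint translation", {
  grid <- rfa_grid(c(20, 20, 20), 1)
  ctr <- grid_center(grid)
  A <- make_tumor_mask(grid, ctr + c(-2, 0, 0), 4)
  B <- make_tumor_mask(grid, ctr + c(1, 1, 0), 3)
  At <- make_tumor_mask(grid, ctr + c(-2, 0, 0) + c(3, -2, 4), 4)
  Bt <- make_tumor_mask(grid, ctr + c(1, 1, 0) + c(3, -2, 4), 3)
  expect_equal(overlap_metrics(A, B), overlap_metrics(At, Bt))
})

test_that("surface distances recover the concentric-sphere offset", {
  grid <- rfa_grid(c(36, 36, 36), 1)
  ctr <- grid_center(grid)
  d <- sqrt(rowSums(sweep(voxel_centers(grid), 2, ctr)^2))
  field <- array(-d, grid$shape) # smooth radial field, iso at -r
  s10 <- iso_surface(field, grid, -10)
  s12 <- iso_surface(field, grid, -12)

  same <- surface_distances(s10, s10)
  expect_equal(same$aae, 0, tolerance = 1e-12)
  expect_equal(same$max_dist, 0, tolerance = 1e-12)

  both <- surface_distances(s10, s12)
  expect_equal(both$aae, 2, tolerance = 0.04)

  # symmetry of the pooled definition
  expect_equal(surface_distances(s12, s10), both)

  one <- surface_distances(s10, s12, one_sided = TRUE)
  expect_equal(one$aae, 2, tolerance = 0.04)

  empty <- rfa_surface(matrix(0, 0, 3), matrix(0L, 0, 3))
  expect_error(surface_distances(empty, s10), "non-empty")
})

test_that("the success rule applies strict inequalities at 20/80/3", {
  expect_true(success_check(19.0, 81.0, 2.9))
  expect_false(success_check(20.0, 81.0, 2.9)) # RVD boundary excluded
  expect_false(success_check(19.0, 80.0, 2.9)) # SN boundary excluded
  expect_false(success_check(19.0, 81.0, 3.0)) # AAE boundary excluded
  expect_true(success_check(0, 100, 0))
  expect_false(success_check(45, 95, 1))
  expect_false(success_check(5, 60, 1))
  expect_false(success_check(5, 95, 8))
})

test_that("safety-margin labels follow the 4.5/5.5 mm bands", {
  grid <- rfa_grid(c(30, 30, 30), 1)
  ctr <- grid_center(grid)
  tumor <- make_tumor_mask(grid, ctr, 6)

  # synthetic probe points at controlled distances from the tumor surface
  dists <- c(3, 5, 6)
  pts <- t(vapply(dists, function(dd) ctr + c(6 + dd, 0, 0), numeric(3)))
  lab <- safety_margin_classify(pts, tumor)
  expect_equal(as.character(lab$label), c("failed", "critical", "safe"))

  # the labels partition every point (none unlabeled)
  sweep_pts <- cbind(ctr[1] + 6 + seq(0.5, 9.5, by = 0.5), ctr[2], ctr[3])
  lab2 <- safety_margin_classify(sweep_pts, tumor)
  expect_false(any(is.na(lab2$label)))

  # translated lesion surface agrees with a brute-force distance transform
  lesion <- make_tumor_mask(grid, ctr + c(2, 0, 0), 9)
  surf <- mask_surface(lesion)
  lab3 <- safety_margin_classify(surf, tumor)
  tum_pts <- voxel_centers(grid)[as.vector(tumor$values), , drop = FALSE]
  brute <- vapply(seq_len(nrow(surf$vertices)), function(i) {
    min(sqrt(rowSums(sweep(tum_pts, 2, surf$vertices[i, ])^2)))
  }, numeric(1))
  # voxel-center distances overestimate surface distances by <= half the
  # voxel diagonal; labels from both routes agree away from band edges
  expect_lt(max(abs(lab3$distance_mm - brute)), sqrt(3) / 2 + 0.3)
  interior <- abs(lab3$distance_mm - 4.5) > 1 & abs(lab3$distance_mm - 5.5) > 1
  brute_lab <- ifelse(brute - sqrt(3) / 2 < 4.5, "failed",
                      ifelse(brute - sqrt(3) / 2 > 5.5, "safe", "critical"))
  agree <- as.character(lab3$label[interior]) == brute_lab[interior]
  expect_gt(mean(agree), 0.95)

  expect_error(safety_margin_classify(pts, rfa_mask(grid, FALSE)), "empty")
})

test_that("metrics reports combine overlap, distance and the success rule", {
  grid <- rfa_grid(c(30, 30, 30), 1)
  ctr <- grid_center(grid)
  lesion <- make_tumor_mask(grid, ctr, 8)
  tumor <- make_tumor_mask(grid, ctr, 6)
  rep_ <- metrics_report(lesion, tumor)
  expect_equal(rep_$sensitivity, 100)
  expect_lt(rep_$ppv, 100)
  expect_gt(rep_$aae, 1)
  expect_lte(rep_$min_dist, rep_$aae)
  expect_gte(rep_$max_dist, rep_$aae)
  expect_type(rep_$success, "logical")

  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$dsc, rep_$dsc, tolerance = 1e-12)
})
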