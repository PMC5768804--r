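test_that("configuration lists are the Cartesian product of value lists", {
  p1 <- parameter_spec("tissue_perfusion", c(0.5, 4), iterations = 5)
  p2 <- parameter_spec("tumor_perfusion", c(0.2, 1), iterations = 5)
  cfgs <- build_configs(p1, p2)
  expect_length(cfgs, 25L)
  expect_length(unique(vapply(cfgs, function(x)
    paste(unlist(x), collapse = "/"), character(1))), 25L)

  single <- build_configs(parameter_spec("heat_capacity", c(3000, 4000), 1))
  expect_length(single, 1L)
  expect_equal(single[[1]]$heat_capacity, 3500) # n = 1 takes the midpoint

  lin <- build_configs(parameter_spec("thermal_conductivity", c(1, 3), 5))
  expect_equal(vapply(lin, `[[`, numeric(1), "thermal_conductivity"),
               c(1, 1.5, 2, 2.5, 3))

  expect_error(build_configs(p1, parameter_spec("tissue_perfusion", c(0, 1), 2)),
               "differ")

  # property: |configs| = it_p1 * it_p2 for random iteration counts
  set.seed(8)
  for (i in 1:12) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    a <- parameter_spec("tissue_perfusion", c(0.5, 4), n1,
                        sampling = sample(c("linear", "random"), 1), seed = i)
    b <- parameter_spec("needle", iterations = n2, r = 1.5, seed = i)
    expect_length(build_configs(a, b), n1 * n2)
  }
})

test_that("random sampling stays in range and is seed-stable", {
  sp <- parameter_spec("tissue_perfusion", c(1, 2), 20, sampling = "random",
                       seed = 5)
  v1 <- vapply(build_configs(sp), `[[`, numeric(1), "tissue_perfusion")
  v2 <- vapply(build_configs(sp), `[[`, numeric(1), "tissue_perfusion")
  expect_identical(v1, v2)
  expect_true(all(v1 >= 1 & v1 <= 2))
  expect_gt(length(unique(v1)), 15)
})

ensemble_fixture <- function() {
  ph <- tiny_phantom(shape = c(20, 20, 20), spacing = 2, tumor_r = 5)
  ndl <- default_needle(ph, prong_length = 10)
  prot <- rfa_protocol(list(protocol_phase(240, "constant_power", 30)),
                       gaussian_sigma = 5)
  list(ph = ph, ndl = ndl, prot = prot)
}

test_that("single and degenerate ensembles reduce to direct simulation", {
  fx <- ensemble_fixture()
  base <- cell_death_params()

  # a config matching the base parameters reproduces run_protocol exactly
  cfg <- list(list(tissue_perfusion = fx$ph$properties$healthy$omega_b))
  ens <- run_ensemble(fx$ph, fx$ndl, fx$prot, cfg, base, dt = 2)
  direct <- run_protocol(fx$ph, fx$ndl, fx$prot, base, dt = 2)
  expect_identical(ens$lesions[[1]]$values, direct$lesion$values)

  # zero-width ranges give identical members
  sp <- parameter_spec("tumor_perfusion", c(0.6, 0.6), 3)
  ens3 <- run_ensemble(fx$ph, fx$ndl, fx$prot, build_configs(sp), base, dt = 2)
  expect_identical(ens3$lesions[[1]]$values, ens3$lesions[[2]]$values)
  expect_identical(ens3$lesions[[1]]$values, ens3$lesions[[3]]$values)
})

test_that("raising tissue perfusion monotonically shrinks the lesion", {
  fx <- ensemble_fixture()
  sp <- parameter_spec("tissue_perfusion", c(0.5, 6), 3)
  ens <- run_ensemble(fx$ph, fx$ndl, fx$prot, build_configs(sp), dt = 2)
  vols <- vapply(ens$lesions, function(m) sum(m$values), integer(1))
  expect_gt(vols[1], 0)
  expect_true(all(diff(vols) <= 0))
  expect_lt(vols[3], vols[1])
})

test_that("ensembles are bit-reproducible under a fixed master seed", {
  fx <- ensemble_fixture()
  sp <- parameter_spec("needle", iterations = 3, r = 2, seed = 77)
  run <- function() {
    ens <- run_ensemble(fx$ph, fx$ndl, fx$prot, build_configs(sp),
                        needle_spec = sp, dt = 2)
    lapply(ens$lesions, `[[`, "values")
  }
  expect_identical(run(), run())
})

test_that("band depth equals brute-force pair enumeration", {
  # nested masks: the middle of 5 attains 4/6, the extremes 0
  masks <- nested_masks(c(2, 3.5, 5, 6.5, 8))
  d <- band_depth(masks)
  expect_equal(d[3], 4 / 6)
  expect_equal(d[1], 0)
  expect_equal(d[5], 0)
  expect_equal(which.max(d), 3L)

  # identical members all have depth 1
  same <- nested_masks(c(4, 4, 4))
  expect_equal(band_depth(same), c(1, 1, 1))

  # random ensembles vs an independent enumeration
  grid <- rfa_grid(c(8, 8, 8), 1)
  brute_depth <- function(V) {
    n <- ncol(V)
    vapply(seq_len(n), function(c_) {
      others <- setdiff(seq_len(n), c_)
      hits <- 0L; tot <- 0L
      for (i in others) for (j in others) {
        if (i < j) {
          tot <- tot + 1L
          inter <- V[, i] & V[, j]; uni <- V[, i] | V[, j]
          if (all(inter <= V[, c_]) && all(V[, c_] <= uni)) hits <- hits + 1L
        }
      }
      hits / tot
    }, numeric(1))
  }
  set.seed(31)
  for (trial in 1:5) {
    n <- sample(3:8, 1)
    masks <- replicate(n, random_mask(grid, p = runif(1, 0.2, 0.6)),
                       simplify = FALSE)
    V <- vapply(masks, function(m) as.vector(m$values), logical(512))
    expect_equal(band_depth(masks), brute_depth(V))
  }

  # permutation invariance
  masks5 <- nested_masks(c(2, 3.5, 5, 6.5, 8))
  perm <- c(4, 1, 5, 3, 2)
  expect_equal(band_depth(masks5[perm]), band_depth(masks5)[perm])

  expect_error(band_depth(masks5[1:2]), "3")
})

test_that("contour boxplots pick the deepest member and nest their bands", {
  masks <- nested_masks(c(2, 3.5, 5, 6.5, 8))
  bp <- contour_boxplot(masks, outlier_depth_threshold = 0.05)
  expect_identical(bp$median_index, 3L)

  samegrid <- nested_masks(c(4, 4, 4, 4))
  bps <- contour_boxplot(samegrid)
  expect_identical(bps$median_index, 1L) # tie broken by lowest index
  expect_identical(bps$band50$inner$values, samegrid[[1]]$values)
  expect_identical(bps$envelope$outer$values, samegrid[[1]]$values)
  expect_length(bps$outlier_indices, 0L)

  # inclusion chain: band50 inner <= median <= band50 outer <= envelope outer
  set.seed(12)
  grid <- rfa_grid(c(10, 10, 10), 1)
  ms <- lapply(1:6, function(i)
    make_tumor_mask(grid, grid_center(grid) + runif(3, -1, 1), runif(1, 2, 4)))
  bp2 <- contour_boxplot(ms, outlier_depth_threshold = 0)
  med <- ms[[bp2$median_index]]
  expect_true(mask_subset(bp2$band50$inner, med))
  expect_true(mask_subset(med, bp2$band50$outer))
  expect_true(mask_subset(bp2$band50$outer, bp2$envelope$outer))
  expect_true(mask_subset(bp2$envelope$inner, bp2$band50$inner))

  expect_error(contour_boxplot(masks, outlier_depth_threshold = 2),
               "degenerate")
})
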