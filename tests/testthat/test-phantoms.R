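test_that("the modified-Gaussian profile is pinned at centre and surface", {
  expect_equal(gaussian_sphere_profile(0, R = 12, r_max = 30), 40)
  expect_equal(gaussian_sphere_profile(30, R = 12, r_max = 30), 2)
  expect_equal(gaussian_sphere_profile(31, R = 12, r_max = 30), 0)
  # R = 0: homogeneous baseline at the surface value
  expect_equal(gaussian_sphere_profile(c(0, 10, 30), R = 0, r_max = 30),
               rep(2, 3))
  # decreasing inside the sphere (the far tail of a narrow Gaussian ties at
  # machine precision, so the assertion is non-strict there)
  d <- seq(0, 30, by = 0.5)
  for (R in c(4, 8, 12, 30)) {
    dd <- diff(gaussian_sphere_profile(d, R, 30))
    expect_true(all(dd <= 0))
    expect_lt(dd[1], 0)
  }
})

test_that("phantom volumes are deterministic, bounded and spherically symmetric", {
  spec <- phantom_spec("single_sphere", R = 8, r_max = 12, grid_shape = rep(27L, 3))
  v1 <- build_phantom(spec)
  v2 <- build_phantom(spec)
  expect_identical(unclass(v1), unclass(v2))
  expect_true(all(v1 >= 0 & v1 <= 40))
  # SUV depends only on distance to the centre: sample a shell
  ci <- 14L  # 1-based index of the centre voxel (odd 27-grid, 0-based centre 13)
  shell <- rbind(c(ci + 5, ci, ci), c(ci - 5, ci, ci), c(ci, ci + 5, ci),
                 c(ci, ci - 5, ci), c(ci, ci, ci + 5), c(ci, ci, ci - 5),
                 c(ci + 3, ci + 4, ci), c(ci, ci + 3, ci - 4))
  vals <- unclass(v1)[shell]
  expect_true(max(vals) - min(vals) < 1e-12)
  expect_equal(unclass(v1)[ci, ci, ci], 40)
})

test_that("the SUV-weighted centroid of a single sphere sits at the construction centre", {
  ph <- small_sphere(R = 10, r_max = 14, n = 31L)
  cc <- suv_centroid(ph$volume, ph$mask)
  expect_equal(cc, rep(15, 3), tolerance = 1e-6)
})

test_that("sub-sphere phantoms blend continuously and reject invalid geometry", {
  spec <- phantom_spec("multi_sphere_N", N = 2, r_s = 4, D = 8, r_max = 15,
                       grid_shape = rep(33L, 3))
  v <- build_phantom(spec)
  expect_true(all(v >= 0 & v <= 40))
  # small-sphere centres peak at suv_max; host centre keeps its host value
  c0 <- (33 - 1) / 2
  expect_equal(unclass(v)[c0 + 1 + 8, c0 + 1, c0 + 1], 40)
  expect_equal(unclass(v)[c0 + 1 - 8, c0 + 1, c0 + 1], 40)
  # just outside the sub-sphere the host profile is untouched
  host <- build_phantom(phantom_spec("single_sphere", R = 15, r_max = 15,
                                     grid_shape = rep(33L, 3)))
  outside <- unclass(v)[c0 + 1, c0 + 1 + 14, c0 + 1]
  expect_equal(outside, unclass(host)[c0 + 1, c0 + 1 + 14, c0 + 1])
  # geometry violations
  expect_error(phantom_spec("two_sphere_D", r_s = 6, D = 28, r_max = 30),
               class = "het_validation_error")
  expect_error(phantom_spec("single_sphere", R = 8, r_max = 30,
                            grid_shape = rep(40L, 3)),
               class = "het_validation_error")
  expect_error(build_phantom(phantom_spec("multi_sphere_N", N = 4, r_s = 10,
                                          D = 12, r_max = 30,
                                          grid_shape = rep(70L, 3))),
               class = "het_validation_error")
})

test_that("2D patterns satisfy their stated constraints", {
  pa <- build_pattern2d(1)
  pb <- build_pattern2d(2)
  expect_equal(mean(pa), 5)
  expect_equal(mean(pb), 5)
  m <- tumor_mask(array(TRUE, dim = dim(unclass(pa))))
  # pattern 2 is strictly more heterogeneous in mean absolute neighbour
  # difference and in |H|
  mad_of <- function(v) {
    ns <- hetindex:::neighbor_sums(unclass(v), m)
    mean((ns$sum_abs / pmax(ns$n, 1))[unclass(m)])
  }
  expect_gt(mad_of(pb), mad_of(pa))
  expect_gt(abs(h_index(pb, m)$h), abs(h_index(pa, m)$h))
  # the ascending-rim pattern carries a negative H
  expect_lt(h_index(build_pattern2d(6), m)$h, 0)
  expect_error(build_pattern2d(7), class = "het_validation_error")
})
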