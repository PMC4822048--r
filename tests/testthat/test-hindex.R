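test_that("the SUV-weighted centroid matches hand values and symmetry", {
  v <- suv_volume(array(c(1, 3), dim = c(2, 1, 1)))
  m <- tumor_mask(array(TRUE, dim = c(2, 1, 1)))
  expect_equal(suv_centroid(v, m), c(0.75, 0, 0))
  # constant SUV: centroid is the unweighted geometric centroid
  set.seed(11)
  msk <- array(runif(5^3) < 0.5, dim = c(5, 5, 5)); msk[3, 3, 3] <- TRUE
  cm <- suv_centroid(suv_volume(array(2, c(5, 5, 5))), tumor_mask(msk))
  expect_equal(cm, colMeans(arrayInd(which(msk), dim(msk)) - 1))
  # symmetric sphere phantom: centroid at the construction centre
  ph <- small_sphere()
  cc <- suv_centroid(ph$volume, ph$mask)
  expect_equal(cc, rep((33 - 1) / 2, 3), tolerance = 1e-6)
  # error cases
  expect_error(suv_centroid(v, tumor_mask(array(FALSE, c(2, 1, 1)))),
               class = "het_validation_error")
  z <- suv_volume(array(0, c(2, 1, 1)))
  expect_error(suv_centroid(z, m), class = "het_validation_error")
})

test_that("centroid distances and peripheral weights follow d_i / d_max", {
  v <- suv_volume(array(1, dim = c(3, 1, 1)))
  m <- tumor_mask(array(TRUE, dim = c(3, 1, 1)))
  dw <- distance_weights(v, m, c(1, 0, 0))
  expect_equal(dw$d, c(1, 0, 1))
  expect_equal(dw$d_max, 1)
  expect_equal(dw$w, c(1, 0, 1))
  # degenerate single voxel
  m1 <- array(FALSE, c(3, 1, 1)); m1[2, 1, 1] <- TRUE
  dw1 <- distance_weights(v, tumor_mask(m1), c(1, 0, 0))
  expect_equal(dw1$d_max, 0)
  expect_equal(dw1$w, 0)
  # full cube, uniform SUV: d_max is the corner-to-centre distance,
  # cross-checked by brute-force maximum over the 27 voxels
  v3 <- suv_volume(array(2, c(3, 3, 3)))
  m3 <- tumor_mask(array(TRUE, c(3, 3, 3)))
  cc <- suv_centroid(v3, m3)
  dw3 <- distance_weights(v3, m3, cc)
  pos <- arrayInd(1:27, c(3, 3, 3)) - 1
  expect_equal(dw3$d_max, max(sqrt(rowSums(sweep(pos, 2, cc, `-`)^2))))
  expect_equal(dw3$d_max, sqrt(3))
  expect_true(all(dw3$w >= 0 & dw3$w <= 1))
})

test_that("the sign rule separates descending, ascending and constant profiles", {
  ph <- small_sphere()
  expect_equal(h_index(ph$volume, ph$mask)$sign, 1)
  # invert the in-mask profile about its mid-value: ascending centre->rim
  vals <- unclass(ph$volume)
  inm <- unclass(ph$mask)
  vals[inm] <- max(vals[inm]) + min(vals[inm]) - vals[inm]
  expect_equal(h_index(suv_volume(vals), ph$mask)$sign, -1)
  # constant tumor takes the tie (+) branch
  const <- suv_volume(array(3, dim = c(4, 4, 4)))
  expect_equal(h_index(const, tumor_mask(array(TRUE, c(4, 4, 4))))$sign, 1)
})

test_that("h_index reproduces the hand-worked 3-voxel example", {
  v <- suv_volume(array(c(4, 2, 4), dim = c(3, 1, 1)))
  m <- tumor_mask(array(TRUE, dim = c(3, 1, 1)))
  h <- h_index(v, m, suv_th = 2.5)
  expect_equal(h$centroid, c(1, 0, 0))
  expect_equal(h$magnitude, (0.8 + 0 + 0.8) / 3)
  expect_equal(h$sign, -1)            # whole mean 10/3 > inner mean 2
  expect_equal(h$h, -1.6 / 3)
  expect_equal(h$h, oracle_h(v, m))
})

test_that("H is zero for homogeneous or single-voxel tumors and errors on empty masks", {
  v <- suv_volume(array(5, dim = c(4, 4, 4)))
  m <- tumor_mask(array(TRUE, c(4, 4, 4)))
  expect_equal(h_index(v, m)$h, 0)
  m1 <- array(FALSE, c(4, 4, 4)); m1[2, 3, 1] <- TRUE
  expect_equal(h_index(v, tumor_mask(m1))$h, 0)
  expect_error(h_index(v, tumor_mask(array(FALSE, c(4, 4, 4)))),
               class = "het_validation_error")
  expect_error(h_index(v, m, suv_th = 0), class = "het_validation_error")
  expect_error(h_index(v, m, inner_fraction = 1), class = "het_validation_error")
})

test_that("h_index matches the brute-force oracle on random grids", {
  set.seed(101)
  for (rep in 1:20) {
    case <- random_case()
    h <- h_index(case$volume, case$mask)
    ref <- oracle_h(case$volume, case$mask)
    expect_equal(h$h, ref, tolerance = 1e-10)
  }
})

test_that("|H| is invariant under grid flips and axis permutations", {
  ph <- small_sphere(R = 6, r_max = 10, n = 25L)
  # make it asymmetric so the test is not vacuous
  vals <- unclass(ph$volume)
  vals[1:12, , ] <- vals[1:12, , ] * 1.5
  v <- suv_volume(vals); m <- ph$mask
  h0 <- abs(h_index(v, m)$h)
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  hf <- h_index(suv_volume(array(flip(vals), dim(vals))),
                tumor_mask(array(flip(unclass(m)), dim(vals))))
  expect_equal(abs(hf$h), h0, tolerance = 1e-12)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    hp <- h_index(suv_volume(aperm(vals, perm)),
                  tumor_mask(aperm(unclass(m), perm)))
    expect_equal(abs(hp$h), h0, tolerance = 1e-12)
  }
})

test_that("|H| is linear in SUV scale and shift-invariant on a symmetric phantom", {
  ph <- small_sphere()
  h0 <- h_index(ph$volume, ph$mask)
  for (a in c(0.5, 2, 7)) {
    ha <- h_index(suv_volume(unclass(ph$volume) * a), ph$mask)
    expect_equal(ha$magnitude, a * h0$magnitude, tolerance = 1e-12)
  }
  # centroid pinned at the centre by symmetry, so an additive shift leaves
  # weights and differences (hence |H|) unchanged
  for (cshift in c(1, 10)) {
    hc <- h_index(suv_volume(unclass(ph$volume) + cshift), ph$mask)
    expect_equal(hc$magnitude, h0$magnitude, tolerance = 1e-10)
  }
})
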