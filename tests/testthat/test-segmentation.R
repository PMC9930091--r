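test_that("region growing floods a uniform image and respects tolerance", {
  img <- array(1, dim = c(6, 6, 6))
  grown <- region_grow(img, c(3, 3, 3), tolerance = 0.1)
  expect_true(all(grown))

  sp <- sphere_image()
  grown <- region_grow(sp$image, sp$center, tolerance = 0.1)
  expect_identical(as.vector(grown), as.vector(sp$truth))
})

test_that("region growing is deterministic and monotone in tolerance", {
  sp <- sphere_image()
  set.seed(5)
  noisy <- sp$image + array(rnorm(length(sp$image), 0, 0.05),
                            dim = dim(sp$image))
  a <- region_grow(noisy, sp$center, tolerance = 0.15)
  b <- region_grow(noisy, sp$center, tolerance = 0.15)
  expect_identical(a, b)

  sizes <- vapply(c(0.05, 0.1, 0.15, 0.25),
                  function(tol) sum(region_grow(noisy, sp$center, tol)),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("a background seed yields a single-voxel mask with a warning", {
  sp <- sphere_image()
  set.seed(9)
  noisy <- sp$image + array(rnorm(length(sp$image), 0, 0.3),
                            dim = dim(sp$image))
  expect_warning(m <- region_grow(noisy, c(1, 1, 1), tolerance = 0.01),
                 "single-voxel")
  expect_equal(sum(m), 1)
})

test_that("mask volume arithmetic is exact and additive", {
  m <- array(FALSE, dim = c(10, 10, 10))
  m[1:10, 1:10, 1:10] <- TRUE                       # 1000 voxels
  expect_equal(volume_from_mask(m, 0.1), 1.0)       # 0.1 mm isotropic

  empty <- array(FALSE, dim = c(4, 4, 4))
  expect_warning(v0 <- volume_from_mask(empty, 1), "Empty")
  expect_equal(v0, 0)

  # additive over disjoint masks
  a <- array(FALSE, dim = c(6, 6, 6)); a[1:2, , ] <- TRUE
  b <- array(FALSE, dim = c(6, 6, 6)); b[5:6, , ] <- TRUE
  expect_equal(volume_from_mask(a | b, 0.5),
               volume_from_mask(a, 0.5) + volume_from_mask(b, 0.5))
})

test_that("tube phantom volume is recovered at the acquisition resolution", {
  spec <- phantom_spec("tube", dim = c(24L, 24L, 10L),
                       voxel_mm = c(0.188, 0.188, 1),
                       times_h = c(0, 24))
  ph <- generate_tube_phantom(spec)
  v <- volume_from_mask(ph$truth$gel_masks[[1]], spec$voxel_mm)
  expect_lt(abs(v - 40), prod(spec$voxel_mm))   # one-voxel quantisation
})

test_that("noiseless phantom segmentation matches the truth mask exactly", {
  spec <- small_tube_spec(sigma = 0)
  ph <- generate_tube_phantom(spec)
  t1 <- ph$truth$t1_fields[[1]]
  gel_truth <- ph$truth$gel_masks[[1]]
  seed <- round(colMeans(arrayInd(which(gel_truth), dim(gel_truth))))
  grown <- region_grow(t1, seed, tolerance = 0.15)
  expect_identical(as.vector(grown), as.vector(gel_truth))
  expect_equal(volume_from_mask(grown, spec$voxel_mm),
               ph$truth$release$volume_uL[1])
})

test_that("morphological erosion matches a brute-force city-block oracle", {
  gel <- cityblock_ball(17, 7)
  core <- mask_erode(gel, 2)
  # oracle: a voxel survives iff every voxel within city-block distance 2
  # is inside the gel
  d <- dim(gel)
  offsets <- expand.grid(dx = -2:2, dy = -2:2, dz = -2:2)
  offsets <- offsets[abs(offsets$dx) + abs(offsets$dy) + abs(offsets$dz) <= 2, ]
  oracle <- array(TRUE, dim = d)
  for (r in seq_len(nrow(offsets))) {
    sh <- gel
    for (ax in 1:3) {
      k <- offsets[r, ax]
      while (k != 0) {
        sh <- gelrelease:::shift_mask(sh, ax, sign(k))
        k <- k - sign(k)
      }
    }
    oracle <- oracle & sh
  }
  expect_identical(core, oracle)
  expect_identical(core, cityblock_ball(17, 5))
})

test_that("ROI construction follows the rim/adjacent/mirror protocol", {
  gel <- cityblock_ball(31, 7)
  rois <- build_roi_set(gel, rim_depth = 2, tissue_offset = 4)
  expect_identical(rois$core, cityblock_ball(31, 5))
  expect_identical(rois$rim, gel & !rois$core)
  expect_true(all(rois$core[gel] | !rois$core[gel]))  # core inside gel
  expect_true(all(gel[rois$core]))
  # adjacent shell sits exactly at the stated offset
  expect_identical(rois$adjacent,
                   cityblock_ball(31, 11) & !cityblock_ball(31, 10))
  # mirrored masks preserve voxel counts; mirroring is an involution
  expect_equal(sum(rois$core_mirror), sum(rois$core))
  expect_identical(mask_mirror(mask_mirror(rois$core)), rois$core)
  # disjointness of core and adjacent tissue
  expect_false(any(rois$core & rois$adjacent))

  # rim depth 0 keeps the full gel
  rois0 <- build_roi_set(gel, rim_depth = 0, tissue_offset = 2)
  expect_identical(rois0$core, gel)

  # over-erosion is a clear error
  expect_error(build_roi_set(cityblock_ball(9, 2), rim_depth = 3),
               "empties")
})

test_that("segmentation volume stays accurate under Rician noise", {
  sp <- sphere_image(n = 25, radius = 7)
  set.seed(21)
  sigma <- 0.02 * 2   # 2% of the object signal
  noisy <- sqrt((sp$image + array(rnorm(length(sp$image), 0, sigma),
                                  dim = dim(sp$image)))^2 +
                array(rnorm(length(sp$image), 0, sigma),
                      dim = dim(sp$image))^2)
  grown <- region_grow(noisy, sp$center, tolerance = 0.2)
  v_err <- abs(sum(grown) - sum(sp$truth)) / sum(sp$truth)
  expect_lt(v_err, 0.05)
})
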