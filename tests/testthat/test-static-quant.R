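test_that("sum_frames is the duration-weighted mean over the window", {
  sch <- default_frame_schema()
  # the four 20-40 min frames are frames 11-14 (ends 25, 30, 35, 40 min);
  # give them 2.0, 2.2, 1.8, 2.0
  vals <- rep(1, 16)
  vals[11:14] <- c(2.0, 2.2, 1.8, 2.0)
  series <- uniform_series(vals)
  img <- sum_frames(series)
  expect_equal(img$voxels[1, 1, 1], 2.0)

  # constant series: identity
  cst <- uniform_series(rep(3.7, 16))
  expect_true(all(sum_frames(cst)$voxels == 3.7))

  # non-aligned window errors and lists boundaries
  expect_error(sum_frames(series, c(20, 42)), "align.*boundaries")
  # a window of unequal frame durations weights by duration
  mix <- uniform_series(c(rep(1, 5), rep(4, 5), rep(1, 6)))
  img2 <- sum_frames(mix, c(0, 20))  # five 1-min at 1, five 3-min at 4
  expect_equal(img2$voxels[1, 1, 1], (5 * 1 * 1 + 15 * 4) / 20)
})

test_that("reference statistics are the arithmetic mean over the mask", {
  img <- volume_image(array(c(1.0, 1.2, 1.4, 9, 9, 9), dim = c(1, 2, 3)),
                      c(2, 2, 2))
  m <- array(FALSE, dim = c(1, 2, 3))
  m[1, , 1] <- TRUE; m[1, 1, 2] <- TRUE  # values 1.0, 1.2, 1.4
  rs <- reference_stats(img, region_mask(m, c(2, 2, 2)))
  expect_equal(rs$mean_suv, 1.2)
  expect_equal(rs$voxel_count, 3L)

  single <- array(FALSE, dim = c(1, 2, 3)); single[1, 1, 1] <- TRUE
  expect_equal(reference_stats(img, region_mask(single, c(2, 2, 2)))$mean_suv,
               1.0)

  zimg <- volume_image(array(0, dim = c(1, 2, 3)), c(2, 2, 2))
  expect_error(reference_stats(zimg, region_mask(m, c(2, 2, 2))),
               "positive reference mean")
})

test_that("find_max_voxel breaks ties lexicographically and honours masks", {
  vox <- array(1, dim = c(4, 4, 4))
  vox[3, 2, 2] <- 4.1
  img <- volume_image(vox, c(2, 2, 2))
  expect_equal(find_max_voxel(img), c(3L, 2L, 2L))

  vox[2, 3, 3] <- 4.1  # tie: (2,3,3) < (3,2,2) lexicographically
  img <- volume_image(vox, c(2, 2, 2))
  expect_equal(find_max_voxel(img), c(2L, 3L, 3L))

  # brute-force oracle within a random mask
  set.seed(5)
  for (rep in 1:20) {
    vox <- array(runif(64), dim = c(4, 4, 4))
    img <- volume_image(vox, c(2, 2, 2))
    m <- array(runif(64) < 0.5, dim = c(4, 4, 4))
    m[1, 1, 1] <- TRUE
    best <- c(Inf, Inf, Inf); bv <- -Inf
    for (z in 1:4) for (y in 1:4) for (x in 1:4)
      if (m[z, y, x] && vox[z, y, x] > bv) {
        bv <- vox[z, y, x]; best <- c(z, y, x)
      }
    expect_equal(find_max_voxel(img, region_mask(m, c(2, 2, 2))),
                 as.integer(best))
  }
})

test_that("tbr_max uses a physical in-plane disc around the max voxel", {
  # uniform image: TBR is the plain ratio
  img <- volume_image(array(3.2, dim = c(5, 9, 9)), c(2, 2, 2))
  expect_equal(tbr_max(img, ref_stats(1.6), c(3L, 5L, 5L)), 2.0)
  # linearity in the reference
  expect_equal(tbr_max(img, ref_stats(3.2), c(3L, 5L, 5L)), 1.0)

  # disc membership at 2 mm in-plane spacing: offsets with
  # (2oy)^2 + (2ox)^2 <= 64 -> oy^2 + ox^2 <= 16
  off <- expand.grid(oy = -4:4, ox = -4:4)
  n_expected <- sum(off$oy^2 + off$ox^2 <= 16)
  vox <- array(0.001, dim = c(5, 19, 19))
  vox[3, , ] <- 0.001
  img <- volume_image(vox, c(2, 2, 2))
  # mark the disc by putting 1 at the centre slice and counting via the mean
  vox[3, , ] <- 1
  img <- volume_image(vox, c(2, 2, 2))
  got <- tbr_max(img, ref_stats(1), c(3L, 10L, 10L))
  expect_equal(got, 1)  # uniform slice sanity
  # count voxels through a delta image: mean = n_hit/n_member
  vox2 <- array(0, dim = c(5, 19, 19))
  vox2[3, 10, 10] <- 1
  img2 <- volume_image(vox2, c(2, 2, 2))
  expect_equal(tbr_max(img2, ref_stats(1), c(3L, 10L, 10L)),
               1 / n_expected)

  # clipping at the border warns
  expect_warning(tbr_max(img, ref_stats(1), c(3L, 1L, 1L)), "clip")
})

test_that("2D auto-contour takes the seeded 4-connected component", {
  img <- box_image()  # 3.2 box on 1.0 background, ref 1.6 -> threshold 2.56
  mv <- find_max_voxel(img)
  res <- autocontour_2d(img, ref_stats(1.6), mv)
  expect_true(res$tumour_detected)
  expect_equal(res$tbr_mean, 2.0)
  # mask confined to the max slice and exactly the box cross-section
  expect_equal(sum(res$mask$voxels), 16L)
  expect_true(all(which(res$mask$voxels, arr.ind = TRUE)[, 1] == mv[1]))

  # two blobs in the slice: only the one containing the max voxel
  vox <- array(1, dim = c(3, 12, 12))
  vox[2, 2:4, 2:4] <- 3.0
  vox[2, 8:10, 8:10] <- 3.4  # hotter blob holds the max voxel
  img2 <- volume_image(vox, c(2, 2, 2))
  mv2 <- find_max_voxel(img2)
  res2 <- autocontour_2d(img2, ref_stats(1.6), mv2)
  above <- array(FALSE, dim = dim(vox))
  above[2, , ] <- vox[2, , ] >= 1.6 * 1.6
  oracle <- flood_fill_oracle(above, mv2, three_d = FALSE)
  expect_identical(res2$mask$voxels, oracle)
  expect_equal(sum(res2$mask$voxels), 9L)

  # everything below threshold: no tumour
  flat <- volume_image(array(1, dim = c(3, 4, 4)), c(2, 2, 2))
  res3 <- autocontour_2d(flat, ref_stats(1.6), c(2L, 2L, 2L))
  expect_false(res3$tumour_detected)
  expect_true(is.na(res3$tbr_mean))
})

test_that("3D auto-contour yields MTV as voxel count times voxel volume", {
  img <- box_image()  # 3x4x4 box of 2mm voxels = 48 voxels = 0.384 mL
  mv <- find_max_voxel(img)
  res <- mtv_3d(img, ref_stats(1.6), mv)
  expect_equal(sum(res$mask$voxels), 48L)
  expect_equal(res$mtv_ml, 48 * 8 / 1000)

  # seeded component against the flood-fill oracle on a random field
  set.seed(9)
  vox <- array(runif(6 * 8 * 8, 0.5, 3.5), dim = c(6, 8, 8))
  vox[3, 4, 4] <- 4
  img2 <- volume_image(vox, c(2, 2, 2))
  res2 <- mtv_3d(img2, ref_stats(1), c(3L, 4L, 4L), tbr_threshold = 2)
  oracle <- flood_fill_oracle(vox >= 2, c(3L, 4L, 4L), three_d = TRUE)
  expect_identical(res2$mask$voxels, oracle)

  # nothing above threshold -> 0; everything above -> field of view
  flat <- volume_image(array(1, dim = c(3, 4, 4)), c(2, 2, 2))
  expect_equal(mtv_3d(flat, ref_stats(1.6), c(2L, 2L, 2L))$mtv_ml, 0)
  hot <- volume_image(array(5, dim = c(3, 4, 4)), c(2, 2, 2))
  expect_equal(mtv_3d(hot, ref_stats(1.6), c(2L, 2L, 2L))$mtv_ml,
               3 * 4 * 4 * 8 / 1000)
})

test_that("static parameters are scale invariant and threshold-monotone", {
  img <- box_image(n = c(8, 16, 16), bg = 1.1, fg = 2.9,
                   z = 3:5, y = 7:10, x = 7:10)
  m <- array(FALSE, dim = dim(img$voxels)); m[7:8, , ] <- TRUE
  refm <- region_mask(m, img$spacing_mm)
  base <- static_params(img, refm)
  for (c_ in c(0.5, 3)) {
    scaled <- volume_image(img$voxels * c_, img$spacing_mm)
    got <- static_params(scaled, refm)
    expect_equal(got$tbr_max, base$tbr_max)
    expect_equal(got$tbr_mean, base$tbr_mean)
    expect_equal(got$mtv_ml, base$mtv_ml)
    expect_identical(got$mtv_mask$voxels, base$mtv_mask$voxels)
  }

  # lowering the threshold never shrinks the MTV mask
  ref <- base$reference
  mv <- base$max_voxel
  prev <- mtv_3d(img, ref, mv, tbr_threshold = 2.2)$mask$voxels
  for (thr in c(1.9, 1.6, 1.3)) {
    cur <- mtv_3d(img, ref, mv, tbr_threshold = thr)$mask$voxels
    expect_true(all(cur[prev]))
    prev <- cur
  }

  # 2D contour is a subset of the 3D mask in the max slice
  ac2 <- autocontour_2d(img, ref, mv)
  ac3 <- mtv_3d(img, ref, mv)
  expect_true(all(ac3$mask$voxels[ac2$mask$voxels]))
})
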