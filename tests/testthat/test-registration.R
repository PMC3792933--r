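test_that("transform algebra: apply, invert, compose, serialize", {
  th <- 20 * pi / 180
  r <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t1 <- affine_transform(r, c(2, -1, 3), kind = "rigid")
  t2 <- affine_transform(diag(c(1.2, 0.9, 1)), c(0, 1, 0))
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_transform(invert_transform(t1), apply_transform(t1, pts)),
               pts, tolerance = 1e-12)
  expect_equal(apply_transform(compose_transform(t2, t1), pts),
               apply_transform(t2, apply_transform(t1, pts)), tolerance = 1e-12)
  m4 <- transform_matrix4(t1)
  expect_equal(m4[1:3, 1:3], r)
  expect_equal(m4[4, ], c(0, 0, 0, 1))
  expect_error(affine_transform(diag(c(1.1, 1, 1)), kind = "rigid"), "rigid")
  expect_error(affine_transform(matrix(0, 3, 3)), "singular")
})

test_that("register_masks returns identity for identical masks", {
  m <- make_ellipsoid_mask(c(20, 20, 14), c(6, 4.5, 4))
  tr <- register_masks(m, m)
  expect_lt(max(abs(tr$matrix - diag(3))), 1e-6)
  expect_lt(max(abs(tr$translation)), 1e-6)
  expect_error(register_masks(vol3d(array(0, c(4, 4, 4))), m), "empty")
})

test_that("register_masks recovers a pure translation to sub-voxel accuracy", {
  mov <- make_ellipsoid_mask(c(24, 24, 16), c(7, 5, 4.5))
  ref <- list(dim = dim(mov$data), affine = mov$affine)
  true_tr <- affine_transform(diag(3), c(3, -2, 1), kind = "rigid")
  fix <- resample_map(mov, true_tr, ref, "nearest")
  fix$data[is.na(fix$data)] <- 0
  rec <- register_masks(mov, fix)
  expect_lt(max(abs(rec$translation - c(3, -2, 1))), 0.25)
  expect_lt(max(abs(rec$matrix - diag(3))), 0.05)
})

test_that("degenerate coplanar masks fall back to centroid translation", {
  dm <- c(12, 12, 8)
  a <- array(0, dm); a[4:9, 4:9, 5] <- 1
  b <- array(0, dm); b[5:10, 5:10, 5] <- 1
  expect_warning(tr <- register_masks(vol3d(a), vol3d(b), refine = FALSE),
                 "degenerate")
  expect_equal(tr$matrix, diag(3))
  expect_equal(tr$translation, c(1, 1, 0), tolerance = 1e-9)
})

test_that("resample_map: exactness on constants and linear ramps, NA handling", {
  dm <- c(10, 12, 8)
  ramp <- array(0, dm)
  for (i in seq_len(dm[1])) ramp[i, , ] <- 2.5 * (i - 1)   # linear in x (mm = vox)
  v <- vol3d(ramp, grid_affine(c(1, 1, 1)))
  idt <- affine_transform(diag(3), c(0, 0, 0))
  # identity on the same grid is bitwise equal
  expect_identical(resample_map(v, idt, v, "linear")$data, v$data)
  # constants stay constant wherever defined
  cv <- vol3d(array(4.2, dm), grid_affine(c(1, 1, 1)))
  sh <- affine_transform(diag(3), c(0.3, -0.4, 0.25))
  out <- resample_map(cv, sh, cv, "linear")
  expect_true(all(out$data[!is.na(out$data)] == 4.2))
  # trilinear is exact on linear fields under pure translation
  out2 <- resample_map(v, affine_transform(diag(3), c(2, 0, 0)), v, "linear")
  inside <- !is.na(out2$data)
  expect_equal(out2$data[inside], ramp[inside] - 5, tolerance = 1e-10)
  # undefined source voxels propagate through trilinear interpolation
  v$data[5, 5, 4] <- NA
  out3 <- resample_map(v, sh, v, "linear")
  expect_true(is.na(out3$data[5, 5, 4]))
  expect_error(resample_map(v, affine_transform(matrix(1e-20, 3, 3) + 0 * diag(3),
                                                c(0, 0, 0), kind = "affine"),
                            v), "singular")
})

test_that("sequential resampling agrees with composed-transform resampling", {
  dm <- c(16, 16, 12)
  set.seed(5)
  smooth <- dcespect:::gaussian_smooth3d(array(rnorm(prod(dm)), dm), 2.5)
  v <- vol3d(smooth, grid_affine(c(1, 1, 1)))
  t1 <- affine_transform(diag(3), c(0.6, -0.4, 0.2))
  th <- 4 * pi / 180
  t2 <- affine_transform(rbind(c(cos(th), -sin(th), 0),
                               c(sin(th), cos(th), 0), c(0, 0, 1)),
                         c(-0.3, 0.2, 0))
  seq2 <- resample_map(resample_map(v, t1, v, "linear"), t2, v, "linear")
  once <- resample_map(v, compose_transform(t2, t1), v, "linear")
  both <- !is.na(seq2$data) & !is.na(once$data)
  expect_gt(sum(both), 1000)
  expect_lt(max(abs(seq2$data[both] - once$data[both])), 0.05)
})
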