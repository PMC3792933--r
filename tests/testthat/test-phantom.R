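test_that("phantom config validates its invariants", {
  expect_error(phantom_config(n_frames = 1), "n_frames")
  expect_error(phantom_config(voxel_size_mm = c(0.4, 0, 0.4)), "voxel")
  expect_error(phantom_config(gap_after_frame = 96), "gap_after_frame")
  expect_error(phantom_config(d50_mm_s = -1), "d50")
  expect_error(generate_parameter_fields(tiny_config(grid_shape = c(8, 8, 8))),
               "at least 10 voxels")
})

test_that("the dynamic time vector carries the inter-acquisition gap", {
  tt <- dce_times(phantom_config())
  expect_length(tt, 96)
  expect_true(all(diff(tt) > 0))
  expect_equal(tt[49] - tt[48], 60 + 4.3)
  expect_equal(unique(round(diff(tt)[-48], 10)), 4.3)
})

test_that("ground-truth fields respect their stated ranges and structure", {
  gt <- generate_parameter_fields(tiny_config())
  tum <- gt$tumor_mask & !gt$vessel_mask
  expect_true(all(gt$ve_map[tum] > 0 & gt$ve_map[tum] < 1))
  expect_true(all(gt$ktrans_map[tum] >= 0 & gt$ktrans_map[tum] <= 0.02 + 1e-12))
  # kep >= ktrans wherever the tumor is set (implied ve <= 1)
  expect_true(all(gt$kep_map[tum] >= gt$ktrans_map[tum]))
  # the pocket is non-empty, contiguous by construction, and exactly zero
  expect_gt(sum(gt$pocket_mask), 0)
  expect_true(all(gt$ktrans_map[gt$pocket_mask] == 0))
  # masks disjoint where required
  expect_false(any(gt$artery_mask & gt$tumor_mask))
  expect_false(any(gt$septa_mask & !gt$tumor_mask))
})

test_that("identical config and seed give bit-identical studies", {
  s1 <- simulate_study(tiny_config(), noise = TRUE)
  s2 <- simulate_study(tiny_config(), noise = TRUE)
  expect_identical(s1$dce$data, s2$dce$data)
  expect_identical(s1$spect$data, s2$spect$data)
  expect_identical(s1$ground_truth$ktrans_map, s2$ground_truth$ktrans_map)
  s3 <- simulate_study(tiny_config(seed = 43), noise = TRUE)
  expect_false(identical(s1$dce$data, s3$dce$data))
})

test_that("noiseless DCE: pre-arrival frames flat, zero-Ktrans voxels flat", {
  cfg <- tiny_config()
  st <- get_tiny_study(noise = FALSE)
  gt <- st$ground_truth
  tt <- st$dce$times_s
  pre <- which(tt < cfg$arrival_s)
  v <- which(gt$tumor_mask & gt$ktrans_map > 0.01, arr.ind = TRUE)[1, ]
  curve <- st$dce$data[v[1], v[2], v[3], ]
  expect_equal(sd(curve[pre]), 0)          # baseline frames identical
  expect_gt(max(curve) - curve[1], 1)      # enhancement after arrival
  z <- which(gt$pocket_mask, arr.ind = TRUE)[1, ]
  zcurve <- st$dce$data[z[1], z[2], z[3], ]
  expect_equal(sd(zcurve), 0)              # Ktrans = 0 voxel stays flat
})

test_that("saturation uptake: midpoint, asymptote, monotonicity", {
  expect_equal(saturation_uptake(45, 30, 45), 15)      # d = d50 -> Umax/2
  expect_gt(saturation_uptake(1e9, 30, 45), 30 - 1e-5) # d -> Inf -> Umax
  expect_error(saturation_uptake(1, 30, 0), "d50")
  d <- sort(runif(500, 0, 200))
  u <- saturation_uptake(d, 30, 45)
  expect_true(all(diff(u) >= 0))           # non-decreasing in delivery
})

test_that("pre-blur uptake is supported exactly on receptor-positive tumor", {
  cfg <- tiny_config()
  st <- get_tiny_study(noise = FALSE)
  gt <- st$ground_truth
  sp <- simulate_spect(gt, st$aif, cfg, with_noise = FALSE, blur_fwhm_mm = 0)
  u <- sp$spect_truth$data
  on <- u > 0
  should <- gt$tumor_mask & gt$receptor_map > 0 & sp$delivery > 0
  expect_identical(on, should)
  expect_true(all(u[gt$vessel_mask] == 0))
  expect_true(all(u[gt$septa_mask] == 0))
})

test_that("the acquired SPECT grid is coarser and the fixed masks are sane", {
  st <- get_tiny_study(noise = FALSE)
  expect_true(all(dcespect:::affine_spacing(st$spect$affine) >
                    dcespect:::affine_spacing(st$dce$affine)))
  expect_gt(sum(st$tumor_mask_fixed$data), 0)
  # fixed-frame tumor volume (mm^3) close to the MRI-frame tumor volume
  vf <- sum(st$tumor_mask_fixed$data) *
    prod(dcespect:::affine_spacing(st$tumor_mask_fixed$affine))
  vm <- sum(st$ground_truth$tumor_mask) *
    prod(dcespect:::affine_spacing(st$dce$affine))
  expect_lt(abs(vf - vm) / vm, 0.1)
})
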