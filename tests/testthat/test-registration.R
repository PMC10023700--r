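test_that("Laplacian filter annihilates constants and affine ramps", {
  const <- image_volume(array(7, dim = c(6, 6, 6)), unit = "HU")
  expect_true(all(laplacian_preprocess(const)$data == 0))
  ramp <- ramp_volume(8)
  lap <- laplacian_preprocess(ramp)
  expect_true(all(abs(lap$data[, , 2:7]) < 1e-12))
})

test_that("Laplacian of an impulse reproduces the 7-point stencil", {
  n <- 7; sp <- 50
  a <- array(0, dim = c(n, n, n)); a[4, 4, 4] <- 1
  lap <- laplacian_preprocess(image_volume(a, spacing = sp, unit = "HU"))$data
  expect_equal(lap[4, 4, 4], -6 / sp^2)
  for (d in list(c(3, 4, 4), c(5, 4, 4), c(4, 3, 4), c(4, 5, 4),
                 c(4, 4, 3), c(4, 4, 5)))
    expect_equal(lap[d[1], d[2], d[3]], 1 / sp^2)
  expect_equal(sum(lap != 0), 7L)
})

test_that("warping with a zero field on a coincident grid is the identity", {
  vol <- ramp_volume(8)
  w <- warp(vol, zero_field(vol), "linear")
  expect_equal(w$data, vol$data, tolerance = 1e-12)
})

test_that("a constant field shifts a ramp by the expected amount", {
  vol <- ramp_volume(10) # value 10 per z slice, spacing 50 um
  w <- warp(vol, constant_field(vol, c(0, 0, 100)), "linear") # +2 voxels
  interior <- 2:7
  expect_equal(w$data[, , interior], vol$data[, , interior + 2],
               tolerance = 1e-9)
})

test_that("masks warp with nearest neighbour and stay strictly binary", {
  m <- array(0L, dim = c(8, 8, 8)); m[3:6, 3:6, 3:6] <- 1L
  mask <- lung_mask(m, spacing = 50)
  f <- constant_field(mask, c(25, 0, 0)) # half-voxel shift
  w <- warp(mask, f, "nearest")
  expect_true(all(w$data %in% c(0L, 1L)))
  expect_error(warp(mask, f, "linear"), "nearest")
})

test_that("TRE matches hand-computed distances and the perfect-field limit", {
  lm <- landmark_set(data.frame(id = 1, fx = 100, fy = 100, fz = 100,
                                mx = 130, my = 140, mz = 100))
  expect_equal(target_registration_error(lm)$distances, 50) # 3-4-5 triangle
  same <- landmark_set(data.frame(id = 1, fx = 50, fy = 50, fz = 50,
                                  mx = 50, my = 50, mz = 50))
  expect_equal(target_registration_error(same)$mean, 0)
  # a field equal to the true displacement zeroes the error
  vol <- ramp_volume(8)
  f <- constant_field(vol, c(30, 40, 0))
  lm2 <- landmark_set(data.frame(id = 1:2, fx = c(100, 150), fy = 100,
                                 fz = 100, mx = c(130, 180), my = 140,
                                 mz = 100))
  expect_equal(target_registration_error(lm2, f)$distances, c(0, 0),
               tolerance = 1e-9)
})

test_that("self-registration returns a negligible field", {
  ph <- fixture("saline48", small_saline(11))
  reg <- demons_register(ph$insp_hu, ph$insp_hu, levels = 3,
                         iterations = c(20, 10, 5))
  mag <- sqrt(rowSums(matrix(reg$field$u, ncol = 3)^2))
  expect_lt(mean(mag), 0.1 * ph$insp_hu$spacing[1])
})

test_that("a known integer-voxel translation is recovered inside the lung", {
  ph <- fixture("saline48", small_saline(11))
  sp <- ph$insp_hu$spacing
  shift <- 3L # voxels along z
  a <- ph$insp_hu$data
  b <- a
  b[, , seq_len(dim(a)[3] - shift)] <- a[, , (shift + 1):dim(a)[3]]
  moving <- image_volume(b, spacing = sp, unit = "HU")
  # moving(p + u) = fixed(p) requires u_z = -shift voxels
  reg <- fixture("acc_shift_reg", demons_register(ph$insp_hu, moving))
  m <- ph$mask_insp$data != 0
  uz <- reg$field$u[, , , 3][m]
  expect_lt(abs(mean(uz) - (-shift * sp[3])), 0.5 * sp[3])
})

test_that("registration recovers the phantom deformation to sub-voxel TRE", {
  ph <- fixture("saline48", small_saline(11))
  res <- fixture("saline48_reg",
                 demons_register(ph$insp_hu, ph$exp_hu, mask = ph$mask_insp,
                                 landmarks = ph$truth$landmarks))
  tre_b <- res$report$tre_before
  tre_a <- res$report$tre_after
  expect_lt(tre_a$mean, ph$insp_hu$spacing[1]) # <= voxel size on average
  expect_true(all(tre_a$distances < tre_b$distances))
})

test_that("invalid registration arguments are rejected", {
  ph <- fixture("saline48", small_saline(11))
  other <- image_volume(ph$exp_hu$data, spacing = c(40, 50, 50), unit = "HU")
  expect_error(demons_register(ph$insp_hu, other), "spacing")
  expect_error(demons_register(ph$insp_hu, ph$exp_hu, levels = 0), "level")
  expect_error(demons_register(ph$insp_hu, ph$exp_hu, levels = 2,
                               iterations = c(10, 0)), "positive")
})
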