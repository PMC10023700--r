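test_that("phantom generation is deterministic for a fixed seed", {
  a <- generate_phantom(phantom_spec("lesioned", shape = c(40, 40, 40), seed = 5))
  b <- generate_phantom(phantom_spec("lesioned", shape = c(40, 40, 40), seed = 5))
  expect_identical(a$insp_raw$data, b$insp_raw$data)
  expect_identical(a$exp_raw$data, b$exp_raw$data)
  expect_identical(a$truth$class_map$data, b$truth$class_map$data)
  expect_identical(as.data.frame(a$truth$landmarks),
                   as.data.frame(b$truth$landmarks))
  c_ <- generate_phantom(phantom_spec("lesioned", shape = c(40, 40, 40), seed = 6))
  expect_false(identical(a$insp_raw$data, c_$insp_raw$data))
})

test_that("compartment HU means produce the analytic SVg values", {
  # saline mode: ventilated compartment at the default -550 / -400 pair
  ph <- fixture("saline48", small_saline(11))
  expect_equal(ph$truth$compartment_hu$hu_insp[3], -550)
  expect_equal(ph$truth$compartment_hu$hu_exp[3], -400)
  # dSVg = 1000/450 - 1000/600 = 0.5556 ml/g at those means
  expect_equal(sv_total(-550) - sv_total(-400), 1000 / 450 - 1000 / 600)
  expect_equal(round(sv_total(-550) - sv_total(-400), 3), 0.556)
  # in-compartment measured mean close to the analytic value
  # on a small grid the correlated texture has few independent samples, so
  # the in-compartment median carries visible sampling error
  m <- ph$mask_insp$data != 0
  svi <- sv_total(ph$insp_hu$data[m]) - svg_constants()$sv_tissue
  expect_equal(median(svi), sv_total(-550) - svg_constants()$sv_tissue,
               tolerance = 0.06)
  # fibrotic compartment: SVg = 1000/900 - 0.939 = 0.172 in both phases
  expect_equal(round(sv_total(-100) - svg_constants()$sv_tissue, 3), 0.172)
})

test_that("saline mode truth is 100% NV and lesioned mode hits target fractions", {
  ph <- fixture("saline48", small_saline(11))
  tl <- ph$truth$class_map$data
  expect_true(all(tl[tl != 0] == 3L))
  les <- fixture("lesioned48",
                 generate_phantom(phantom_spec("lesioned", shape = small_shape,
                                               seed = 7)))
  tt <- table(les$truth$class_map$data[les$truth$class_map$data != 0])
  fracs <- as.numeric(tt) / sum(tt)
  expect_equal(fracs[1], 0.10, tolerance = 0.35) # F target 10%
  expect_equal(fracs[2], 0.15, tolerance = 0.35) # LV target 15%
})

test_that("the truth field maps landmarks exactly and masks onto each other", {
  ph <- fixture("saline48", small_saline(11))
  tre <- target_registration_error(ph$truth$landmarks, ph$truth$field)
  expect_equal(tre$mean, 0, tolerance = 1e-9)
  # warping the expiratory mask through the truth field recovers the
  # inspiratory mask except for a thin resampling boundary
  w <- warp(ph$mask_exp, ph$truth$field, "nearest")
  agree <- mean(w$data == ph$mask_insp$data)
  expect_gt(agree, 0.98)
})

test_that("per-compartment ventilation ordering holds by construction", {
  les <- fixture("lesioned48",
                 generate_phantom(phantom_spec("lesioned", shape = small_shape,
                                               seed = 7)))
  w <- warp(les$exp_hu, les$truth$field, "linear")
  svi <- svg_map(les$insp_hu, les$mask_insp)
  sve <- svg_map(w, les$mask_insp)
  dsvg <- ventilation_map(svi, sve, les$mask_insp)
  lab <- les$truth$class_map$data
  # ventilated voxels: inspiratory SVg above expiratory by construction
  nv <- lab == 3L
  expect_gt(mean(svi$data[nv] > sve$data[nv], na.rm = TRUE), 0.95)
  # fibrotic voxels barely ventilate: |dSVg| below any plausible beta
  f <- lab == 1L & !is.na(dsvg$data)
  expect_lt(median(abs(dsvg$data[f])), 0.2)
  # NV ventilates more than LV, which ventilates more than F
  expect_gt(median(dsvg$data[nv], na.rm = TRUE),
            median(dsvg$data[lab == 2L], na.rm = TRUE))
})

test_that("dice evaluation matches hand-computed overlaps", {
  d <- c(6, 1, 1)
  mk <- function(v) image_volume(array(v, dim = d), spacing = 50, unit = "label")
  truth <- mk(c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(unname(evaluate_recovery(truth, truth)$dice), c(1, 1, 1))
  # half of an F lesion mislabeled LV: Dice(F) = 2*(n/2)/(n + n/2) = 2/3
  pred <- mk(c(1L, 2L, 2L, 2L, 3L, 3L))
  expect_equal(evaluate_recovery(truth, pred)$dice[["F"]], 2 / 3)
  # all-NV prediction has zero F overlap
  allnv <- mk(rep(3L, 6))
  expect_equal(evaluate_recovery(truth, allnv)$dice[["F"]], 0)
  expect_error(evaluate_recovery(truth, mk(rep(1L, 6))[["data"]]), "label")
})

test_that("infeasible phantom parameters are rejected", {
  expect_error(phantom_spec(frac_f = 0.9, frac_lv = 0.3), "fractions")
  expect_error(phantom_spec(shape = c(24, 24, 24), amplitude_vox = 12),
               "invertible")
  # a blob bigger than the lung cannot be placed
  expect_error(generate_phantom(phantom_spec("lesioned", shape = c(32, 32, 32),
                                             frac_f = 0.6, n_blobs_f = 1,
                                             frac_lv = 0, seed = 1)),
               "infeasible|fit inside")
})

test_that("fibrotic mode builds a confluent dorsal consolidation", {
  fib <- generate_phantom(phantom_spec("fibrotic", shape = small_shape,
                                       seed = 13))
  lab <- fib$truth$class_map$data
  tt <- table(lab[lab != 0]) / sum(lab != 0)
  expect_gt(tt[["1"]], 0.30)  # F about 40%
  expect_gt(tt[["2"]], 0.12)  # LV about 20%
  # fibrosis sits dorsal to the low-ventilation band on average
  iy <- slice.index(lab, 2)
  expect_gt(mean(iy[lab == 1L]), mean(iy[lab == 3L]))
})
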