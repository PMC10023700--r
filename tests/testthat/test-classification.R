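test_that("threshold percentiles follow linear interpolation of order statistics", {
  grid <- seq(0, 1, by = 0.1)
  th <- derive_thresholds(grid, grid, grid)
  expect_equal(th$beta, 0.25)          # 25th percentile of the 11-point grid
  expect_equal(th$alpha_I, 0.05)
  # degenerate constant pool
  thc <- derive_thresholds(rep(3, 10), rep(3, 10), rep(3, 10))
  expect_equal(c(thc$alpha_I, thc$alpha_E, thc$beta), c(3, 3, 3))
  # two-point pool at p = 50 gives the midpoint
  th2 <- derive_thresholds(c(2, 4), c(2, 4), c(2, 4), p_alpha = 50, p_beta = 50)
  expect_equal(th2$beta, 3)
  expect_error(derive_thresholds(numeric(0), 1, 1), "non-empty")
  expect_error(derive_thresholds(1, 1, 1, p_alpha = 0), "0, 100")
})

make_maps <- function(svi, sve, mask_vals = NULL) {
  d <- c(length(svi), 1, 1)
  m <- lung_mask(array(if (is.null(mask_vals)) 1L else mask_vals, dim = d),
                 spacing = 50)
  svi <- image_volume(array(svi, dim = d), spacing = 50, unit = "SVg")
  sve <- image_volume(array(sve, dim = d), spacing = 50, unit = "SVg")
  dsvg <- image_volume(array(svi$data - sve$data, dim = d), spacing = 50,
                       unit = "dSVg")
  list(svi = svi, sve = sve, dsvg = dsvg, mask = m)
}

test_that("classification rules follow the F / LV / NV definitions exactly", {
  th <- structure(list(alpha_I = 1, alpha_E = 0.6, beta = 0.5,
                       p_alpha = 5, p_beta = 25, cohort_id = "test"),
                  class = "functional_thresholds")
  eps <- 1e-6
  # voxel 1: both SVg below alphas -> F regardless of dSVg
  # voxel 2: both above, dSVg below beta -> LV
  # voxel 3: both above, dSVg exactly beta -> NV (boundary belongs to NV)
  # voxel 4: mixed margins (insp below only) -> assigned by the dSVg rule
  x <- make_maps(svi = c(1 - eps, 1.9, 1.9, 1 - eps),
                 sve = c(0.6 - eps, 1.5, 1.4, 0.7))
  x$dsvg$data[] <- c(0.0, 0.5 - eps, 0.5, 0.4)
  fmap <- classify_voxels(x$svi, x$sve, x$dsvg, th, x$mask)
  expect_equal(as.integer(fmap$data), c(1L, 2L, 3L, 2L)) # F, LV, NV, LV
  expect_equal(attr(fmap, "mixed_margin_fraction"), 0.25)
})

test_that("class percentages partition to exactly 100", {
  th <- structure(list(alpha_I = 1, alpha_E = 0.6, beta = 0.5),
                  class = "functional_thresholds")
  x <- make_maps(svi = c(0.5, 1.9, 1.9, 1.9, 1.9, 0.5, 1.9, 1.9, 1.9, 1.9),
                 sve = c(0.1, 1.0, 1.0, 1.0, 1.0, 0.2, 1.0, 1.0, 1.0, 1.0))
  x$dsvg$data[] <- c(0, 0.1, 0.2, 0.4, 0.6, 0, 0.6, 0.7, 0.8, 0.9)
  fmap <- classify_voxels(x$svi, x$sve, x$dsvg, th, x$mask)
  pct <- class_percentages(fmap)
  expect_equal(sum(pct), 100)
  expect_equal(unname(pct), c(20, 30, 50)) # 2 F, 3 LV, 5 NV of 10
  # a region with no classified voxels is an error
  d <- dim(x$mask$data)
  partial <- lung_mask(array(c(0L, rep(1L, prod(d) - 1L)), dim = d), spacing = 50)
  fmap2 <- classify_voxels(x$svi, x$sve, x$dsvg, th, partial)
  outside_only <- lung_mask(array(c(1L, rep(0L, prod(d) - 1L)), dim = d),
                            spacing = 50)
  expect_error(class_percentages(fmap2, outside_only), "no classified voxels")
})

test_that("raising beta never shrinks LV nor grows NV; F is invariant", {
  set.seed(42)
  n <- 500
  svi <- runif(n, 0.5, 2); sve <- runif(n, 0.3, 1.5)
  dsvg <- svi - sve
  x <- make_maps(svi, sve)
  x$dsvg$data[] <- dsvg
  betas <- seq(-0.5, 1.5, by = 0.25)
  prev <- NULL
  for (b in betas) {
    th <- structure(list(alpha_I = 0.8, alpha_E = 0.5, beta = b),
                    class = "functional_thresholds")
    pct <- class_percentages(classify_voxels(x$svi, x$sve, x$dsvg, th, x$mask))
    if (!is.null(prev)) {
      expect_gte(pct[["pctLV"]], prev[["pctLV"]])
      expect_lte(pct[["pctNV"]], prev[["pctNV"]])
      expect_equal(pct[["pctF"]], prev[["pctF"]])
    }
    prev <- pct
  }
})

test_that("a saline phantom classified with its own thresholds shows the nominal tail fractions", {
  ph <- fixture("saline48", small_saline(11))
  # analytic (truth-field) processing isolates the percentile construction
  w <- warp(ph$exp_hu, ph$truth$field, "linear")
  svi <- svg_map(ph$insp_hu, ph$mask_insp)
  sve <- svg_map(w, ph$mask_insp)
  dsvg <- ventilation_map(svi, sve, ph$mask_insp)
  m <- ph$mask_insp$data != 0
  th <- derive_thresholds(svi$data[m], sve$data[m], dsvg$data[m])
  expect_equal(mean(svi$data[m] < th$alpha_I), 0.05, tolerance = 0.1)
  expect_equal(mean(dsvg$data[m] < th$beta), 0.25, tolerance = 0.02)
  pct <- class_percentages(classify_voxels(svi, sve, dsvg, th, ph$mask_insp))
  expect_gte(pct[["pctNV"]], 70)
})

test_that("thresholds serialize to JSON and back", {
  th <- derive_thresholds(runif(100), runif(100), runif(100),
                          cohort_id = "saline-d7")
  path <- tempfile(fileext = ".json")
  write_thresholds(th, path)
  back <- read_thresholds(path)
  expect_equal(back$alpha_I, th$alpha_I)
  expect_equal(back$beta, th$beta)
  expect_equal(back$cohort_id, "saline-d7")
})
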