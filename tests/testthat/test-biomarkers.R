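box_mask <- function(zslices, spacing = 50) {
  # 10 x 10 x zslices box inside a slightly larger grid
  d <- c(12, 12, zslices + 4)
  m <- array(0L, dim = d)
  m[2:11, 2:11, 3:(zslices + 2)] <- 1L
  lung_mask(m, spacing = spacing)
}

test_that("region splitting follows the equal-slab rule with cranial remainder", {
  m60 <- box_mask(60)
  p <- split_regions(m60, "halves", axis = 3)
  expect_equal(unname(p$counts), c(30, 30) * 100)
  m61 <- box_mask(61)
  p61 <- split_regions(m61, "halves", axis = 3)
  expect_equal(unname(p61$counts), c(31, 30) * 100) # cranial slab gets the extra
  # thirds along the chosen axis
  p3 <- split_regions(box_mask(10), "thirds", axis = 3)
  expect_equal(unname(p3$counts), c(4, 3, 3) * 100)
  expect_equal(p3$region_names, c("ventral", "intermediate", "dorsal"))
  # partition properties: disjoint and exhaustive over the mask
  lab <- p61$labels$data
  expect_equal(sum(lab != 0), sum(m61$data))
  expect_true(all(lab[m61$data == 1L] > 0))
  expect_error(split_regions(box_mask(2), "thirds", axis = 3), "shorter")
})

test_that("distribution metrics match type-7 order statistics", {
  dm <- distribution_metrics(1:100)
  expect_equal(unname(dm), c(50.5, 75.25, 49.5))
  expect_equal(unname(distribution_metrics(rep(4, 10))), c(4, 4, 0))
  expect_equal(unname(distribution_metrics(7)), c(7, 7, 0))
  expect_error(distribution_metrics(numeric(0)), "no values")
})

test_that("distribution metrics agree with a brute-force oracle on random vectors", {
  # independent oracle: percentiles by explicit interpolation of sorted values
  brute <- function(v, p) {
    s <- sort(v)
    h <- (length(s) - 1) * p
    lo <- floor(h) + 1
    hi <- ceiling(h) + 1
    s[lo] + (h - floor(h)) * (s[hi] - s[lo])
  }
  set.seed(99)
  for (i in 1:100) {
    v <- rnorm(sample(3:40, 1))
    if (i %% 3 == 0) v <- round(v, 1) # introduce ties
    dm <- distribution_metrics(v)
    expect_equal(dm[["median"]], brute(v, 0.5), tolerance = 1e-12)
    expect_equal(dm[["p75"]], brute(v, 0.75), tolerance = 1e-12)
    expect_equal(dm[["IQR"]], brute(v, 0.75) - brute(v, 0.25), tolerance = 1e-12)
  }
})

test_that("subject histograms normalize, clamp outliers and validate input", {
  m <- box_mask(4)
  vol <- image_volume(array(0, dim = dim(m$data)), spacing = 50, unit = "HU")
  vol$data[m$data == 1L] <- -500
  edges <- seq(-1000, 0, by = 100)
  h <- subject_histogram(vol, m, edges)
  expect_equal(sum(h$frequency), 1)
  expect_equal(h$frequency[6], 1) # all mass in [-500, -400)
  # uniform across k bins
  vol2 <- vol
  vals <- rep(seq(-950, -50, by = 100), length.out = sum(m$data))
  vol2$data[m$data == 1L] <- vals
  h2 <- subject_histogram(vol2, m, edges)
  expect_equal(h2$frequency, rep(0.1, 10), tolerance = 0.01)
  # out-of-range values go to the end bins with a warning
  vol3 <- vol
  vol3$data[m$data == 1L][1] <- 500
  expect_warning(h3 <- subject_histogram(vol3, m, edges), "end bins")
  expect_equal(sum(h3$frequency), 1)
  expect_error(subject_histogram(vol, m, c(0, 0, 1)), "increasing")
})

test_that("group median histogram takes per-bin medians", {
  m <- box_mask(4)
  edges <- seq(0, 1, by = 0.5)
  mk <- function(f) structure(list(bin_edges = edges, mid = c(0.25, 0.75),
                                   frequency = f), class = "histogram_summary")
  expect_equal(group_median_histogram(list(mk(c(0.3, 0.7))))$frequency,
               c(0.3, 0.7))
  expect_equal(group_median_histogram(list(mk(c(0.1, 0.9)), mk(c(0.2, 0.8)),
                                           mk(c(0.3, 0.7))))$frequency,
               c(0.2, 0.8))
  expect_equal(group_median_histogram(list(mk(c(0.1, 0.9)),
                                           mk(c(0.3, 0.7))))$frequency,
               c(0.2, 0.8)) # midpoint of two
  bad <- mk(c(0.5, 0.5)); bad$bin_edges <- c(0, 1, 2)
  expect_error(group_median_histogram(list(mk(c(0.1, 0.9)), bad)), "edges")
})

test_that("spearman matches the hand-computed example and the limits", {
  expect_equal(spearman_cor(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearman_cor(1:3, 1:4), "equal length")
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("spearman agrees with brute-force ranks and cor.test to 1e-12", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (i %% 4 == 0) { x <- round(x); y <- round(y) } # ties
    s <- spearman_cor(x, y)
    # brute force: midranks + explicit Pearson formula
    rx <- rank(x); ry <- rank(y)
    rho_bf <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(s$rho, rho_bf, tolerance = 1e-12)
    if (!any(duplicated(x)) && !any(duplicated(y))) {
      ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
      expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
    }
  }
})

test_that("exact permutation p-values are consistent with the null", {
  # perfect monotone with n = 5: p = 2/5! (both orientations reach |rho| = 1)
  s <- spearman_cor(1:5, c(2, 4, 6, 8, 10), p_method = "exact")
  expect_equal(s$p_value, 2 / factorial(5))
  expect_error(spearman_cor(1:11, rnorm(11), p_method = "exact"), "n <= 10")
})

test_that("left-lung restriction honours side labels or splits at the centroid", {
  m <- array(0L, dim = c(10, 6, 6))
  m[2:9, 2:5, 2:5] <- 1L
  mask <- lung_mask(m, spacing = 50)
  sides <- image_volume(array(0L, dim = dim(m)), spacing = 50, unit = "label")
  sides$data[2:5, , ] <- 1L; sides$data[6:9, , ] <- 2L
  left <- left_lung_mask(mask, side_labels = sides)
  expect_equal(sum(left$data), 4 * 4 * 4)
  expect_warning(left2 <- left_lung_mask(mask), "midsagittal")
  expect_equal(sum(left2$data), sum(mask$data) / 2)
})

test_that("biomarker tables have the expected cardinality and fail without inputs", {
  ph <- fixture("saline48", small_saline(11))
  w <- warp(ph$exp_hu, ph$truth$field, "linear")
  svi <- svg_map(ph$insp_hu, ph$mask_insp)
  sve <- svg_map(w, ph$mask_insp)
  dsvg <- ventilation_map(svi, sve, ph$mask_insp)
  m <- ph$mask_insp$data != 0
  th <- derive_thresholds(svi$data[m], sve$data[m], dsvg$data[m])
  fmap <- classify_voxels(svi, sve, dsvg, th, ph$mask_insp)
  subj <- list(subject = "p1", day = 7, hu_insp = ph$insp_hu, dsvg = dsvg,
               fmap = fmap, mask = ph$mask_insp)
  tab <- biomarker_table(list(subj), scheme = "whole")
  expect_equal(nrow(tab), 9)
  tab2 <- biomarker_table(list(subj), scheme = "halves")
  expect_equal(nrow(tab2), 18)
  no_fmap <- subj; no_fmap$fmap <- NULL
  expect_error(biomarker_table(list(no_fmap), metrics = "pctF"),
               "functional map")
})
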