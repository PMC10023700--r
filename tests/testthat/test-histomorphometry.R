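# fixtures are constructed in code: an RGB "slide" with known pixel classes
make_slide <- function(nr = 90, nc = 60) {
  slide <- array(0, dim = c(nr, nc, 3))
  # default background: pink-ish stained tissue
  slide[, , 1] <- 0.8; slide[, , 2] <- 0.4; slide[, , 3] <- 0.5
  slide
}

paint <- function(slide, sel, rgb) {
  for (ch in 1:3) {
    m <- slide[, , ch]
    m[sel] <- rgb[ch]
    slide[, , ch] <- m
  }
  slide
}

test_that("slide ROIs split the vertical extent equally with the remainder on top", {
  m <- matrix(0L, 90, 60); m[1:90, 11:50] <- 1L
  lab <- split_slide_rois(m)
  expect_equal(as.integer(table(lab[lab != 0])), c(30, 30, 30) * 40)
  m91 <- matrix(0L, 95, 60); m91[3:93, 11:50] <- 1L # 91 rows
  lab91 <- split_slide_rois(m91)
  expect_equal(as.integer(table(lab91[lab91 != 0])), c(31, 30, 30) * 40)
  expect_error(split_slide_rois(matrix(0L, 5, 5)), "empty")
  thin <- matrix(0L, 5, 5); thin[2, ] <- 1L
  expect_error(split_slide_rois(thin), "shorter")
})

test_that("collagen fraction recovers an exact constructed percentage", {
  slide <- make_slide()
  roi <- matrix(FALSE, 90, 60); roi[1:50, 1:40] <- TRUE # 2000 px
  green_sel <- matrix(FALSE, 90, 60); green_sel[1:15, 1:40] <- TRUE # 600 px = 30%
  slide <- paint(slide, green_sel, c(0.2, 0.7, 0.25)) # saturated green
  expect_equal(collagen_fraction(slide, roi), 30.0)
  # no green pixels
  expect_equal(collagen_fraction(make_slide(), roi), 0)
  # exclusion covering all green pixels drops the fraction to zero
  expect_equal(collagen_fraction(slide, roi, exclusion = green_sel), 0)
})

test_that("air fraction recovers an exact constructed percentage", {
  slide <- make_slide()
  roi <- matrix(FALSE, 90, 60); roi[1:40, 1:30] <- TRUE # 1200 px
  white_sel <- matrix(FALSE, 90, 60); white_sel[1:20, 1:30] <- TRUE # 50%
  slide <- paint(slide, white_sel, c(0.95, 0.95, 0.97))
  expect_equal(air_fraction(slide, roi), 50.0)
  # fully stained ROI has no air
  expect_equal(air_fraction(make_slide(), roi), 0)
  # white pixels only inside excluded vessels do not count
  expect_equal(air_fraction(slide, roi, exclusion = white_sel), 0)
})

test_that("colour rules select disjoint pixel sets on the fixtures", {
  slide <- make_slide()
  sel_g <- matrix(FALSE, 90, 60); sel_g[1:10, ] <- TRUE
  sel_w <- matrix(FALSE, 90, 60); sel_w[11:20, ] <- TRUE
  slide <- paint(slide, sel_g, c(0.2, 0.7, 0.25))
  slide <- paint(slide, sel_w, c(0.95, 0.95, 0.97))
  g <- green_rule()(slide)
  w <- white_rule()(slide)
  expect_false(any(g & w))
  expect_equal(sum(g), sum(sel_g))
  expect_equal(sum(w), sum(sel_w))
})

test_that("fractions are invariant to ROI-preserving translation", {
  slide <- make_slide()
  roi <- matrix(FALSE, 90, 60); roi[10:49, 10:39] <- TRUE
  gr <- matrix(FALSE, 90, 60); gr[10:21, 10:39] <- TRUE # 30%
  slide <- paint(slide, gr, c(0.2, 0.7, 0.25))
  f0 <- collagen_fraction(slide, roi)
  # translate image, ROI and green region by (5, 5)
  sh <- function(m) { out <- m; out[] <- FALSE; out[6:90, 6:60] <- m[1:85, 1:55]; out }
  slide2 <- make_slide()
  slide2 <- paint(slide2, sh(gr), c(0.2, 0.7, 0.25))
  expect_equal(collagen_fraction(slide2, sh(roi)), f0)
})

test_that("slides round-trip through PNG and the table reports all ROIs", {
  slide <- make_slide(30, 24)
  sel <- matrix(FALSE, 30, 24); sel[1:10, ] <- TRUE
  slide <- paint(slide, sel, c(0.2, 0.7, 0.25))
  path <- tempfile(fileext = ".png")
  png::writePNG(slide, path)
  back <- read_slide(path)
  expect_equal(dim(back)[1:2], c(30, 24))
  mask <- matrix(1L, 30, 24)
  tab <- histomorphometry_table(list(s1 = list(slide = back, mask = mask)))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$roi, c("upper", "middle", "lower"))
  expect_true(all(tab$collagen_pct >= 0 & tab$collagen_pct <= 100))
})
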