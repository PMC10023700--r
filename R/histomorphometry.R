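#' Colour rule for green-stained collagen
#'
#' Pixels count as collagen when their hue lies in the green band and both
#' saturation and value clear minimum levels. Colour thresholds are
#' inherently specific to the staining and scanning protocol, so these
#' defaults require calibration against the protocol in use.
#'
#' @param hue_min,hue_max hue band in degrees (default 80-160).
#' @param min_saturation minimum HSV saturation (default 0.15).
#' @param min_value minimum HSV value (default 0.2).
#' @return A `colour_rule` function of an RGB array.
#' @export
green_rule <- function(hue_min = 80, hue_max = 160, min_saturation = 0.15,
                       min_value = 0.2) {
  structure(function(rgb) {
    hsv <- rgb2hsv(rbind(as.numeric(rgb[, , 1]), as.numeric(rgb[, , 2]),
                         as.numeric(rgb[, , 3])), maxColorValue = 1)
    hue <- hsv[1, ] * 360
    matrix(hue >= hue_min & hue <= hue_max & hsv[2, ] >= min_saturation &
             hsv[3, ] >= min_value, nrow = dim(rgb)[1])
  }, class = "colour_rule", kind = "green")
}

#' Colour rule for alveolar air (white threshold)
#'
#' Pixels count as air when every RGB channel is at least `min_channel` of
#' full scale.
#'
#' @param min_channel minimum per-channel level in \[0, 1\] (default 0.85).
#' @return A `colour_rule` function of an RGB array.
#' @export
white_rule <- function(min_channel = 0.85) {
  structure(function(rgb) {
    rgb[, , 1] >= min_channel & rgb[, , 2] >= min_channel &
      rgb[, , 3] >= min_channel
  }, class = "colour_rule", kind = "white")
}

#' Split a 2D left-lung mask into three ROIs of equal vertical extent
#'
#' The mask's bounding row range is cut into three slabs of equal row count,
#' remainder to the upper slabs — the 2D analogue of [split_regions()]
#' thirds.
#'
#' @param lung_mask_2d logical or 0/1 matrix (rows = vertical axis).
#' @return Integer matrix of ROI labels (0 outside, 1 upper, 2 middle,
#'   3 lower).
#' @export
split_slide_rois <- function(lung_mask_2d) {
  m <- lung_mask_2d != 0
  if (!any(m)) stop("mask is empty", call. = FALSE)
  rows <- which(apply(m, 1, any))
  extent <- max(rows) - min(rows) + 1L
  if (extent < 3L) stop("mask vertical extent is shorter than 3 pixels", call. = FALSE)
  base <- extent %/% 3L
  rem <- extent %% 3L
  sizes <- rep(base, 3L) + c(rep(1L, rem), rep(0L, 3L - rem))
  bounds <- min(rows) + cumsum(c(0L, sizes))
  lab <- matrix(0L, nrow = nrow(m), ncol = ncol(m))
  ri <- row(m)
  for (r in 1:3) lab[m & ri >= bounds[r] & ri < bounds[r + 1]] <- r
  lab
}

roi_fraction <- function(slide, roi, exclusion, rule) {
  if (length(dim(slide)) != 3L || dim(slide)[3] < 3L)
    stop("slide must be an RGB array", call. = FALSE)
  sel <- roi != 0
  if (!is.null(exclusion)) sel <- sel & !(exclusion != 0)
  if (!any(sel)) stop("ROI is empty after exclusion", call. = FALSE)
  hit <- rule(slide[, , 1:3, drop = FALSE])
  100 * sum(hit & sel) / sum(sel)
}

#' Collagen area fraction within an ROI
#'
#' Percent of ROI pixels (after subtracting the bronchus/vessel exclusion
#' mask) that satisfy the green-stain rule. The fraction is scale-invariant,
#' so pixel area metadata is not needed.
#'
#' @param slide RGB array `[rows, cols, 3]` with channels in \[0, 1\].
#' @param roi 0/1 or logical matrix selecting the ROI.
#' @param exclusion optional 0/1 matrix of pixels to exclude (bronchi,
#'   vessels).
#' @param rule a `colour_rule` (default [green_rule()]).
#' @return Percentage in \[0, 100\].
#' @export
collagen_fraction <- function(slide, roi, exclusion = NULL,
                              rule = green_rule()) {
  roi_fraction(slide, roi, exclusion, rule)
}

#' Alveolar air area fraction within an ROI
#'
#' As [collagen_fraction()] but with the white threshold rule.
#'
#' @inheritParams collagen_fraction
#' @param rule a `colour_rule` (default [white_rule()]).
#' @return Percentage in \[0, 100\].
#' @export
air_fraction <- function(slide, roi, exclusion = NULL, rule = white_rule()) {
  roi_fraction(slide, roi, exclusion, rule)
}

#' Read an RGB slide image (PNG or TIFF)
#'
#' @param path image path.
#' @return Numeric array `[rows, cols, channels]` with values in \[0, 1\].
#' @export
read_slide <- function(path) {
  lower <- tolower(path)
  img <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path)
  } else stop("unsupported slide format: ", path, call. = FALSE)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  img
}

#' Histomorphometry table for a set of slides
#'
#' Applies [split_slide_rois()] per slide and reports collagen and air
#' fractions per ROI.
#'
#' @param slides named list; each element is a list with `slide` (RGB
#'   array), `mask` (2D left-lung mask) and optional `exclusion`.
#' @param rule_green,rule_white colour rules.
#' @return Data frame with columns `slide_id, roi, collagen_pct, air_pct`.
#' @export
histomorphometry_table <- function(slides, rule_green = green_rule(),
                                   rule_white = white_rule()) {
  rows <- list()
  roi_names <- c("upper", "middle", "lower")
  for (id in names(slides)) {
    s <- slides[[id]]
    lab <- split_slide_rois(s$mask)
    for (r in 1:3) {
      roi <- lab == r
      rows[[length(rows) + 1L]] <- data.frame(
        slide_id = id, roi = roi_names[r],
        collagen_pct = collagen_fraction(s$slide, roi, s$exclusion, rule_green),
        air_pct = air_fraction(s$slide, roi, s$exclusion, rule_white),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
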