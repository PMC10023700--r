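#' Grey-level to Hounsfield-unit calibration specification
#'
#' Micro-CT reconstructions come in scanner-specific grey levels; conversion
#' to Hounsfield Units (HU) is the affine map sending the grey level of air to
#' `hu_air` and the grey level of water to `hu_water`. The defaults follow the
#' standard HU convention (air = -1000, water = 0), which is the convention
#' under which the specific-gas-volume formula `1000 / (HU + 1000)` assigns
#' water a specific volume of 1 ml/g. The scanner grey-level anchors have no
#' universal default and must be supplied per acquisition.
#'
#' @param raw_air grey level imaged for air.
#' @param raw_water grey level imaged for water.
#' @param hu_air HU value assigned to air (default -1000).
#' @param hu_water HU value assigned to water (default 0).
#' @return A `calibration_spec` object.
#' @export
calibration_spec <- function(raw_air, raw_water, hu_air = -1000, hu_water = 0) {
  if (!is.finite(raw_air) || !is.finite(raw_water))
    stop("calibration anchors must be finite", call. = FALSE)
  if (raw_air == raw_water)
    stop("degenerate calibration: raw_air == raw_water", call. = FALSE)
  if (hu_air == hu_water)
    stop("degenerate calibration: hu_air == hu_water", call. = FALSE)
  structure(list(raw_air = raw_air, raw_water = raw_water,
                 hu_air = hu_air, hu_water = hu_water),
            class = "calibration_spec")
}

#' Convert a raw grey-level volume to Hounsfield Units
#'
#' Applies the voxel-wise affine map defined by a [calibration_spec()]:
#' `HU = hu_air + (raw - raw_air) * (hu_water - hu_air) / (raw_water - raw_air)`.
#'
#' @param raw an [image_volume()] with unit `"raw"`.
#' @param cal a [calibration_spec()].
#' @return An [image_volume()] with unit `"HU"`.
#' @export
grey_to_hu <- function(raw, cal) {
  stopifnot_unit(raw, "raw")
  if (!inherits(cal, "calibration_spec"))
    stop("cal must be a calibration_spec", call. = FALSE)
  slope <- (cal$hu_water - cal$hu_air) / (cal$raw_water - cal$raw_air)
  hu <- cal$hu_air + (raw$data - cal$raw_air) * slope
  if (any(!is.finite(hu))) stop("non-finite HU values after calibration", call. = FALSE)
  image_volume(hu, spacing = raw$spacing, origin = raw$origin, unit = "HU")
}

#' Re-encode an HU volume into scanner grey levels
#'
#' Inverse of [grey_to_hu()]; used by the phantom generator so that the
#' calibration stage is exercised by synthetic data.
#'
#' @param hu an [image_volume()] with unit `"HU"`.
#' @param cal a [calibration_spec()].
#' @return An [image_volume()] with unit `"raw"`.
#' @export
hu_to_grey <- function(hu, cal) {
  stopifnot_unit(hu, "HU")
  slope <- (cal$raw_water - cal$raw_air) / (cal$hu_water - cal$hu_air)
  raw <- cal$raw_air + (hu$data - cal$hu_air) * slope
  image_volume(raw, spacing = hu$spacing, origin = hu$origin, unit = "raw")
}
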