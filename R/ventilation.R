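#' Specific gas volume constants
#'
#' `sv_tissue` is the specific volume of lung tissue, taken as the inverse of
#' the standard soft-tissue density 1.065 g/ml, i.e. 1/1.065 = 0.939 ml/g.
#' `hu_floor` clamps HU values before conversion: the specific-volume formula
#' `1000 / (HU + 1000)` is singular at -1000 HU, so voxels approaching pure
#' air are clamped (the number of clamped voxels is reported).
#'
#' @param sv_tissue specific volume of tissue in ml/g (default `1/1.065`).
#' @param hu_floor lower HU clamp, must exceed -1000 (default -990).
#' @return An `svg_constants` object.
#' @export
svg_constants <- function(sv_tissue = 1 / 1.065, hu_floor = -990) {
  if (!is.finite(sv_tissue) || sv_tissue <= 0)
    stop("sv_tissue must be positive", call. = FALSE)
  if (!is.finite(hu_floor) || hu_floor <= -1000)
    stop("hu_floor must be greater than -1000 HU", call. = FALSE)
  structure(list(sv_tissue = sv_tissue, hu_floor = hu_floor),
            class = "svg_constants")
}

#' Total specific volume of tissue plus gas
#'
#' `SV_tissueandgas (ml/g) = 1000 / (HU + 1000)`, the inverse of the density
#' implied by the HU scale. Values are clamped at `hu_floor` first, which
#' makes the result finite and strictly decreasing in HU.
#'
#' @param hu numeric vector or array of HU values.
#' @param consts an [svg_constants()].
#' @return Specific volume in ml/g, same shape as `hu`.
#' @export
sv_total <- function(hu, consts = svg_constants()) {
  hu <- pmax(hu, consts$hu_floor)
  1000 / (hu + 1000)
}

#' Specific gas volume map
#'
#' Inside the lung mask, `SVg = SV_tissueandgas - SV_tissue` (ml of gas per
#' gram of tissue). Voxels outside the mask are set to `NA`, the sentinel
#' excluded from all downstream statistics. The number of voxels clamped at
#' `hu_floor` is recorded in the `clamped` attribute.
#'
#' @param vol an [image_volume()] with unit `"HU"`.
#' @param mask a [lung_mask()] on the same grid.
#' @param consts an [svg_constants()].
#' @return An [image_volume()] with unit `"SVg"`.
#' @export
svg_map <- function(vol, mask, consts = svg_constants()) {
  stopifnot_unit(vol, "HU")
  stopifnot_same_grid(vol, mask, "volume and mask")
  inmask <- mask_logical(mask)
  out <- array(NA_real_, dim = dim(vol$data))
  hu <- vol$data[inmask]
  clamped <- sum(hu < consts$hu_floor)
  out[inmask] <- sv_total(hu, consts) - consts$sv_tissue
  res <- image_volume(out, spacing = vol$spacing, origin = vol$origin, unit = "SVg")
  attr(res, "clamped") <- clamped
  res
}

#' Voxel-wise ventilation map (dSVg)
#'
#' `dSVg = SVg_insp - SVg_exp`, computed voxel by voxel on the inspiratory
#' grid (the expiratory SVg volume must already be warped onto it). Negative
#' values are preserved: clipping would bias regional medians. The analysis
#' domain is the inspiratory lung mask intersected with the voxels where both
#' SVg volumes are defined; excluded voxels are counted in the `excluded`
#' attribute.
#'
#' @param svg_insp inspiratory [image_volume()] (unit `"SVg"`).
#' @param svg_exp_warped expiratory SVg volume warped onto the inspiratory
#'   grid (unit `"SVg"`).
#' @param mask_insp inspiratory [lung_mask()].
#' @return An [image_volume()] with unit `"dSVg"`; `NA` outside the domain.
#' @export
ventilation_map <- function(svg_insp, svg_exp_warped, mask_insp) {
  stopifnot_unit(svg_insp, "SVg")
  stopifnot_unit(svg_exp_warped, "SVg")
  stopifnot_same_grid(svg_insp, svg_exp_warped, "SVg volumes")
  stopifnot_same_grid(svg_insp, mask_insp, "volume and mask")
  inmask <- mask_logical(mask_insp)
  out <- array(NA_real_, dim = dim(svg_insp$data))
  d <- svg_insp$data - svg_exp_warped$data
  out[inmask] <- d[inmask]
  res <- image_volume(out, spacing = svg_insp$spacing, origin = svg_insp$origin,
                      unit = "dSVg")
  attr(res, "excluded") <- sum(inmask & is.na(d))
  res
}
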