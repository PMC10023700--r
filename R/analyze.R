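#' Run the paired-phase analysis chain on in-memory volumes
#'
#' Convenience wrapper over the full single-subject chain: grey-level
#' calibration, optional denoising (plain smoothing feeds the registration;
#' mask-normalized smoothing feeds the quantitative path), Demons
#' registration of the expiratory onto the inspiratory volume, warping, SVg
#' conversion and dSVg ventilation mapping. The analysis domain is the
#' inspiratory lung mask intersected with the warped expiratory mask.
#'
#' @param insp_raw,exp_raw inspiratory and expiratory grey-level volumes
#'   (unit `"raw"`), or HU volumes (unit `"HU"`) in which case `calibration`
#'   is not needed.
#' @param mask_insp inspiratory [lung_mask()].
#' @param mask_exp expiratory [lung_mask()] (optional but recommended).
#' @param calibration a [calibration_spec()] (required for raw inputs).
#' @param denoise_sigma Gaussian noise-control sigma in voxels (0 disables).
#' @param landmarks optional `landmark_set` for TRE reporting.
#' @param registration list of [demons_register()] arguments
#'   (`levels`, `iterations`, `smoothing_sigma`).
#' @param consts an [svg_constants()].
#' @return A list with `hu_insp`, `svg_insp`, `svg_exp`, `dsvg`, `domain`,
#'   `field` and `report`.
#' @export
analyze_pair <- function(insp_raw, exp_raw, mask_insp, mask_exp = NULL,
                         calibration = NULL, denoise_sigma = 0,
                         landmarks = NULL,
                         registration = list(levels = 4,
                                             iterations = c(100, 100, 50, 25),
                                             smoothing_sigma = 1.5),
                         consts = svg_constants()) {
  to_hu <- function(v) {
    if (identical(v$unit, "HU")) return(v)
    if (is.null(calibration))
      stop("raw input volumes require a calibration_spec", call. = FALSE)
    grey_to_hu(v, calibration)
  }
  insp <- to_hu(insp_raw)
  expv <- to_hu(exp_raw)
  insp_reg <- insp; expv_reg <- expv
  if (denoise_sigma > 0) {
    insp_reg <- gaussian_denoise(insp, denoise_sigma)
    expv_reg <- gaussian_denoise(expv, denoise_sigma)
    insp <- gaussian_denoise(insp, denoise_sigma, mask = mask_insp)
    expv <- if (!is.null(mask_exp))
      gaussian_denoise(expv, denoise_sigma, mask = mask_exp) else expv_reg
  }
  reg <- demons_register(insp_reg, expv_reg,
                         levels = registration$levels,
                         iterations = registration$iterations,
                         smoothing_sigma = registration$smoothing_sigma,
                         mask = mask_insp, landmarks = landmarks)
  exp_warped <- warp(expv, reg$field, "linear")
  domain <- mask_insp
  if (!is.null(mask_exp)) {
    mask_exp_w <- warp(mask_exp, reg$field, "nearest")
    keep <- mask_logical(mask_insp) & mask_logical(mask_exp_w)
    domain <- lung_mask(array(as.integer(keep), dim = dim(keep)),
                        spacing = mask_insp$spacing, origin = mask_insp$origin)
  }
  svg_insp <- svg_map(insp, domain, consts)
  svg_exp <- svg_map(exp_warped, domain, consts)
  dsvg <- ventilation_map(svg_insp, svg_exp, domain)
  list(hu_insp = insp, svg_insp = svg_insp, svg_exp = svg_exp, dsvg = dsvg,
       domain = domain, field = reg$field, report = reg$report)
}

#' Run the analysis chain with a known deformation field
#'
#' As [analyze_pair()] but skipping registration: the supplied field (for
#' example a phantom's analytic ground-truth deformation) is used to warp
#' the expiratory volume. Useful for isolating downstream stages from
#' registration error, e.g. when deriving control-cohort thresholds whose
#' construction does not depend on registration accuracy.
#'
#' @inheritParams analyze_pair
#' @param field a [deformation_field()] on the inspiratory grid.
#' @return As [analyze_pair()], without a registration report.
#' @export
analyze_pair_with_field <- function(insp_raw, exp_raw, mask_insp, field,
                                    mask_exp = NULL, calibration = NULL,
                                    denoise_sigma = 0,
                                    consts = svg_constants()) {
  to_hu <- function(v) {
    if (identical(v$unit, "HU")) return(v)
    if (is.null(calibration))
      stop("raw input volumes require a calibration_spec", call. = FALSE)
    grey_to_hu(v, calibration)
  }
  insp <- to_hu(insp_raw)
  expv <- to_hu(exp_raw)
  if (denoise_sigma > 0) {
    insp <- gaussian_denoise(insp, denoise_sigma, mask = mask_insp)
    expv <- if (!is.null(mask_exp))
      gaussian_denoise(expv, denoise_sigma, mask = mask_exp)
    else gaussian_denoise(expv, denoise_sigma)
  }
  exp_warped <- warp(expv, field, "linear")
  domain <- mask_insp
  if (!is.null(mask_exp)) {
    mask_exp_w <- warp(mask_exp, field, "nearest")
    keep <- mask_logical(mask_insp) & mask_logical(mask_exp_w)
    domain <- lung_mask(array(as.integer(keep), dim = dim(keep)),
                        spacing = mask_insp$spacing, origin = mask_insp$origin)
  }
  svg_insp <- svg_map(insp, domain, consts)
  svg_exp <- svg_map(exp_warped, domain, consts)
  dsvg <- ventilation_map(svg_insp, svg_exp, domain)
  list(hu_insp = insp, svg_insp = svg_insp, svg_exp = svg_exp, dsvg = dsvg,
       domain = domain, field = field, report = NULL)
}

#' Pool in-mask voxel values across analyzed subjects
#'
#' @param results list of [analyze_pair()] results.
#' @param what one of `"svg_insp"`, `"svg_exp"`, `"dsvg"`.
#' @return Numeric vector of pooled in-domain voxel values.
#' @export
pool_values <- function(results, what = c("svg_insp", "svg_exp", "dsvg")) {
  what <- match.arg(what)
  unlist(lapply(results, function(r) {
    v <- r[[what]]$data[mask_logical(r$domain)]
    v[!is.na(v)]
  }), use.names = FALSE)
}
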