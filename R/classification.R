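#' Derive functional classification thresholds from a control cohort
#'
#' The "normal" thresholds are defined on the pooled in-mask voxel values of
#' saline-treated control animals: `alpha_I` and `alpha_E` are the 5th
#' percentiles of the inspiratory and expiratory SVg distributions, and
#' `beta` is the 25th percentile of the dSVg distribution. Percentiles use
#' linear interpolation between order statistics (type 7); thresholds are
#' always recomputed per cohort, never shipped as constants.
#'
#' @param svg_insp_samples,svg_exp_samples,dsvg_samples numeric vectors of
#'   pooled in-mask voxel values (NAs dropped).
#' @param p_alpha percentile level for the SVg thresholds (default 5).
#' @param p_beta percentile level for the dSVg threshold (default 25).
#' @param cohort_id provenance label for the pool.
#' @return A `functional_thresholds` object with fields `alpha_I`, `alpha_E`,
#'   `beta`, the percentile levels, cohort id and pool sizes.
#' @export
derive_thresholds <- function(svg_insp_samples, svg_exp_samples, dsvg_samples,
                              p_alpha = 5, p_beta = 25,
                              cohort_id = "saline") {
  pools <- list(insp = svg_insp_samples, exp = svg_exp_samples,
                dsvg = dsvg_samples)
  pools <- lapply(pools, function(x) as.numeric(x[!is.na(x)]))
  if (any(vapply(pools, length, 1L) == 0L))
    stop("every sample pool must be non-empty", call. = FALSE)
  if (p_alpha <= 0 || p_alpha >= 100 || p_beta <= 0 || p_beta >= 100)
    stop("percentile levels must lie in (0, 100)", call. = FALSE)
  structure(list(
    alpha_I = unname(quantile(pools$insp, p_alpha / 100, type = 7)),
    alpha_E = unname(quantile(pools$exp, p_alpha / 100, type = 7)),
    beta = unname(quantile(pools$dsvg, p_beta / 100, type = 7)),
    p_alpha = p_alpha, p_beta = p_beta, cohort_id = cohort_id,
    n_voxels = vapply(pools, length, 1L),
    percentile_type = 7L), class = "functional_thresholds")
}

#' @export
print.functional_thresholds <- function(x, ...) {
  cat(sprintf("<functional_thresholds> alpha_I = %.4f, alpha_E = %.4f, beta = %.4f ml/g (p%g/p%g, cohort %s)\n",
              x$alpha_I, x$alpha_E, x$beta, x$p_alpha, x$p_beta, x$cohort_id))
  invisible(x)
}

FMAP_LEVELS <- c(outside = 0L, F = 1L, LV = 2L, NV = 3L)

#' Voxel-wise functional classification
#'
#' Each in-mask voxel is sorted into three classes: fibrosis (F) when the
#' inspiratory SVg is below `alpha_I` AND the expiratory SVg is below
#' `alpha_E`; otherwise low ventilation (LV) when `dSVg < beta`; otherwise
#' normal ventilation (NV, `dSVg >= beta`). Strict inequalities for F and LV,
#' the boundary belongs to NV. Voxels with exactly one SVg value below its
#' alpha threshold do not meet the F definition and are assigned by the dSVg
#' rule, which guarantees a total partition; their fraction is recorded in
#' the `mixed_margin_fraction` attribute for QC.
#'
#' @param svg_insp,svg_exp inspiratory and (warped) expiratory SVg volumes.
#' @param dsvg the [ventilation_map()] output.
#' @param thresholds a `functional_thresholds` object.
#' @param mask the inspiratory [lung_mask()] defining the analysis domain.
#' @return A `functional_map`: an [image_volume()] with unit `"label"` and
#'   levels 0 = outside, 1 = F, 2 = LV, 3 = NV, carrying the thresholds as
#'   provenance.
#' @export
classify_voxels <- function(svg_insp, svg_exp, dsvg, thresholds, mask) {
  stopifnot_unit(svg_insp, "SVg")
  stopifnot_unit(svg_exp, "SVg")
  stopifnot_unit(dsvg, "dSVg")
  stopifnot_same_grid(svg_insp, svg_exp, "SVg volumes")
  stopifnot_same_grid(svg_insp, dsvg, "SVg and dSVg volumes")
  stopifnot_same_grid(svg_insp, mask, "volumes and mask")
  if (!inherits(thresholds, "functional_thresholds")) {
    warning("thresholds lack provenance (not a functional_thresholds object)")
    thresholds <- structure(as.list(thresholds), class = "functional_thresholds")
  }
  inmask <- mask_logical(mask) & !is.na(dsvg$data) &
    !is.na(svg_insp$data) & !is.na(svg_exp$data)
  lab <- array(FMAP_LEVELS[["outside"]], dim = dim(mask$data))
  below_i <- svg_insp$data < thresholds$alpha_I
  below_e <- svg_exp$data < thresholds$alpha_E
  is_f <- inmask & below_i & below_e
  is_lv <- inmask & !is_f & (dsvg$data < thresholds$beta)
  is_nv <- inmask & !is_f & !is_lv
  lab[is_f] <- FMAP_LEVELS[["F"]]
  lab[is_lv] <- FMAP_LEVELS[["LV"]]
  lab[is_nv] <- FMAP_LEVELS[["NV"]]
  out <- image_volume(lab, spacing = mask$spacing, origin = mask$origin,
                      unit = "label")
  class(out) <- c("functional_map", class(out))
  attr(out, "thresholds") <- thresholds
  mixed <- inmask & !is_f & (below_i != below_e)
  attr(out, "mixed_margin_fraction") <- sum(mixed) / max(sum(inmask), 1L)
  out
}

#' Per-class volume percentages of a functional map
#'
#' Percent volume of F, LV and NV among the in-region voxels of a functional
#' map; the three percentages sum to 100 exactly.
#'
#' @param fmap a `functional_map` from [classify_voxels()].
#' @param region_mask optional [lung_mask()] restricting the region (defaults
#'   to all classified voxels).
#' @return Named numeric vector `c(pctF, pctLV, pctNV)`.
#' @export
class_percentages <- function(fmap, region_mask = NULL) {
  if (!inherits(fmap, "functional_map"))
    stop("expected a functional_map", call. = FALSE)
  sel <- fmap$data != FMAP_LEVELS[["outside"]]
  if (!is.null(region_mask)) {
    stopifnot_same_grid(fmap, region_mask, "map and region mask")
    sel <- sel & mask_logical(region_mask)
  }
  n <- sum(sel)
  if (n == 0L) stop("region contains no classified voxels", call. = FALSE)
  v <- fmap$data[sel]
  c(pctF = 100 * sum(v == FMAP_LEVELS[["F"]]) / n,
    pctLV = 100 * sum(v == FMAP_LEVELS[["LV"]]) / n,
    pctNV = 100 * sum(v == FMAP_LEVELS[["NV"]]) / n)
}

#' Serialize thresholds to JSON
#' @param thresholds a `functional_thresholds` object.
#' @param path output JSON path.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read thresholds from JSON
#' @param path JSON file written by [write_thresholds()].
#' @return A `functional_thresholds` object.
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "functional_thresholds")
}

#' Write a functional map as an 8-bit label volume with a JSON legend
#' @param fmap a `functional_map`.
#' @param path output volume path (`.nii`, `.nii.gz`, `.mha`, `.mhd`); the
#'   legend is written next to it as `<path>.legend.json`.
#' @export
write_functional_map <- function(fmap, path) {
  write_volume(fmap, path)
  legend <- list(levels = as.list(FMAP_LEVELS),
                 thresholds = unclass(attr(fmap, "thresholds")))
  jsonlite::write_json(legend, paste0(path, ".legend.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
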