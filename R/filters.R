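#' Laplacian structure filter
#'
#' Computes the discrete 3D Laplacian (7-point stencil, second differences
#' per axis divided by the squared spacing, edge values replicated). The
#' response emphasizes structural boundaries over absolute intensity, which
#' is why it precedes the Demons similarity computation: lung intensity
#' changes globally with inflation while anatomical structure does not. The
#' output is tagged `"raw"` since it is no longer on the HU scale.
#'
#' @param vol an [image_volume()] with unit `"HU"`.
#' @return An [image_volume()] (unit `"raw"`) with the Laplacian response,
#'   in HU per square micrometre.
#' @export
laplacian_preprocess <- function(vol) {
  stopifnot_unit(vol, "HU")
  out <- .laplacian_c(vol$data, dim(vol$data), vol$spacing)
  image_volume(out, spacing = vol$spacing, origin = vol$origin, unit = "raw")
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with per-axis standard deviation given in voxel
#' units (reflective boundaries). Used for noise control before quantitative
#' mapping; the unit tag is preserved.
#'
#' When a mask is supplied, smoothing is mask-normalized (normalized
#' convolution): each in-mask voxel averages only in-mask neighbours, so
#' parenchymal values are never contaminated by the much denser tissue
#' outside the lung boundary. Out-of-mask voxels receive the plain smoothed
#' value.
#'
#' @param vol an [image_volume()].
#' @param sigma_vox standard deviation in voxels (scalar or length 3).
#' @param mask optional [lung_mask()] for mask-normalized smoothing.
#' @return The smoothed [image_volume()].
#' @export
gaussian_denoise <- function(vol, sigma_vox, mask = NULL) {
  if (!is_image_volume(vol)) stop("expected an image_volume", call. = FALSE)
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  if (any(sigma_vox < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (all(sigma_vox == 0)) return(vol)
  d <- dim(vol$data)
  plain <- .gaussian_smooth_c(vol$data, d, as.numeric(sigma_vox))
  if (is.null(mask)) {
    out <- plain
  } else {
    stopifnot_same_grid(vol, mask, "volume and mask")
    m <- array(as.numeric(mask_logical(mask)), dim = d)
    num <- .gaussian_smooth_c(vol$data * m, d, as.numeric(sigma_vox))
    den <- .gaussian_smooth_c(m, d, as.numeric(sigma_vox))
    out <- plain
    inm <- m != 0
    out[inm] <- num[inm] / pmax(den[inm], 1e-12)
  }
  image_volume(out, spacing = vol$spacing, origin = vol$origin, unit = vol$unit)
}
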