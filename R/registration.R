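#' Dense deformation field on the fixed (inspiratory) grid
#'
#' Maps a fixed-grid physical point `p` to the corresponding moving-image
#' point `p + u(p)`; displacements are stored per voxel in micrometres.
#'
#' @param u 4D numeric array `[nx, ny, nz, 3]` of displacement components.
#' @param spacing,origin grid metadata of the fixed volume (micrometres).
#' @return A `deformation_field` object.
#' @export
deformation_field <- function(u, spacing, origin = c(0, 0, 0)) {
  d <- dim(u)
  if (length(d) != 4L || d[4] != 3L)
    stop("deformation field must be a [nx, ny, nz, 3] array", call. = FALSE)
  if (any(!is.finite(u))) stop("deformation field must be finite", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(u = u, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$u)
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<deformation_field> %d x %d x %d voxels, |u| mean %.1f um, max %.1f um\n",
              d[1], d[2], d[3], mean(mag), max(mag)))
  invisible(x)
}

field_grid_matches <- function(field, vol, tol = 1e-6) {
  identical(dim(field$u)[1:3], dim(vol$data)) &&
    all(abs(field$spacing - vol$spacing) < tol) &&
    all(abs(field$origin - vol$origin) < tol)
}

#' Demons deformable registration of the expiratory onto the inspiratory image
#'
#' Symmetric-forces Thirion Demons with Gaussian field regularization and a
#' multiresolution pyramid (default four levels, downsampled by two per
#' level). Both inputs are internally pre-processed with
#' [laplacian_preprocess()] once at full resolution, and each filtered image
#' is normalized to unit standard deviation, so the similarity is driven by
#' structure rather than by the global intensity change that accompanies lung
#' inflation. The returned field applies to the unfiltered HU volumes.
#'
#' @param fixed inspiratory [image_volume()] (unit `"HU"`).
#' @param moving expiratory [image_volume()] (unit `"HU"`, same spacing).
#' @param levels number of pyramid levels (default 4).
#' @param iterations iterations per level, coarse to fine
#'   (default `c(100, 100, 50, 25)`).
#' @param smoothing_sigma Gaussian regularization of the field after each
#'   iteration, in voxels (default 1.5).
#' @param mask optional fixed-grid [lung_mask()] used only for reporting the
#'   final in-mask mean squared intensity difference.
#' @param landmarks optional `landmark_set`; when given, the report carries
#'   the target registration error before and after registration.
#' @return A list with elements `field` (a [deformation_field()]) and
#'   `report` (per-level iterations and mean squared difference on the
#'   filtered scale, plus TRE summaries when landmarks are supplied).
#' @export
demons_register <- function(fixed, moving, levels = 4,
                            iterations = c(100, 100, 50, 25),
                            smoothing_sigma = 1.5, mask = NULL,
                            landmarks = NULL) {
  stopifnot_unit(fixed, "HU")
  stopifnot_unit(moving, "HU")
  if (any(abs(fixed$spacing - moving$spacing) > 1e-6))
    stop("fixed and moving volumes must share voxel spacing", call. = FALSE)
  if (levels < 1) stop("at least one pyramid level is required", call. = FALSE)
  if (length(iterations) != levels)
    stop("iterations must give one count per level (coarse to fine)", call. = FALSE)
  if (any(iterations <= 0)) stop("iteration counts must be positive", call. = FALSE)

  f_lap <- laplacian_preprocess(fixed)
  m_lap <- laplacian_preprocess(moving)
  res <- .demons_core_c(f_lap$data, m_lap$data, dim(fixed$data), fixed$spacing,
                        as.integer(levels), as.integer(iterations),
                        as.numeric(smoothing_sigma))
  d <- dim(fixed$data)
  u <- array(0, dim = c(d, 3L))
  u[, , , 1] <- res$u1; u[, , , 2] <- res$u2; u[, , , 3] <- res$u3
  field <- deformation_field(u, spacing = fixed$spacing, origin = fixed$origin)

  report <- list(levels = levels,
                 iterations = as.integer(res$level_iterations),
                 level_mse = as.numeric(res$level_mse),
                 smoothing_sigma = smoothing_sigma)
  warped <- warp(moving, field, interpolation = "linear")
  report$out_of_domain <- attr(warped, "out_of_domain")
  diff2 <- (warped$data - fixed$data)^2
  report$final_mse <- if (!is.null(mask)) mean(diff2[mask_logical(mask)]) else mean(diff2)
  if (!is.null(landmarks)) {
    report$tre_before <- target_registration_error(landmarks, field = NULL)
    report$tre_after <- target_registration_error(landmarks, field = field)
  }
  list(field = field, report = report)
}

#' Apply a deformation field to a volume or mask
#'
#' Resamples the moving image on the fixed grid: the output voxel at physical
#' point `p` takes the moving-image value at `p + u(p)`. Intensity volumes
#' use trilinear interpolation; masks and label maps must use nearest
#' neighbour (which keeps them strictly categorical). Out-of-domain samples
#' take the moving image's edge value and are counted in the
#' `out_of_domain` attribute.
#'
#' @param moving an [image_volume()] (any unit).
#' @param field a [deformation_field()] on the fixed grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return An [image_volume()] on the fixed grid, same unit as `moving`,
#'   with attribute `out_of_domain`.
#' @export
warp <- function(moving, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!inherits(field, "deformation_field"))
    stop("field must be a deformation_field", call. = FALSE)
  if (!is_image_volume(moving)) stop("expected an image_volume", call. = FALSE)
  if (moving$unit %in% c("mask", "label") && interpolation != "nearest")
    stop("masks and label maps must be warped with nearest-neighbour interpolation",
         call. = FALSE)
  fd <- dim(field$u)[1:3]
  res <- .warp_c(moving$data, dim(moving$data), moving$spacing, moving$origin,
                 fd, field$spacing, field$origin,
                 field$u[, , , 1], field$u[, , , 2], field$u[, , , 3],
                 interpolation == "nearest")
  out <- image_volume(res$data, spacing = field$spacing, origin = field$origin,
                      unit = moving$unit)
  attr(out, "out_of_domain") <- res$out_of_domain
  out
}

#' Landmark target registration error
#'
#' With no field, the TRE of a pair is the Euclidean distance between its
#' fixed and moving points (pre-registration error). With a field, the fixed
#' point is mapped through the field (displacement trilinearly interpolated
#' at the fixed point's physical position) before measuring the distance to
#' the moving point.
#'
#' @param landmarks a `landmark_set`.
#' @param field optional [deformation_field()].
#' @return A list with `distances` (micrometres, per pair), `mean` and `sd`.
#' @export
target_registration_error <- function(landmarks, field = NULL) {
  if (!inherits(landmarks, "landmark_set"))
    stop("expected a landmark_set", call. = FALSE)
  fx <- as.matrix(as.data.frame(landmarks)[c("fx", "fy", "fz")])
  mx <- as.matrix(as.data.frame(landmarks)[c("mx", "my", "mz")])
  mapped <- fx
  if (!is.null(field)) {
    fd <- dim(field$u)[1:3]
    for (cmp in 1:3) {
      mapped[, cmp] <- fx[, cmp] +
        .trilin_points_c(field$u[, , , cmp], fd, field$spacing, field$origin, fx)
    }
  }
  d <- sqrt(rowSums((mapped - mx)^2))
  list(distances = as.numeric(d), mean = mean(d),
       sd = if (length(d) > 1) sd(d) else 0)
}

#' Write a deformation field as a 3-component MetaImage
#' @param field a [deformation_field()].
#' @param path output path (`.mha` or `.mhd`).
#' @export
write_deformation_field <- function(field, path) {
  vol <- list(data = field$u, spacing = field$spacing, origin = field$origin,
              unit = "raw")
  class(vol) <- "image_volume"
  write_meta_file(vol, path, channels = 3L)
  invisible(path)
}

#' Read a 3-component MetaImage deformation field
#' @param path path to a field written by [write_deformation_field()].
#' @return A [deformation_field()].
#' @export
read_deformation_field <- function(path) {
  parsed <- read_meta_file(path)
  if (is.null(parsed$channels) || parsed$channels != 3L)
    stop("expected a 3-component field volume", call. = FALSE)
  deformation_field(parsed$data, spacing = parsed$spacing, origin = parsed$origin)
}
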