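#' 3D image volume with grid metadata and an intensity-unit tag
#'
#' The basic container of the package: a 3D numeric array on a regular grid
#' with per-axis physical voxel spacing (micrometres), a physical origin (the
#' coordinate of voxel `[1,1,1]`, 0-based index (0,0,0)), and a unit tag.
#' Axis order is (x, y, z) with z the cranio-caudal axis. Physical coordinates
#' follow the voxel-center convention: `p = origin + index * spacing` with
#' 0-based indices.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size per axis in micrometres
#'   (all > 0). A scalar is recycled (isotropic).
#' @param origin numeric length-3, physical coordinate of the first voxel
#'   center in micrometres.
#' @param unit one of `"raw"`, `"HU"`, `"SVg"`, `"dSVg"`, `"mask"`, `"label"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(50, 50, 50), origin = c(0, 0, 0),
                         unit = c("raw", "HU", "SVg", "dSVg", "mask", "label")) {
  unit <- match.arg(unit)
  if (length(dim(data)) != 3L)
    stop("volume must be 3-dimensional", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values", call. = FALSE)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  storage.mode(data) <- if (unit %in% c("mask", "label")) "integer" else "double"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), unit = unit),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing (%g, %g, %g) um, unit %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$unit))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_image_volume <- function(x) inherits(x, "image_volume")

stopifnot_unit <- function(vol, unit) {
  if (!is_image_volume(vol)) stop("expected an image_volume", call. = FALSE)
  if (!identical(vol$unit, unit))
    stop(sprintf("expected a volume with unit '%s', got '%s'", unit, vol$unit),
         call. = FALSE)
  invisible(vol)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share shape, spacing and origin", what), call. = FALSE)
  invisible(NULL)
}

#' Construct a binary lung mask on the grid of a paired volume
#'
#' Any nonzero voxel is treated as foreground; if values other than 0/1 are
#' present a warning is raised (the stored mask is always 0/1).
#'
#' @param data 3D array (logical or numeric).
#' @inheritParams image_volume
#' @return An `image_volume` with unit `"mask"` and 0/1 integer data.
#' @export
lung_mask <- function(data, spacing = c(50, 50, 50), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume must be 3-dimensional", call. = FALSE)
  v <- as.numeric(data)
  if (any(!(v %in% c(0, 1))))
    warning("mask contains values other than 0/1; treating any nonzero voxel as foreground")
  m <- array(as.integer(v != 0), dim = dim(data))
  if (sum(m) == 0L) stop("mask is empty", call. = FALSE)
  image_volume(m, spacing = spacing, origin = origin, unit = "mask")
}

mask_logical <- function(mask) {
  if (!is_image_volume(mask) || mask$unit != "mask")
    stop("expected a lung mask (unit 'mask')", call. = FALSE)
  mask$data != 0L
}

#' Physical voxel-center coordinates of a volume
#'
#' @param vol an `image_volume`.
#' @return A list with vectors `x`, `y`, `z` of per-axis center coordinates
#'   (micrometres).
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
}
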