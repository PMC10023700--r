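#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`) and MetaImage (`.mha`,
#' `.mhd`). Grid spacing and origin are taken from the header; a header
#' without voxel spacing is rejected rather than silently defaulted. All
#' physical quantities are interpreted as micrometres.
#'
#' @param path path to an existing volume file.
#' @param expected_unit unit tag to attach to the returned volume (the file
#'   formats themselves carry no intensity-unit information).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, expected_unit = "raw") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- volume_format(path)
  parsed <- switch(ext,
    nifti = read_nifti_file(path),
    meta  = read_meta_file(path),
    stop("unsupported volume format: ", path, call. = FALSE))
  if (length(parsed$dim) != 3L || any(parsed$dim < 1L))
    stop("volume must be 3-dimensional", call. = FALSE)
  if (is.null(parsed$spacing) || any(!is.finite(parsed$spacing)) ||
      any(parsed$spacing <= 0))
    stop("volume header has no usable voxel spacing: ", path, call. = FALSE)
  image_volume(parsed$data, spacing = parsed$spacing, origin = parsed$origin,
               unit = expected_unit)
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' The output is readable by [read_volume()] with identical grid metadata.
#' Integer-valued volumes (masks, label maps) round-trip bit-exactly; floating
#' point data are stored at double precision in NIfTI and single precision in
#' MetaImage.
#'
#' @param vol an [image_volume()].
#' @param path output path; the extension selects the format.
#' @export
write_volume <- function(vol, path) {
  if (!is_image_volume(vol)) stop("expected an image_volume", call. = FALSE)
  ext <- volume_format(path)
  switch(ext,
    nifti = write_nifti_file(vol, path),
    meta  = write_meta_file(vol, path),
    stop("unsupported volume extension: ", path, call. = FALSE))
  invisible(path)
}

#' Read a binary lung mask
#'
#' Reads a volume and coerces it to a 0/1 mask; nonzero values are treated as
#' foreground (with a warning when values other than 0/1 occur).
#'
#' @inheritParams read_volume
#' @return An [image_volume()] with unit `"mask"`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path, expected_unit = "raw")
  lung_mask(v$data, spacing = v$spacing, origin = v$origin)
}

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.(mha|mhd)$", lower)) return("meta")
  stop("unsupported volume extension: ", path, call. = FALSE)
}

read_nifti_file <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  sp <- RNifti::pixdim(img)
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  org <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  list(data = array(as.numeric(img), dim = d), dim = d,
       spacing = as.numeric(sp)[seq_along(d)], origin = org)
}

write_nifti_file <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (vol$unit %in% c("mask", "label")) "uint8" else "auto")
}

meta_type_map <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                   MET_SHORT = "integer", MET_USHORT = "integer",
                   MET_INT = "integer", MET_UINT = "integer",
                   MET_FLOAT = "double", MET_DOUBLE = "double")
meta_type_size <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
                    MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

read_meta_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- scan_meta_line(con)
    if (is.null(line)) stop("truncated MetaImage header: ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!is.null(hdr$BinaryDataByteOrderMSB) &&
      tolower(hdr$BinaryDataByteOrderMSB) == "true")
    stop("big-endian MetaImage not supported", call. = FALSE)
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage not supported", call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  nchan <- if (!is.null(hdr$ElementNumberOfChannels))
    as.integer(hdr$ElementNumberOfChannels) else 1L
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else NULL
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, length(dims))
  type <- hdr$ElementType
  if (is.null(type) || !type %in% names(meta_type_map))
    stop("unsupported MetaImage element type: ", type, call. = FALSE)
  n <- prod(dims) * nchan
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  what <- meta_type_map[[type]]
  size <- meta_type_size[[type]]
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  vals <- readBin(raw_con, what = what, n = n, size = size,
                  signed = if (what == "integer" && size < 4) signed else TRUE,
                  endian = "little")
  if (length(vals) != n) stop("truncated MetaImage data: ", path, call. = FALSE)
  data <- if (nchan == 1L) array(as.numeric(vals), dim = dims)
          else aperm(array(as.numeric(vals), dim = c(nchan, dims)),
                     c(seq_along(dims) + 1L, 1L))
  list(data = data, dim = dims, spacing = spacing, origin = origin,
       channels = nchan)
}

# read one newline-terminated ASCII header line from a binary connection
scan_meta_line <- function(con) {
  chars <- character(0)
  repeat {
    ch <- readBin(con, "raw", n = 1L)
    if (length(ch) == 0) return(if (length(chars)) paste(chars, collapse = "") else NULL)
    if (ch == as.raw(10L)) return(paste(chars, collapse = ""))
    if (ch != as.raw(13L)) chars <- c(chars, rawToChar(ch))
  }
}

write_meta_file <- function(vol, path, channels = 1L) {
  d <- dim(vol$data)
  ndim <- if (channels > 1L) length(d) - 1L else length(d)
  dims <- d[seq_len(ndim)]
  integerish <- vol$unit %in% c("mask", "label")
  type <- if (integerish) "MET_UCHAR" else "MET_FLOAT"
  is_mhd <- grepl("\\.mhd$", tolower(path))
  raw_name <- if (is_mhd) sub("\\.mhd$", ".raw", basename(path)) else "LOCAL"
  hdr <- c("ObjectType = Image",
           sprintf("NDims = %d", ndim),
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("TransformMatrix = %s",
                   paste(as.numeric(diag(ndim)), collapse = " ")),
           sprintf("Offset = %s", paste(format(vol$origin[seq_len(ndim)],
                                               digits = 17), collapse = " ")),
           sprintf("ElementSpacing = %s", paste(format(vol$spacing[seq_len(ndim)],
                                                       digits = 17), collapse = " ")),
           sprintf("DimSize = %s", paste(dims, collapse = " ")),
           if (channels > 1L) sprintf("ElementNumberOfChannels = %d", channels),
           sprintf("ElementType = %s", type),
           sprintf("ElementDataFile = %s", raw_name))
  vals <- if (channels > 1L)
    as.numeric(aperm(vol$data, c(length(d), seq_len(ndim)))) else
    as.numeric(vol$data)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  data_con <- con
  if (is_mhd) {
    data_con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(data_con), add = TRUE)
  }
  if (integerish) {
    writeBin(as.integer(vals), data_con, size = 1L, endian = "little")
  } else {
    writeBin(vals, data_con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read paired landmarks from CSV
#'
#' Landmark files are plain-text CSV with columns `id, fx, fy, fz, mx, my, mz`
#' giving paired physical coordinates (micrometres) in the fixed
#' (inspiratory) and moving (expiratory) volumes.
#'
#' @param path CSV file path.
#' @return A `landmark_set` data frame.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  landmark_set(df)
}

#' Construct a landmark set
#'
#' @param df data frame with columns `id, fx, fy, fz, mx, my, mz` (micrometres).
#' @return The validated data frame with class `landmark_set`.
#' @export
landmark_set <- function(df) {
  need <- c("id", "fx", "fy", "fz", "mx", "my", "mz")
  if (!all(need %in% names(df)))
    stop("landmark set needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(df) < 1L) stop("landmark set must contain at least one pair", call. = FALSE)
  for (cc in need[-1]) df[[cc]] <- as.numeric(df[[cc]])
  if (any(!is.finite(as.matrix(df[need[-1]]))))
    stop("landmark coordinates must be finite", call. = FALSE)
  class(df) <- c("landmark_set", "data.frame")
  df
}

#' Write a landmark set to CSV
#' @param landmarks a `landmark_set`.
#' @param path output CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  write.csv(as.data.frame(landmarks)[c("id", "fx", "fy", "fz", "mx", "my", "mz")],
            path, row.names = FALSE)
  invisible(path)
}
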