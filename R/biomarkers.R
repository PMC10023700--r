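#' Partition a lung mask into regions of equal vertical size
#'
#' Cuts the mask's bounding range along the chosen axis into 2 (halves) or 3
#' (thirds) contiguous slabs with equal slice counts; when the extent is not
#' divisible, the remainder goes to the first (cranial-most or ventral-most)
#' slabs. Halves follow the cranio-caudal axis (upper/lower lung); thirds
#' follow the ventral-dorsal axis (ventral/intermediate/dorsal), matching the
#' dorsal-plane histology sectioning, but the axis is an explicit argument.
#'
#' @param mask a [lung_mask()].
#' @param scheme `"whole"`, `"halves"` or `"thirds"`.
#' @param axis axis along which to cut: 1 = x (lateral), 2 = y
#'   (ventral-dorsal), 3 = z (cranio-caudal). Defaults to 3 for halves,
#'   2 for thirds.
#' @return A `region_partition`: list with `labels` (integer [image_volume()],
#'   0 outside, 1..k per region), `scheme`, `axis`, `region_names` and
#'   per-region voxel `counts`.
#' @export
split_regions <- function(mask, scheme = c("whole", "halves", "thirds"),
                          axis = NULL) {
  scheme <- match.arg(scheme)
  m <- mask_logical(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  k <- switch(scheme, whole = 1L, halves = 2L, thirds = 3L)
  if (is.null(axis)) axis <- if (scheme == "thirds") 2L else 3L
  names <- switch(scheme,
    whole = "whole",
    halves = c("upper", "lower"),
    thirds = c("ventral", "intermediate", "dorsal"))
  lab <- array(0L, dim = dim(m))
  if (k == 1L) {
    lab[m] <- 1L
  } else {
    present <- apply(m, axis, any)
    rng <- range(which(present))
    extent <- rng[2] - rng[1] + 1L
    if (extent < k)
      stop(sprintf("mask extent along axis %d (%d slices) is shorter than %d regions",
                   axis, extent, k), call. = FALSE)
    base <- extent %/% k
    rem <- extent %% k
    sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
    bounds <- rng[1] + cumsum(c(0L, sizes))
    idx <- slice.index(m, axis)
    for (r in seq_len(k)) {
      sel <- m & idx >= bounds[r] & idx < bounds[r + 1]
      lab[sel] <- r
    }
  }
  labels <- image_volume(lab, spacing = mask$spacing, origin = mask$origin,
                         unit = "label")
  structure(list(labels = labels, scheme = scheme, axis = axis,
                 region_names = names,
                 counts = setNames(vapply(seq_len(k), function(r) sum(lab == r), 1L),
                                   names)),
            class = "region_partition")
}

#' Restrict a lung mask to the left lung
#'
#' For comparison against left-lobe histology. When a side-label volume is
#' available (1 = left, 2 = right on the same grid) it is used directly;
#' otherwise the mask is split at the midsagittal plane through the mask
#' centroid, with a warning.
#'
#' @param mask a [lung_mask()].
#' @param side_labels optional integer [image_volume()] with per-voxel side
#'   labels (1 left, 2 right).
#' @param left_is_low_x when splitting at the centroid, whether the left
#'   lung is on the low-x side (default TRUE: supine animal, x from the
#'   animal's left to right... adjust to the acquisition convention).
#' @return A [lung_mask()] covering the left lung only.
#' @export
left_lung_mask <- function(mask, side_labels = NULL, left_is_low_x = TRUE) {
  m <- mask_logical(mask)
  if (!is.null(side_labels)) {
    stopifnot_same_grid(mask, side_labels, "mask and side labels")
    keep <- m & side_labels$data == 1L
  } else {
    warning("no side labels: splitting at the midsagittal plane through the mask centroid")
    ix <- slice.index(m, 1)
    cx <- mean(ix[m])
    keep <- if (left_is_low_x) m & ix < cx else m & ix >= cx
  }
  lung_mask(array(as.integer(keep), dim = dim(keep)),
            spacing = mask$spacing, origin = mask$origin)
}

region_values <- function(vol, partition, region) {
  r <- match(region, partition$region_names)
  if (is.na(r)) stop("unknown region: ", region, call. = FALSE)
  v <- vol$data[partition$labels$data == r]
  v[!is.na(v)]
}

#' Distribution metrics of a regional value pool
#'
#' Median, 75th percentile and interquartile range (p75 - p25), with the same
#' type-7 percentile convention used for threshold derivation. The median
#' tracks the histogram peak, the 75th percentile the right-side tail
#' (density increases such as ground glass and consolidation; for dSVg the
#' normal tail), and the IQR heterogeneity.
#'
#' @param values numeric vector of in-region voxel values (NAs dropped), or
#'   an [image_volume()] combined with `region`.
#' @param region optional logical array or [lung_mask()] selecting voxels
#'   when `values` is a volume.
#' @return Named vector `c(median, p75, IQR)`.
#' @export
distribution_metrics <- function(values, region = NULL) {
  if (is_image_volume(values)) {
    if (is.null(region)) {
      values <- values$data
    } else {
      sel <- if (is_image_volume(region)) mask_logical(region) else region
      values <- values$data[sel]
    }
  }
  values <- as.numeric(values[!is.na(values)])
  if (length(values) == 0L) stop("region contains no values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], p75 = q[3], IQR = q[3] - q[1])
}

#' Per-subject normalized histogram
#'
#' Frequencies per bin over the in-mask voxels, normalized to sum to one.
#' Values falling outside the bin range are counted into the end bins (with a
#' warning), so the frequencies always account for every in-mask voxel.
#'
#' @param vol an [image_volume()] (HU or dSVg).
#' @param mask a [lung_mask()] on the same grid.
#' @param bin_edges strictly increasing numeric vector of bin edges.
#' @return A `histogram_summary` row: list with `bin_edges`, `mid` and
#'   `frequency`.
#' @export
subject_histogram <- function(vol, mask, bin_edges) {
  stopifnot_same_grid(vol, mask, "volume and mask")
  if (any(diff(bin_edges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  v <- vol$data[mask_logical(mask)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("mask selects no values", call. = FALSE)
  n_out <- sum(v < bin_edges[1] | v > bin_edges[length(bin_edges)])
  if (n_out > 0)
    warning(sprintf("%d values outside the bin range were counted into the end bins", n_out))
  v <- pmin(pmax(v, bin_edges[1]), bin_edges[length(bin_edges)])
  counts <- tabulate(findInterval(v, bin_edges, rightmost.closed = TRUE),
                     nbins = length(bin_edges) - 1L)
  structure(list(bin_edges = bin_edges,
                 mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
                 frequency = counts / sum(counts)),
            class = "histogram_summary")
}

#' Group median histogram curve
#'
#' Per-bin median frequency across subjects sharing the same bin edges. The
#' median curve is a summary, not a distribution: it need not sum to one.
#'
#' @param rows list of `histogram_summary` rows from [subject_histogram()].
#' @return A `histogram_summary`-like list with the per-bin median in
#'   `frequency`.
#' @export
group_median_histogram <- function(rows) {
  if (length(rows) < 1L) stop("at least one subject is required", call. = FALSE)
  edges <- rows[[1]]$bin_edges
  for (r in rows)
    if (!isTRUE(all.equal(r$bin_edges, edges)))
      stop("subjects must share bin edges", call. = FALSE)
  freq <- apply(do.call(rbind, lapply(rows, `[[`, "frequency")), 2, median)
  structure(list(bin_edges = edges, mid = rows[[1]]$mid, frequency = freq),
            class = "histogram_summary")
}

#' Default density histogram bin edges
#'
#' 25-HU-wide bins over \[-1000, 500\] HU.
#' @return Numeric vector of edges.
#' @export
default_hu_bins <- function() seq(-1000, 500, by = 25)

#' Spearman rank-order correlation
#'
#' Rank-based correlation with midranks for ties. The p-value uses the
#' t-approximation on n - 2 degrees of freedom by default; for n of 10 or
#' fewer an exact permutation p-value (full enumeration over all n!
#' orderings) is available.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @param p_method `"t-approx"` or `"exact"` (permutation, n <= 10).
#' @return List with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y, p_method = c("t-approx", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("at least 3 observations are required", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero variance in ranks", call. = FALSE)
  rho <- cor(rx, ry)
  if (p_method == "exact") {
    if (n > 10L) stop("exact permutation p-value is limited to n <= 10", call. = FALSE)
    p <- .spearman_perm_c(rx, ry)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = min(p, 1))
}

BIOMARKER_METRICS <- c("HU_median", "HU_p75", "HU_IQR",
                       "dSVg_median", "dSVg_p75", "dSVg_IQR",
                       "pctF", "pctLV", "pctNV")

#' Regional biomarker table
#'
#' One record per subject x region x metric: density metrics (median, p75,
#' IQR of inspiratory HU), ventilation metrics (same for dSVg) and functional
#' class percentages. Rows are ordered deterministically (subject, region,
#' metric).
#'
#' @param subjects list of subject entries; each entry is a list with fields
#'   `subject` (id), `day` (timepoint), `hu_insp` ([image_volume()], HU),
#'   `dsvg` ([image_volume()], dSVg), `fmap` (a `functional_map`, required
#'   only for the class percentages) and `mask` (a [lung_mask()]).
#' @param scheme region scheme passed to [split_regions()] (plus `"whole"`
#'   which is always included when another scheme is requested).
#' @param metrics subset of metrics to compute (default all nine).
#' @param axis optional axis override for [split_regions()].
#' @return A data frame with columns
#'   `subject, day, region, metric, value, units`.
#' @export
biomarker_table <- function(subjects, scheme = "whole",
                            metrics = BIOMARKER_METRICS, axis = NULL) {
  bad <- setdiff(metrics, BIOMARKER_METRICS)
  if (length(bad)) stop("unknown metrics: ", paste(bad, collapse = ", "), call. = FALSE)
  rows <- list()
  for (s in subjects) {
    if (is.null(s$mask)) stop("each subject needs a mask", call. = FALSE)
    parts <- split_regions(s$mask, scheme, axis = axis)
    for (region in parts$region_names) {
      sel <- parts$labels$data == match(region, parts$region_names)
      for (metric in metrics) {
        units <- "ml/g"
        if (startsWith(metric, "HU")) {
          if (is.null(s$hu_insp)) stop("metric ", metric, " needs hu_insp", call. = FALSE)
          dm <- distribution_metrics(s$hu_insp$data[sel])
          units <- "HU"
          value <- switch(metric, HU_median = dm[["median"]],
                          HU_p75 = dm[["p75"]], HU_IQR = dm[["IQR"]])
        } else if (startsWith(metric, "dSVg")) {
          if (is.null(s$dsvg)) stop("metric ", metric, " needs dsvg", call. = FALSE)
          dm <- distribution_metrics(s$dsvg$data[sel])
          value <- switch(metric, dSVg_median = dm[["median"]],
                          dSVg_p75 = dm[["p75"]], dSVg_IQR = dm[["IQR"]])
        } else {
          if (is.null(s$fmap))
            stop("metric ", metric, " needs a functional map", call. = FALSE)
          rm <- lung_mask(array(as.integer(sel), dim = dim(sel)),
                          spacing = s$mask$spacing, origin = s$mask$origin)
          pct <- class_percentages(s$fmap, rm)
          units <- "%"
          value <- pct[[metric]]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s$subject, day = if (is.null(s$day)) NA else s$day,
          region = region, metric = metric, value = as.numeric(value),
          units = units, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
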