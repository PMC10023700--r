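#' Load and validate a study configuration
#'
#' The study configuration is a single YAML file describing the cohort
#' manifest (per-subject inspiratory/expiratory volumes, masks, optional
#' landmarks, group and timepoint), the calibration anchors, registration
#' parameters, SVg constants, threshold cohort, region scheme and histogram
#' binning. Unknown keys are rejected so typos cannot silently disable an
#' option.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated `study_config` (invisibly carries resolved defaults).
#' @export
study_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  issues <- validate_config(cfg)
  if (length(issues))
    stop("invalid study configuration:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  defaults <- list(
    seed = 1L,
    denoise_sigma = 0,
    registration = list(levels = 4L, iterations = c(100L, 100L, 50L, 25L),
                        smoothing_sigma = 1.5),
    svg = list(sv_tissue = 1 / 1.065, hu_floor = -990),
    thresholds = list(p_alpha = 5, p_beta = 25, cohort_group = "saline"),
    histogram = list(min = -1000, max = 500, width = 25),
    regions = list(scheme = "halves", axis = NULL))
  cfg <- modifyList(defaults, cfg)
  structure(cfg, class = "study_config")
}

config_keys <- list(
  top = c("output_dir", "seed", "calibration", "registration", "svg",
          "denoise_sigma", "thresholds", "histogram", "regions", "subjects"),
  calibration = c("raw_air", "raw_water", "hu_air", "hu_water"),
  registration = c("levels", "iterations", "smoothing_sigma"),
  svg = c("sv_tissue", "hu_floor"),
  thresholds = c("p_alpha", "p_beta", "cohort_group"),
  histogram = c("min", "max", "width"),
  regions = c("scheme", "axis"),
  subject = c("id", "day", "group", "insp", "exp", "mask_insp", "mask_exp",
              "landmarks"))

#' Validate a study configuration
#'
#' Schema and path checks; returns a character vector of issues (empty when
#' the configuration is valid).
#'
#' @param cfg a list parsed from YAML, or a YAML file path.
#' @return Character vector of field-level issues.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  issues <- character(0)
  note <- function(...) issues <<- c(issues, sprintf(...))
  unknown <- setdiff(names(cfg), config_keys$top)
  if (length(unknown)) note("unknown key(s): %s", paste(unknown, collapse = ", "))
  for (sect in c("calibration", "registration", "svg", "thresholds",
                 "histogram", "regions")) {
    if (!is.null(cfg[[sect]])) {
      bad <- setdiff(names(cfg[[sect]]), config_keys[[sect]])
      if (length(bad)) note("%s: unknown key(s): %s", sect, paste(bad, collapse = ", "))
    }
  }
  if (is.null(cfg$output_dir)) note("output_dir is required")
  if (is.null(cfg$calibration)) {
    note("calibration with raw_air and raw_water is required")
  } else {
    ca <- cfg$calibration
    if (is.null(ca$raw_air) || is.null(ca$raw_water))
      note("calibration: raw_air and raw_water are required")
    else if (identical(ca$raw_air, ca$raw_water))
      note("calibration: raw_air must differ from raw_water")
  }
  if (!is.null(cfg$denoise_sigma) && cfg$denoise_sigma < 0)
    note("denoise_sigma: must be non-negative")
  if (!is.null(cfg$registration$levels) && cfg$registration$levels < 1)
    note("registration: levels must be at least 1")
  if (!is.null(cfg$svg$hu_floor) && cfg$svg$hu_floor <= -1000)
    note("svg: hu_floor must exceed -1000")
  if (!is.null(cfg$thresholds)) {
    for (p in c("p_alpha", "p_beta")) {
      v <- cfg$thresholds[[p]]
      if (!is.null(v) && (v <= 0 || v >= 100))
        note("thresholds: %s must lie in (0, 100)", p)
    }
  }
  if (!is.null(cfg$regions$scheme) &&
      !cfg$regions$scheme %in% c("whole", "halves", "thirds"))
    note("regions: scheme must be whole, halves or thirds")
  if (is.null(cfg$subjects) || !length(cfg$subjects)) {
    note("at least one subject is required")
  } else {
    for (i in seq_along(cfg$subjects)) {
      s <- cfg$subjects[[i]]
      bad <- setdiff(names(s), config_keys$subject)
      if (length(bad)) note("subject %d: unknown key(s): %s", i,
                            paste(bad, collapse = ", "))
      for (fld in c("id", "group", "insp", "exp", "mask_insp")) {
        if (is.null(s[[fld]])) note("subject %d: %s is required", i, fld)
      }
      for (fld in c("insp", "exp", "mask_insp", "mask_exp", "landmarks")) {
        if (!is.null(s[[fld]]) && !file.exists(s[[fld]]))
          note("subject %d: file not found: %s", i, s[[fld]])
      }
    }
  }
  issues
}

process_subject <- function(s, cfg, cal, consts) {
  insp <- read_volume(s$insp, "raw")
  expv <- read_volume(s$exp, "raw")
  mask_insp <- read_mask(s$mask_insp)
  mask_exp <- if (!is.null(s$mask_exp)) read_mask(s$mask_exp) else NULL
  landmarks <- if (!is.null(s$landmarks)) read_landmarks(s$landmarks) else NULL
  res <- analyze_pair(insp, expv, mask_insp, mask_exp, calibration = cal,
                      denoise_sigma = cfg$denoise_sigma,
                      landmarks = landmarks,
                      registration = cfg$registration, consts = consts)
  excluded_exp <- sum(mask_logical(mask_insp)) - sum(mask_logical(res$domain))
  list(id = s$id, day = s$day, group = s$group, hu_insp = res$hu_insp,
       svg_insp = res$svg_insp, svg_exp = res$svg_exp, dsvg = res$dsvg,
       mask = res$domain, report = res$report, field = res$field,
       excluded_exp_background = excluded_exp,
       clamped = attr(res$svg_insp, "clamped") + attr(res$svg_exp, "clamped"))
}

#' Run the full study pipeline
#'
#' For every subject: calibration, optional denoising, Demons registration,
#' warping of the expiratory image, SVg and dSVg mapping. Thresholds are then
#' derived from the pooled in-mask voxels of the configured control group and
#' every subject is classified; biomarker and histogram tables and a run log
#' are written under `output_dir`. A failing subject is recorded and skipped;
#' the returned summary lists completed and failed subjects.
#'
#' @param cfg a [study_config()] (or path to one).
#' @return Invisibly, a list with `thresholds`, `biomarkers`, `completed`,
#'   `failed` and the output directory.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "study_config")) cfg <- study_config(cfg)
  set.seed(cfg$seed)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cal <- calibration_spec(cfg$calibration$raw_air, cfg$calibration$raw_water,
                          cfg$calibration$hu_air %||% -1000,
                          cfg$calibration$hu_water %||% 0)
  consts <- svg_constants(cfg$svg$sv_tissue, cfg$svg$hu_floor)
  results <- list()
  failed <- list()
  for (s in cfg$subjects) {
    res <- tryCatch(process_subject(s, cfg, cal, consts),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[[s$id]] <- conditionMessage(res)
      message(sprintf("subject %s failed: %s", s$id, conditionMessage(res)))
    } else {
      results[[s$id]] <- res
    }
  }
  if (!length(results)) stop("no subject completed", call. = FALSE)

  cohort <- Filter(function(r) identical(r$group, cfg$thresholds$cohort_group),
                   results)
  if (!length(cohort))
    stop("no completed subject in the threshold cohort group '",
         cfg$thresholds$cohort_group, "'", call. = FALSE)
  thresholds <- derive_thresholds(
    unlist(lapply(cohort, function(r) r$svg_insp$data[mask_logical(r$mask)])),
    unlist(lapply(cohort, function(r) r$svg_exp$data[mask_logical(r$mask)])),
    unlist(lapply(cohort, function(r) r$dsvg$data[mask_logical(r$mask)])),
    p_alpha = cfg$thresholds$p_alpha, p_beta = cfg$thresholds$p_beta,
    cohort_id = cfg$thresholds$cohort_group)
  write_thresholds(thresholds, file.path(out_dir, "thresholds.json"))

  subjects <- list()
  edges <- seq(cfg$histogram$min, cfg$histogram$max, by = cfg$histogram$width)
  hist_rows <- list()
  for (r in results) {
    fmap <- classify_voxels(r$svg_insp, r$svg_exp, r$dsvg, thresholds, r$mask)
    sub_dir <- file.path(out_dir, r$id)
    dir.create(sub_dir, showWarnings = FALSE)
    write_volume(r$hu_insp, file.path(sub_dir, "insp_hu.nii.gz"))
    write_volume(r$dsvg, file.path(sub_dir, "dsvg.nii.gz"))
    write_functional_map(fmap, file.path(sub_dir, "functional_map.nii.gz"))
    write_deformation_field(r$field, file.path(sub_dir, "field.mha"))
    rep <- r$report
    rep$clamped_voxels <- r$clamped
    rep$excluded_exp_background <- r$excluded_exp_background
    rep$mixed_margin_fraction <- attr(fmap, "mixed_margin_fraction")
    jsonlite::write_json(rep, file.path(sub_dir, "registration_report.json"),
                         auto_unbox = TRUE, digits = NA)
    subjects[[length(subjects) + 1L]] <- list(
      subject = r$id, day = r$day, hu_insp = r$hu_insp, dsvg = r$dsvg,
      fmap = fmap, mask = r$mask)
    h <- subject_histogram(r$hu_insp, r$mask, edges)
    hist_rows[[r$id]] <- data.frame(subject = r$id, bin_lo = h$bin_edges[-length(h$bin_edges)],
                                    bin_hi = h$bin_edges[-1], frequency = h$frequency)
  }
  schemes <- unique(c("whole", cfg$regions$scheme))
  bm <- do.call(rbind, lapply(schemes, function(sc)
    biomarker_table(subjects, scheme = sc,
                    axis = if (identical(sc, cfg$regions$scheme)) cfg$regions$axis)))
  write.csv(bm, file.path(out_dir, "biomarkers.csv"), row.names = FALSE)
  write.csv(do.call(rbind, hist_rows), file.path(out_dir, "histograms.csv"),
            row.names = FALSE)
  log <- list(package_version = as.character(utils::packageVersion("microvent")),
              seed = cfg$seed,
              completed = names(results), failed = failed,
              thresholds = unclass(thresholds))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(thresholds = thresholds, biomarkers = bm,
                 completed = names(results), failed = failed,
                 output_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
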