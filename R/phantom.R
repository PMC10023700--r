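#' Specification of the synthetic paired-phase lung phantom
#'
#' The phantom emulates a free-breathing micro-CT mouse chest: two
#' ellipsoidal lungs in a soft-tissue torso, vessel-like bright markers that
#' double as registration landmarks, optional fibrotic and low-ventilation
#' lesions, a smooth analytic cranio-caudal compression between the
#' inspiratory and expiratory phases, spatially correlated parenchymal
#' density texture shared between phases, and optional additive Gaussian HU
#' noise. Raw grey-level volumes are an affine re-encoding of HU through a
#' known calibration so that the calibration stage is exercised.
#'
#' Modes:
#' * `"lesioned"` (default): focal spherical lesions at the target volume
#'   fractions (fibrosis 10%, low ventilation 15% of the lung).
#' * `"saline"`: no lesions; the ventilated compartment takes exactly the
#'   default inspiratory/expiratory HU pair (-550 / -400).
#' * `"fibrotic"`: confluent dorsal consolidation (fibrosis about 40% of the
#'   lung as a dorsal cap, with a 20% peri-lesional low-ventilation band),
#'   emulating severe late-timepoint disease.
#'
#' In lesion-bearing modes the ventilated (spared) compartment inflates more
#' at inspiration: the tidal gas volume displaced per breath is conserved at
#' the animal level, so parenchyma spared by non-ventilating lesions receives
#' a proportionally larger share of the tidal volume. This compensatory
#' redistribution is what separates the spared-parenchyma ventilation
#' distribution from the healthy cohort's distribution.
#'
#' @param mode `"lesioned"`, `"saline"` or `"fibrotic"`.
#' @param shape grid size per axis in voxels (default `c(128, 128, 128)`).
#' @param spacing isotropic voxel size in micrometres (default 50).
#' @param seed integer seed controlling every random element.
#' @param hu named list of compartment HU means; defaults: soft tissue +40,
#'   ventilated parenchyma -550 (insp) / -400 (exp), low-ventilation lesion
#'   -450 / -420, fibrotic lesion -100 (both phases), marker 0.
#' @param frac_f,frac_lv target lesion volume fractions of the lung.
#' @param n_blobs_f,n_blobs_lv number of spherical blobs per lesion class
#'   (lesioned mode).
#' @param amplitude_vox peak cranio-caudal compression in voxels (default 6).
#' @param lateral_expansion relative lateral expansion coefficient
#'   (default 0.008, about half a voxel at the chest wall).
#' @param texture_sd_common,texture_sd_phase standard deviation (HU) of the
#'   shared tissue-density texture and of the per-phase texture component.
#' @param texture_corr_vox Gaussian correlation scale of the texture
#'   (smoothing sigma in voxels).
#' @param noise_sd additive Gaussian HU noise standard deviation (default 0).
#' @param n_landmarks number of marker landmarks (default 10).
#' @param tidal_conservation logical; apply the compensatory redistribution
#'   described above (default TRUE).
#' @param calibration a [calibration_spec()] used to re-encode HU into raw
#'   grey levels.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(mode = c("lesioned", "saline", "fibrotic"),
                         shape = c(128, 128, 128), spacing = 50, seed = 7,
                         hu = list(), frac_f = NULL, frac_lv = NULL,
                         n_blobs_f = 2, n_blobs_lv = 2,
                         amplitude_vox = 6, lateral_expansion = 0.008,
                         texture_sd_common = 18, texture_sd_phase = 8,
                         texture_corr_vox = 2.5, noise_sd = 0,
                         n_landmarks = 10, tidal_conservation = TRUE,
                         calibration = calibration_spec(raw_air = 120,
                                                        raw_water = 4620)) {
  mode <- match.arg(mode)
  hu_default <- list(soft_tissue = 40, vent_insp = -550, vent_exp = -400,
                     lv_insp = -450, lv_exp = -420, fib = -100, marker = 0)
  hu <- modifyList(hu_default, hu)
  if (is.null(frac_f)) frac_f <- switch(mode, lesioned = 0.10, saline = 0,
                                        fibrotic = 0.40)
  if (is.null(frac_lv)) frac_lv <- switch(mode, lesioned = 0.15, saline = 0,
                                          fibrotic = 0.20)
  if (frac_f < 0 || frac_lv < 0 || frac_f + frac_lv > 1)
    stop("lesion fractions must be non-negative with F + LV <= 1", call. = FALSE)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  spec <- list(mode = mode, shape = as.integer(shape), spacing = spacing,
               seed = as.integer(seed), hu = hu, frac_f = frac_f,
               frac_lv = frac_lv, n_blobs_f = n_blobs_f,
               n_blobs_lv = n_blobs_lv, amplitude_vox = amplitude_vox,
               lateral_expansion = lateral_expansion,
               texture_sd_common = texture_sd_common,
               texture_sd_phase = texture_sd_phase,
               texture_corr_vox = texture_corr_vox, noise_sd = noise_sd,
               n_landmarks = n_landmarks,
               tidal_conservation = tidal_conservation,
               calibration = calibration)
  # invertibility of the compression profile: max |du_z/dz| < 1
  n <- spec$shape
  span <- (0.78 - 0.16) * n[3]
  if (amplitude_vox * pi / (2 * span) >= 1)
    stop("deformation amplitude too large for an invertible field", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

# geometry in voxel coordinates (0-based voxel centers)
phantom_geometry <- function(spec) {
  n <- spec$shape
  list(n = n,
       torso_c = c(0.50, 0.50, 0.48) * n, torso_a = c(0.44, 0.40, 0.47) * n,
       lung_c = rbind(c(0.30, 0.50, 0.47) * n, c(0.70, 0.50, 0.47) * n),
       lung_a = c(0.16, 0.21, 0.31) * n,
       z_apex = 0.16 * n[3], z_diaphragm = 0.78 * n[3],
       # dorsal-cap thresholds (normalized y) giving 40% F / 20% LV fractions
       cap_s_f = 0.13535, cap_s_lv = -0.13535)
}

raised_cosine <- function(z, z0, z1) {
  t <- pmin(pmax((z - z0) / (z1 - z0), 0), 1)
  0.5 * (1 - cos(pi * t))
}

# forward map phi(p) = p + u(p), voxel coordinates
phantom_forward <- function(spec, geom, px, py, pz) {
  cz <- raised_cosine(pz, geom$z_apex, geom$z_diaphragm)
  eps <- spec$lateral_expansion
  list(x = px + eps * (px - geom$n[1] / 2) * cz,
       y = py + eps * (py - geom$n[2] / 2) * cz,
       z = pz - spec$amplitude_vox * cz)
}

# inverse of the forward map at expiratory voxel coordinates
phantom_inverse <- function(spec, geom, qx, qy, qz) {
  zg <- seq(-2 * spec$amplitude_vox - 2, geom$n[3] + 2, length.out = 4096)
  fz <- zg - spec$amplitude_vox * raised_cosine(zg, geom$z_apex, geom$z_diaphragm)
  pz <- approx(fz, zg, xout = as.numeric(qz), rule = 2)$y
  cz <- raised_cosine(pz, geom$z_apex, geom$z_diaphragm)
  eps <- spec$lateral_expansion
  list(x = (as.numeric(qx) + eps * geom$n[1] / 2 * cz) / (1 + eps * cz),
       y = (as.numeric(qy) + eps * geom$n[2] / 2 * cz) / (1 + eps * cz),
       z = pz)
}

in_ellipsoid <- function(px, py, pz, centre, axes, shrink = 0) {
  a <- pmax(axes - shrink, 1e-6)
  ((px - centre[1]) / a[1])^2 + ((py - centre[2]) / a[2])^2 +
    ((pz - centre[3]) / a[3])^2 <= 1
}

# compartment codes: 0 air, 1 soft tissue, 2 ventilated parenchyma,
# 3 LV lesion, 4 fibrotic lesion, 5 marker
phantom_code <- function(spec, geom, anatomy, px, py, pz) {
  lung1 <- in_ellipsoid(px, py, pz, geom$lung_c[1, ], geom$lung_a)
  lung2 <- in_ellipsoid(px, py, pz, geom$lung_c[2, ], geom$lung_a)
  lung <- lung1 | lung2
  torso <- in_ellipsoid(px, py, pz, geom$torso_c, geom$torso_a)
  code <- ifelse(torso, 1L, 0L)
  code[lung] <- 2L
  if (spec$mode == "fibrotic") {
    sy <- rep(NA_real_, length(px))
    sy[lung1] <- (py[lung1] - geom$lung_c[1, 2]) / geom$lung_a[2]
    sy[lung2] <- (py[lung2] - geom$lung_c[2, 2]) / geom$lung_a[2]
    code[lung & sy > geom$cap_s_lv] <- 3L
    code[lung & sy > geom$cap_s_f] <- 4L
  }
  if (nrow(anatomy$lesions)) {
    for (i in seq_len(nrow(anatomy$lesions))) {
      L <- anatomy$lesions[i, ]
      hit <- lung & ((px - L$cx)^2 + (py - L$cy)^2 + (pz - L$cz)^2 <= L$r^2)
      code[hit] <- if (L$class == "F") 4L else 3L
    }
  }
  if (nrow(anatomy$markers)) {
    for (i in seq_len(nrow(anatomy$markers))) {
      M <- anatomy$markers[i, ]
      hit <- (px - M$cx)^2 + (py - M$cy)^2 + (pz - M$cz)^2 <= M$r^2
      code[hit] <- 5L
    }
  }
  code
}

# sample lesion blobs and marker positions (voxel coordinates)
phantom_anatomy <- function(spec, geom) {
  lung_vol <- 2 * (4 / 3) * pi * prod(geom$lung_a)
  lesions <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                        r = numeric(0), class = character(0),
                        stringsAsFactors = FALSE)
  place_in_lung <- function(margin, side = NULL) {
    a <- geom$lung_a - margin
    if (any(a <= 0)) stop("infeasible lesion fractions: a blob does not fit inside the lung",
                          call. = FALSE)
    for (try in 1:2000) {
      s <- if (is.null(side)) sample(1:2, 1) else side
      u <- runif(3, -1, 1)
      if (sum(u^2) > 1) next
      return(geom$lung_c[s, ] + u * a)
    }
    stop("could not place a component inside the lung", call. = FALSE)
  }
  if (spec$mode == "lesioned" && (spec$frac_f > 0 || spec$frac_lv > 0)) {
    # blobs alternate between the two lungs; lesions of the same class may
    # coalesce, but the F and LV classes must stay disjoint
    add_blobs <- function(frac, count, class, lesions) {
      if (frac <= 0 || count < 1) return(lesions)
      r_base <- (frac * lung_vol / (count * 4 / 3 * pi))^(1 / 3)
      jitter <- runif(count, 0.92, 1.08)
      radii <- r_base * jitter / (sum(jitter^3) / count)^(1 / 3)
      for (b in seq_along(radii)) {
        r <- radii[b]
        side <- (b - 1L) %% 2L + 1L
        ok <- FALSE
        for (try in 1:300) {
          c0 <- place_in_lung(margin = r + 1, side = side)
          other <- lesions[lesions$class != class, , drop = FALSE]
          if (nrow(other)) {
            d <- sqrt((other$cx - c0[1])^2 + (other$cy - c0[2])^2 +
                        (other$cz - c0[3])^2)
            if (any(d < other$r + r + 2)) next
          }
          lesions <- rbind(lesions, data.frame(cx = c0[1], cy = c0[2],
                                               cz = c0[3], r = r,
                                               class = class,
                                               stringsAsFactors = FALSE))
          ok <- TRUE
          break
        }
        if (!ok) stop("lesion layout attempt failed", call. = FALSE)
      }
      lesions
    }
    # an unlucky early blob can make the remaining placements infeasible:
    # restart the whole layout rather than fail
    empty <- lesions
    placed <- FALSE
    for (attempt in 1:100) {
      lesions <- tryCatch({
        l <- add_blobs(spec$frac_f, spec$n_blobs_f, "F", empty)
        add_blobs(spec$frac_lv, spec$n_blobs_lv, "LV", l)
      }, error = function(e) {
        if (grepl("does not fit inside the lung", conditionMessage(e))) stop(e)
        NULL
      })
      if (!is.null(lesions)) { placed <- TRUE; break }
    }
    if (!placed)
      stop("infeasible lesion fractions: could not place class-disjoint blobs",
           call. = FALSE)
  }
  marker_r <- 2.0
  markers <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  in_spared <- function(c0) {
    if (spec$mode == "fibrotic") {
      side <- which.min((geom$lung_c[, 1] - c0[1])^2)
      sy <- (c0[2] - geom$lung_c[side, 2]) / geom$lung_a[2]
      if (sy > geom$cap_s_lv - 0.06) return(FALSE)
    }
    if (nrow(lesions)) {
      d <- sqrt((lesions$cx - c0[1])^2 + (lesions$cy - c0[2])^2 +
                  (lesions$cz - c0[3])^2)
      if (any(d < lesions$r + marker_r + 0.5)) return(FALSE)
    }
    TRUE
  }
  # markers prefer a wide spread; if the lung is too crowded (small grids,
  # large lesion load) the minimum pairwise separation is relaxed stepwise
  for (min_sep in c(8, 6, 4, 3, 2)) {
    markers <- markers[0, ]
    ok_all <- TRUE
    while (nrow(markers) < spec$n_landmarks) {
      placed <- FALSE
      for (try in 1:500) {
        c0 <- round(place_in_lung(margin = marker_r + 1)) # snap to voxel center
        if (!in_spared(c0)) next
        if (nrow(markers)) {
          d <- sqrt((markers$cx - c0[1])^2 + (markers$cy - c0[2])^2 +
                      (markers$cz - c0[3])^2)
          if (any(d < min_sep)) next
        }
        markers <- rbind(markers, data.frame(cx = c0[1], cy = c0[2],
                                             cz = c0[3], r = marker_r,
                                             stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) { ok_all <- FALSE; break }
    }
    if (ok_all) break
  }
  if (nrow(markers) < spec$n_landmarks)
    stop("could not place landmarks", call. = FALSE)
  list(lesions = lesions, markers = markers)
}

smooth_noise_field <- function(n, sigma_vox, sd_target) {
  if (sd_target <= 0) return(array(0, dim = n))
  w <- array(rnorm(prod(n)), dim = n)
  s <- .gaussian_smooth_c(w, n, rep(sigma_vox, 3))
  s * (sd_target / sd(as.numeric(s)))
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic paired-phase micro-CT phantom
#'
#' Builds the inspiratory anatomy analytically, produces the expiratory
#' volume by evaluating the same anatomy through the exact inverse of a
#' smooth analytic compression field (raised-cosine profile, zero at the lung
#' apex and maximal at the diaphragm, plus a small lateral expansion), and
#' re-encodes both HU volumes into scanner grey levels through the spec's
#' calibration. The same seed always yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `insp_raw`, `exp_raw` (grey-level
#'   [image_volume()]s), `insp_hu`, `exp_hu`, `mask_insp`, `mask_exp`
#'   ([lung_mask()]s), `calibration`, and `truth` (a `phantom_truth`: class
#'   labelmap, analytic [deformation_field()], `landmark_set`, compartment
#'   HU table and the resolved spec).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec", call. = FALSE)
  geom <- phantom_geometry(spec)
  n <- geom$n
  sp <- rep(spec$spacing, 3)
  with_local_seed(spec$seed, {
    anatomy <- phantom_anatomy(spec, geom)
    tex_common <- smooth_noise_field(n, spec$texture_corr_vox, spec$texture_sd_common)
    tex_insp <- smooth_noise_field(n, spec$texture_corr_vox, spec$texture_sd_phase)
    tex_exp <- smooth_noise_field(n, spec$texture_corr_vox, spec$texture_sd_phase)

    # compensatory redistribution of the tidal volume to spared parenchyma
    tidal <- (spec$hu$vent_exp - spec$hu$vent_insp) / 1000 # gas fraction per breath
    f_eff <- spec$frac_f + 0.8 * spec$frac_lv
    spared <- 1 - spec$frac_f - spec$frac_lv
    vent_insp_hu <- spec$hu$vent_insp
    if (spec$tidal_conservation && f_eff > 0 && spared > 0)
      vent_insp_hu <- vent_insp_hu - 1000 * tidal * f_eff / spared

    base_insp <- c(-1000, spec$hu$soft_tissue, vent_insp_hu,
                   spec$hu$lv_insp, spec$hu$fib, spec$hu$marker)
    base_exp <- c(-1000, spec$hu$soft_tissue, spec$hu$vent_exp,
                  spec$hu$lv_exp, spec$hu$fib, spec$hu$marker)

    ix <- slice.index(array(0L, n), 1) - 1
    iy <- slice.index(array(0L, n), 2) - 1
    iz <- slice.index(array(0L, n), 3) - 1

    code_insp <- phantom_code(spec, geom, anatomy, as.numeric(ix),
                              as.numeric(iy), as.numeric(iz))
    hu_insp <- base_insp[code_insp + 1L]
    paren <- code_insp %in% c(2L, 3L, 4L)
    hu_insp[paren] <- hu_insp[paren] + as.numeric(tex_common)[paren] +
      as.numeric(tex_insp)[paren]
    tiss <- code_insp == 1L
    hu_insp[tiss] <- hu_insp[tiss] + 0.5 * as.numeric(tex_common)[tiss]

    p <- phantom_inverse(spec, geom, ix, iy, iz)
    code_exp <- phantom_code(spec, geom, anatomy, p$x, p$y, p$z)
    hu_exp <- base_exp[code_exp + 1L]
    pts <- cbind(p$x, p$y, p$z)
    tex_common_at_p <- .trilin_points_c(tex_common, n, c(1, 1, 1), c(0, 0, 0), pts)
    paren_e <- code_exp %in% c(2L, 3L, 4L)
    hu_exp[paren_e] <- hu_exp[paren_e] + tex_common_at_p[paren_e] +
      as.numeric(tex_exp)[paren_e]
    tiss_e <- code_exp == 1L
    hu_exp[tiss_e] <- hu_exp[tiss_e] + 0.5 * tex_common_at_p[tiss_e]

    if (spec$noise_sd > 0) {
      hu_insp <- hu_insp + rnorm(length(hu_insp), 0, spec$noise_sd)
      hu_exp <- hu_exp + rnorm(length(hu_exp), 0, spec$noise_sd)
    }

    dimify <- function(v) array(v, dim = n)
    insp_hu <- image_volume(dimify(hu_insp), spacing = sp, unit = "HU")
    exp_hu <- image_volume(dimify(hu_exp), spacing = sp, unit = "HU")
    mask_insp <- lung_mask(dimify(code_insp %in% c(2L, 3L, 4L)), spacing = sp)
    mask_exp <- lung_mask(dimify(code_exp %in% c(2L, 3L, 4L)), spacing = sp)

    # ground truth on the inspiratory grid
    class_map <- dimify(ifelse(code_insp == 4L, 1L,
                        ifelse(code_insp == 3L, 2L,
                        ifelse(code_insp == 2L, 3L, 0L))))
    truth_map <- image_volume(class_map, spacing = sp, unit = "label")
    fwd <- phantom_forward(spec, geom, ix, iy, iz)
    u <- array(0, dim = c(n, 3L))
    u[, , , 1] <- (fwd$x - ix) * sp[1]
    u[, , , 2] <- (fwd$y - iy) * sp[2]
    u[, , , 3] <- (fwd$z - iz) * sp[3]
    truth_field <- deformation_field(u, spacing = sp)

    mk <- anatomy$markers
    fwd_m <- phantom_forward(spec, geom, mk$cx, mk$cy, mk$cz)
    landmarks <- landmark_set(data.frame(
      id = seq_len(nrow(mk)),
      fx = mk$cx * sp[1], fy = mk$cy * sp[2], fz = mk$cz * sp[3],
      mx = fwd_m$x * sp[1], my = fwd_m$y * sp[2], mz = fwd_m$z * sp[3]))

    compartment_hu <- data.frame(
      compartment = c("air", "soft_tissue", "ventilated", "low_ventilation",
                      "fibrotic", "marker"),
      hu_insp = base_insp, hu_exp = base_exp, stringsAsFactors = FALSE)

    truth <- structure(list(class_map = truth_map, field = truth_field,
                            landmarks = landmarks,
                            compartment_hu = compartment_hu,
                            anatomy = anatomy, spec = spec),
                       class = "phantom_truth")

    list(insp_raw = hu_to_grey(insp_hu, spec$calibration),
         exp_raw = hu_to_grey(exp_hu, spec$calibration),
         insp_hu = insp_hu, exp_hu = exp_hu,
         mask_insp = mask_insp, mask_exp = mask_exp,
         calibration = spec$calibration, truth = truth)
  })
}

#' Per-class recovery of a predicted functional map against phantom truth
#'
#' Dice(c) = 2 |T intersect P| / (|T| + |P|) per class, plus the full
#' confusion matrix over voxels that are inside the analysis domain of
#' either map.
#'
#' @param truth a `phantom_truth` or a truth label [image_volume()].
#' @param predicted a `functional_map` (or label volume) on the same grid.
#' @return List with `dice` (named vector over F, LV, NV) and `confusion`
#'   (4x4 table over outside/F/LV/NV, truth in rows).
#' @export
evaluate_recovery <- function(truth, predicted) {
  tmap <- if (inherits(truth, "phantom_truth")) truth$class_map else truth
  if (!is_image_volume(tmap) || !is_image_volume(predicted))
    stop("expected label volumes", call. = FALSE)
  if (!identical(dim(tmap$data), dim(predicted$data)))
    stop("truth and prediction must share the same grid", call. = FALSE)
  lv <- c("outside", "F", "LV", "NV")
  # compare where both maps are defined: the prediction's analysis domain
  # (inspiratory mask intersected with the warped expiratory mask) may be a
  # strict subset of the truth domain
  both <- tmap$data != 0L & predicted$data != 0L
  tf <- factor(lv[tmap$data[both] + 1L], levels = lv)
  pf <- factor(lv[predicted$data[both] + 1L], levels = lv)
  confusion <- table(truth = tf, predicted = pf)
  dice <- vapply(c("F", "LV", "NV"), function(cl) {
    t <- tf == cl; p <- pf == cl
    denom <- sum(t) + sum(p)
    if (denom == 0) return(NA_real_)
    2 * sum(t & p) / denom
  }, 1.0)
  list(dice = dice, confusion = confusion)
}
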