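# Shared fixtures, built lazily and cached for the whole test session.
# Small grids keep the unit tests fast; the acceptance tests use the
# study-scale 128^3 phantoms through the same cache.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# full single-subject chain from raw grey levels, as the pipeline runs it
analyze_phantom <- function(ph, denoise_sigma = 0) {
  analyze_pair(ph$insp_raw, ph$exp_raw, ph$mask_insp, ph$mask_exp,
               calibration = ph$calibration, denoise_sigma = denoise_sigma,
               landmarks = ph$truth$landmarks)
}

small_shape <- c(48, 48, 48)

small_saline <- function(seed, noise_sd = 0) {
  generate_phantom(phantom_spec("saline", shape = small_shape, seed = seed,
                                noise_sd = noise_sd))
}

# a tiny deterministic HU volume with a ramp along z
ramp_volume <- function(n = 8, spacing = 50) {
  a <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) a[, , k] <- k * 10
  image_volume(a, spacing = spacing, unit = "HU")
}

zero_field <- function(vol) {
  deformation_field(array(0, dim = c(dim(vol$data), 3L)),
                    spacing = vol$spacing, origin = vol$origin)
}

constant_field <- function(vol, u_um) {
  u <- array(0, dim = c(dim(vol$data), 3L))
  for (c in 1:3) u[, , , c] <- u_um[c]
  deformation_field(u, spacing = vol$spacing, origin = vol$origin)
}
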