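# Synthetic single-nucleus fluorescence scenes with known ground truth.
#
# A scene is a roughly spherical nucleus with a single central nucleolus,
# rendered on an anisotropic voxel grid (200 nm z-spacing by default),
# blurred with a Gaussian PSF and corrupted with Poisson photon noise and
# Gaussian camera read noise. The chromatin channel follows a radial
# density that is single-peaked ("fed") or double-peaked at the nucleolar
# edge and nuclear periphery ("fasted").

#' Preset ring parameters for the chromatin radial density
#'
#' Parameters of the sum-of-two-Gaussians radial density in normalized
#' distance units (0 = nucleolus centre, 1 = nuclear surface):
#' `A_i, x_i, sigma_i` inner peak, `A_o, x_o, sigma_o` outer peak,
#' `B` background. The "fed" preset is a single mid-radius peak
#' (`A_o = 0`); the "fasted" preset places an inner peak just outside the
#' nucleolus and an outer peak at the nuclear periphery with
#' outer-to-inner amplitude ratio 0.6.
#'
#' @param mode `"fed"` or `"fasted"`.
#' @return named numeric vector of the 7 ring parameters.
#' @export
ring_preset <- function(mode = c("fed", "fasted")) {
  mode <- match.arg(mode)
  if (mode == "fed") {
    c(A_i = 1, x_i = 0.55, sigma_i = 0.15, A_o = 0, x_o = 0.90,
      sigma_o = 0.06, B = 0.1)
  } else {
    c(A_i = 1, x_i = 0.25, sigma_i = 0.10, A_o = 0.6, x_o = 0.90,
      sigma_o = 0.07, B = 0.1)
  }
}

validate_ring_params <- function(p) {
  need <- c("A_i", "x_i", "sigma_i", "A_o", "x_o", "sigma_o", "B")
  if (!all(need %in% names(p))) {
    cr_error(paste("ring_params must contain", paste(need, collapse = ", ")),
             "invalid_parameter")
  }
  p <- p[need]
  if (any(!is.finite(p))) cr_error("ring_params must be finite", "invalid_parameter")
  if (p["sigma_i"] <= 0 || p["sigma_o"] <= 0)
    cr_error("ring sigmas must be positive", "invalid_parameter")
  if (p["A_i"] < 0 || p["A_o"] < 0 || p["B"] < 0)
    cr_error("ring amplitudes and background must be >= 0", "invalid_parameter")
  if (p["A_i"] > 0 && p["A_o"] > 0 && p["x_i"] >= p["x_o"])
    cr_error("inner peak centre x_i must be below outer centre x_o",
             "invalid_parameter")
  p
}

#' Radial chromatin density function
#'
#' Returns the function of normalized distance r in `[0, 1]`
#' `B + A_i exp(-(r - x_i)^2 / (2 sigma_i^2)) +
#'      A_o exp(-(r - x_o)^2 / (2 sigma_o^2))`
#' used generatively by the scene renderer. Presets `"fed"` and
#' `"fasted"` supply [ring_preset()] parameters; `"custom"` requires
#' `ring_params`.
#'
#' @param mode `"fed"`, `"fasted"` or `"custom"`.
#' @param ring_params named vector overriding/supplying the 7 parameters.
#' @return function mapping numeric `r` to intensity.
#' @export
radial_density <- function(mode = c("fed", "fasted", "custom"),
                           ring_params = NULL) {
  mode <- match.arg(mode)
  p <- if (mode == "custom") {
    if (is.null(ring_params)) cr_error("custom mode requires ring_params",
                                       "invalid_parameter")
    ring_params
  } else if (is.null(ring_params)) ring_preset(mode) else ring_params
  # fill unstated parameters with zeros (amplitude-off peaks need no centre)
  full <- c(A_i = 0, x_i = 0.5, sigma_i = 0.1, A_o = 0, x_o = 0.9,
            sigma_o = 0.1, B = 0)
  full[names(p)] <- p
  p <- validate_ring_params(full)
  function(r) {
    p[["B"]] +
      p[["A_i"]] * exp(-(r - p[["x_i"]])^2 / (2 * p[["sigma_i"]]^2)) +
      p[["A_o"]] * exp(-(r - p[["x_o"]])^2 / (2 * p[["sigma_o"]]^2))
  }
}

#' Scene configuration for the synthetic-nucleus renderer
#'
#' Defaults describe an intestinal nucleus: radius 3 um, single central
#' nucleolus (sigma 0.55 um per axis), 130 nm xy pixels and 200 nm
#' z-spacing, a near-diffraction-limited PSF and moderate shot noise.
#' `tissue_size_scale` defaults per tissue; muscle nuclei are about 25%
#' of the intestinal nuclear volume, i.e. 0.25^(1/3) ~ 0.63 of the radius.
#'
#' @param nucleus_radius nuclear radius in um (before tissue scaling).
#' @param tissue one of `"intestine"`, `"hypoderm"`, `"muscle"`.
#' @param tissue_size_scale factor in (0, 1] applied to the radius;
#'   default 1 (intestine), 0.85 (hypoderm), 0.63 (muscle).
#' @param chromatin_mode `"fed"`, `"fasted"` or `"custom"`.
#' @param ring_params ring parameters (see [ring_preset()]); defaults to
#'   the preset of `chromatin_mode`.
#' @param nucleolus_sigmas length-3 sigmas (um) of the nucleolar 3D
#'   Gaussian, order `(y, x, z)`.
#' @param nucleolus_amplitude peak nucleolar intensity (arbitrary units).
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas (um).
#' @param photon_scale photons per intensity unit (`Inf` = no shot noise).
#' @param read_noise_sd camera read noise SD in counts.
#' @param voxel_xy,voxel_z voxel pitches (um); z defaults to 0.2 um.
#' @param condition condition label recorded on scenes (defaults to
#'   `chromatin_mode`).
#' @param seed integer seed for the scene's noise.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(nucleus_radius = 3,
                         tissue = c("intestine", "hypoderm", "muscle"),
                         tissue_size_scale = NULL,
                         chromatin_mode = c("fed", "fasted", "custom"),
                         ring_params = NULL,
                         nucleolus_sigmas = c(0.55, 0.55, 0.55),
                         nucleolus_amplitude = 5,
                         psf_sigma_xy = 0.08,
                         psf_sigma_z = 0.25,
                         photon_scale = 200,
                         read_noise_sd = 1.5,
                         voxel_xy = 0.13,
                         voxel_z = 0.2,
                         condition = NULL,
                         seed = NULL) {
  tissue <- match.arg(tissue)
  chromatin_mode <- match.arg(chromatin_mode)
  if (is.null(tissue_size_scale)) {
    tissue_size_scale <- switch(tissue, intestine = 1, hypoderm = 0.85,
                                muscle = round(0.25^(1 / 3), 2))
  }
  if (is.null(condition)) condition <- chromatin_mode
  cfg <- list(
    nucleus_radius = nucleus_radius, tissue = tissue,
    tissue_size_scale = tissue_size_scale,
    chromatin_mode = chromatin_mode,
    ring_params = if (is.null(ring_params) && chromatin_mode != "custom")
      ring_preset(chromatin_mode) else ring_params,
    nucleolus_sigmas = nucleolus_sigmas,
    nucleolus_amplitude = nucleolus_amplitude,
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    photon_scale = photon_scale, read_noise_sd = read_noise_sd,
    voxel_xy = voxel_xy, voxel_z = voxel_z,
    condition = condition, seed = seed)
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  with(cfg, {
    if (nucleus_radius <= 0 || voxel_xy <= 0 || voxel_z <= 0)
      cr_error("lengths must be positive", "invalid_parameter")
    if (tissue_size_scale <= 0 || tissue_size_scale > 1)
      cr_error("tissue_size_scale must be in (0, 1]", "invalid_parameter")
    if (length(nucleolus_sigmas) != 3 || any(nucleolus_sigmas <= 0))
      cr_error("nucleolus_sigmas must be 3 positive lengths", "invalid_parameter")
    if (psf_sigma_xy < 0 || psf_sigma_z < 0 || read_noise_sd < 0)
      cr_error("psf sigmas and read noise must be >= 0", "invalid_parameter")
    if (photon_scale <= 0) cr_error("photon_scale must be > 0", "invalid_parameter")
  })
  validate_ring_params(cfg$ring_params)
  invisible(cfg)
}

# Apply shot + read noise and quantize to integer camera counts.
apply_camera <- function(field, photon_scale, read_noise_sd) {
  if (!is.finite(photon_scale)) {
    out <- field
    if (read_noise_sd > 0)
      out <- out + array(stats::rnorm(length(field), 0, read_noise_sd),
                         dim = dim(field))
    return(out)
  }
  counts <- array(stats::rpois(length(field), pmax(field, 0) * photon_scale),
                  dim = dim(field))
  if (read_noise_sd > 0)
    counts <- counts + array(stats::rnorm(length(counts), 0, read_noise_sd),
                             dim = dim(counts))
  pmax(round(counts), 0)
}

#' Render a synthetic single-nucleus scene
#'
#' Renders a spherical nucleus of radius `nucleus_radius * tissue_size_scale`
#' centred on the grid. Chromatin voxel intensity is the radial density
#' evaluated at the voxel's normalized distance from the nucleolus centre
#' (0 at centre, 1 at the nuclear surface, 0 outside). The nucleolus
#' channel is a 3D Gaussian. Both channels are convolved with the
#' anisotropic PSF and passed through the camera model (Poisson photons,
#' Gaussian read noise, integer counts). Ground truth is recorded before
#' blur and noise; post-PSF ("effective") nucleolar sigmas are recorded
#' too, since they are what the imaged object measures.
#'
#' @param config a [scene_config()].
#' @return object of class `nucleus_scene` with fields `channels`
#'   (chromatin / nucleolus / optional spots arrays, `(y, x, z)` counts),
#'   `mask2d`, `mask3d`, `nucleolus_center` (1-based `(y, x, z)` voxel),
#'   `central_z`, voxel pitches, labels and `truth`.
#' @export
generate_nucleus_scene <- function(config) {
  validate_scene_config(config)
  cfg <- config
  R_um <- cfg$nucleus_radius * cfg$tissue_size_scale
  if (3 * max(cfg$nucleolus_sigmas) >= R_um)
    cr_error("nucleolus sigmas too large for the nucleus", "configuration_error")
  margin_xy <- 4 * cfg$psf_sigma_xy + 0.4
  margin_z <- 4 * cfg$psf_sigma_z + 0.4
  hx <- ceiling((R_um + margin_xy) / cfg$voxel_xy)
  hz <- ceiling((R_um + margin_z) / cfg$voxel_z)
  if (hx < 4 || hz < 2)
    cr_error("stack dimensions too small for the nucleus", "configuration_error")
  ny <- nx <- 2L * hx + 1L
  nz <- 2L * hz + 1L
  dy <- (seq_len(ny) - (hx + 1)) * cfg$voxel_xy
  dx <- (seq_len(nx) - (hx + 1)) * cfg$voxel_xy
  dz <- (seq_len(nz) - (hz + 1)) * cfg$voxel_z
  yx2 <- outer(dy^2, dx^2, "+")
  dens <- radial_density(cfg$chromatin_mode, cfg$ring_params)
  chrom <- array(0, dim = c(ny, nx, nz))
  nucl <- array(0, dim = c(ny, nx, nz))
  mask3d <- array(0L, dim = c(ny, nx, nz))
  s <- cfg$nucleolus_sigmas
  gyx <- exp(-outer(dy^2 / (2 * s[1]^2), dx^2 / (2 * s[2]^2), "+"))
  for (k in seq_len(nz)) {
    r_um <- sqrt(yx2 + dz[k]^2)
    rn <- r_um / R_um
    inside <- rn <= 1
    slice <- numeric(length(rn))
    slice[inside] <- dens(rn[inside])
    chrom[, , k] <- slice
    nucl[, , k] <- cfg$nucleolus_amplitude * gyx * exp(-dz[k]^2 / (2 * s[3]^2))
    mask3d[, , k] <- inside * 1L
  }
  sig_vox <- c(cfg$psf_sigma_xy / cfg$voxel_xy, cfg$psf_sigma_xy / cfg$voxel_xy,
               cfg$psf_sigma_z / cfg$voxel_z)
  if (any(sig_vox > 0)) {
    chrom <- gaussian_blur_3d(chrom, sig_vox)
    nucl <- gaussian_blur_3d(nucl, sig_vox)
  }
  chrom <- with_local_seed(cfg$seed, apply_camera(chrom, cfg$photon_scale,
                                                  cfg$read_noise_sd))
  nucl <- with_local_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L,
                          apply_camera(nucl, cfg$photon_scale,
                                       cfg$read_noise_sd))
  eff <- sqrt(s^2 + c(cfg$psf_sigma_xy, cfg$psf_sigma_xy, cfg$psf_sigma_z)^2)
  eff_vox <- eff / c(cfg$voxel_xy, cfg$voxel_xy, cfg$voxel_z)
  s_vox <- s / c(cfg$voxel_xy, cfg$voxel_xy, cfg$voxel_z)
  truth <- list(
    ring_params = cfg$ring_params,
    nucleolus_sigmas_um = s,
    nucleolus_sigmas_vox = s_vox,
    nucleolus_sigmas_eff_um = eff,
    nucleolus_sigmas_eff_vox = eff_vox,
    nucleolus_center = c(y = hx + 1, x = hx + 1, z = hz + 1),
    nucleolus_volume_vox = 4 / 3 * pi * prod(s_vox),
    nucleolus_volume_um3 = 4 / 3 * pi * prod(s),
    nucleolus_volume_eff_vox = 4 / 3 * pi * prod(eff_vox),
    nucleolus_volume_eff_um3 = 4 / 3 * pi * prod(eff),
    nucleus_center = c(y = hx + 1, x = hx + 1, z = hz + 1),
    nucleus_radius_um = R_um,
    nucleus_radius_px = R_um / cfg$voxel_xy,
    spots = list())
  scene <- list(
    channels = list(chromatin = chrom, nucleolus = nucl, spots = NULL),
    mask2d = mask3d[, , hz + 1L],
    mask3d = mask3d,
    nucleolus_center = c(y = hx + 1, x = hx + 1, z = hz + 1),
    central_z = hz + 1L,
    voxel_xy = cfg$voxel_xy, voxel_z = cfg$voxel_z,
    tissue = cfg$tissue, condition = cfg$condition,
    nucleus_id = paste0(cfg$condition, "_1"),
    truth = truth, config = cfg)
  class(scene) <- "nucleus_scene"
  scene
}

#' @export
print.nucleus_scene <- function(x, ...) {
  d <- dim(x$channels$chromatin)
  cat("<nucleus_scene>", x$nucleus_id, "\n")
  cat("  tissue:", x$tissue, " condition:", x$condition, "\n")
  cat(sprintf("  stack: %d x %d x %d voxels (%.2f x %.2f x %.2f um)\n",
              d[1], d[2], d[3], d[1] * x$voxel_xy, d[2] * x$voxel_xy,
              d[3] * x$voxel_z))
  cat(sprintf("  nucleus radius: %.2f um; nucleolus volume (true): %.2f um^3\n",
              x$truth$nucleus_radius_um, x$truth$nucleolus_volume_um3))
  invisible(x)
}

#' Half-maximum nucleolus mask of a synthetic scene
#'
#' Ellipsoid where the noiseless (post-PSF) nucleolar Gaussian exceeds
#' `level` of its peak; used as the nucleolar segmentation ground truth.
#'
#' @param scene a `nucleus_scene`.
#' @param level fraction of the peak (default 0.5, the half-max surface).
#' @param effective use post-PSF sigmas (default `TRUE`).
#' @return 0/1 integer array `(y, x, z)`.
#' @export
nucleolus_truth_mask <- function(scene, level = 0.5, effective = TRUE) {
  stopifnot(inherits(scene, "nucleus_scene"), level > 0, level < 1)
  d <- dim(scene$mask3d)
  ctr <- scene$nucleolus_center
  s <- if (effective) scene$truth$nucleolus_sigmas_eff_vox
       else scene$truth$nucleolus_sigmas_vox
  thr <- 2 * log(1 / level)
  dy2 <- ((seq_len(d[1]) - ctr[["y"]]) / s[1])^2
  dx2 <- ((seq_len(d[2]) - ctr[["x"]]) / s[2])^2
  m <- array(0L, dim = d)
  q_yx <- outer(dy2, dx2, "+")
  for (k in seq_len(d[3])) {
    m[, , k] <- (q_yx + ((k - ctr[["z"]]) / s[3])^2 <= thr) * 1L
  }
  m
}

#' Add a diffraction-limited reporter spot to a scene
#'
#' Places a 3D Gaussian spot in the `spots` channel at normalized radial
#' position `relative_radius` (0 = nucleolus centre, 1 = nuclear contour)
#' in the central plane, at a uniformly random angle (seeded). The true
#' continuous position and the injected integral (in stored count units)
#' are appended to the scene truth.
#'
#' @param scene a `nucleus_scene`.
#' @param relative_radius position in `[0, 1]`.
#' @param intensity peak spot intensity (pre-camera units).
#' @param sigma_um spot sigma in um, `(y, x, z)` (default a
#'   diffraction-limited `c(0.1, 0.1, 0.25)`).
#' @param background uniform background level added to the spot channel
#'   (pre-camera units).
#' @param seed seed for the angle and the channel noise.
#' @return the scene with an updated `spots` channel and truth.
#' @export
place_reporter_spot <- function(scene, relative_radius, intensity = 20,
                                sigma_um = c(0.1, 0.1, 0.25),
                                background = 0.5, seed = NULL) {
  stopifnot(inherits(scene, "nucleus_scene"))
  if (relative_radius < 0 || relative_radius > 1)
    cr_error("relative_radius must be in [0, 1]", "invalid_parameter")
  cfg <- scene$config
  d <- dim(scene$mask3d)
  angle <- with_local_seed(seed, stats::runif(1, 0, 2 * pi))
  r_px <- relative_radius * scene$truth$nucleus_radius_px
  cy <- scene$nucleolus_center[["y"]] + r_px * sin(angle)
  cx <- scene$nucleolus_center[["x"]] + r_px * cos(angle)
  cz <- scene$central_z
  iy <- min(max(round(cy), 1L), d[1]); ix <- min(max(round(cx), 1L), d[2])
  if (relative_radius < 1 && scene$mask3d[iy, ix, cz] == 0)
    cr_error("spot position falls outside the nucleus mask", "invalid_parameter")
  s_vox <- sigma_um / c(scene$voxel_xy, scene$voxel_xy, scene$voxel_z)
  field <- array(background, dim = d)
  if (!is.null(scene$truth$spot_field)) field <- scene$truth$spot_field
  gy <- exp(-((seq_len(d[1]) - cy)^2) / (2 * s_vox[1]^2))
  gx <- exp(-((seq_len(d[2]) - cx)^2) / (2 * s_vox[2]^2))
  gz <- exp(-((seq_len(d[3]) - cz)^2) / (2 * s_vox[3]^2))
  add <- intensity * outer(gy, gx)
  for (k in seq_len(d[3])) field[, , k] <- field[, , k] + add * gz[k]
  count_scale <- if (is.finite(cfg$photon_scale)) cfg$photon_scale else 1
  spot_truth <- list(
    center = c(y = cy, x = cx, z = cz), angle = angle,
    relative_radius = relative_radius,
    sigma_vox = s_vox,
    integral_counts = intensity * count_scale * (2 * pi)^1.5 * prod(s_vox))
  scene$truth$spots <- c(scene$truth$spots, list(spot_truth))
  scene$truth$spot_field <- field  # pre-camera accumulated field
  scene$channels$spots <- with_local_seed(
    if (is.null(seed)) NULL else seed + 1L,
    apply_camera(field, cfg$photon_scale, cfg$read_noise_sd))
  scene
}

#' Add a nucleolar FISH signal to a scene
#'
#' Renders a pre-rRNA pool as a uniform-intensity ellipsoid centred on
#' the nucleolus (FISH probes against the unprocessed precursor
#' accumulate throughout the nucleolar volume, so the signal is a filled
#' compartment rather than a point source), convolves it with the
#' scene's PSF, adds a uniform cellular background, and passes it
#' through the camera model into the `spots` channel. The injected
#' integral (sum of the rendered, background-free signal, in stored
#' count units) is recorded in the scene truth as `fish_integral`.
#'
#' @param scene a `nucleus_scene`.
#' @param intensity plateau intensity of the pool (pre-camera units).
#' @param semi_axes_um ellipsoid semi-axes `(y, x, z)` in um.
#' @param background uniform background level (pre-camera units).
#' @param seed seed for the channel noise.
#' @return the scene with a `spots` channel and `truth$fish_integral`.
#' @export
add_fish_signal <- function(scene, intensity = 1.5,
                            semi_axes_um = c(0.9, 0.9, 0.9),
                            background = 0.1, seed = NULL) {
  stopifnot(inherits(scene, "nucleus_scene"), intensity > 0,
            length(semi_axes_um) == 3, all(semi_axes_um > 0))
  cfg <- scene$config
  d <- dim(scene$mask3d)
  ctr <- scene$nucleolus_center
  semi_vox <- semi_axes_um / c(scene$voxel_xy, scene$voxel_xy, scene$voxel_z)
  field <- array(0, dim = d)
  q_yx <- outer(((seq_len(d[1]) - ctr[["y"]]) / semi_vox[1])^2,
                ((seq_len(d[2]) - ctr[["x"]]) / semi_vox[2])^2, "+")
  for (k in seq_len(d[3])) {
    field[, , k] <- intensity *
      ((q_yx + ((k - ctr[["z"]]) / semi_vox[3])^2) <= 1)
  }
  sig_vox <- c(cfg$psf_sigma_xy / scene$voxel_xy,
               cfg$psf_sigma_xy / scene$voxel_xy,
               cfg$psf_sigma_z / scene$voxel_z)
  if (any(sig_vox > 0)) field <- gaussian_blur_3d(field, sig_vox)
  count_scale <- if (is.finite(cfg$photon_scale)) cfg$photon_scale else 1
  scene$truth$fish_integral <- sum(field) * count_scale
  scene$channels$spots <- with_local_seed(
    seed, apply_camera(field + background, cfg$photon_scale,
                       cfg$read_noise_sd))
  scene
}

#' Generate a two-condition cohort of synthetic scenes
#'
#' Renders `n_per_condition` scenes for each configuration with per-scene
#' seeds derived from the master seed and nuclear radii jittered by a
#' log-normal-free multiplicative factor with coefficient of variation
#' `radius_cv` (truncated at +/- 2 cv). Reproducible for a fixed seed.
#'
#' @param config_A,config_B [scene_config()] objects (their `condition`
#'   labels tag the scenes).
#' @param n_per_condition scenes per condition (>= 1).
#' @param seed master integer seed.
#' @param radius_cv coefficient of variation of the radius jitter.
#' @return list of `nucleus_scene` objects, conditions interleaved A then B.
#' @export
generate_cohort <- function(config_A, config_B, n_per_condition, seed = 1,
                            radius_cv = 0.08) {
  stopifnot(n_per_condition >= 1)
  n <- as.integer(n_per_condition)
  draws <- with_local_seed(seed, list(
    seeds = sample.int(.Machine$integer.max %/% 2L, 2L * n),
    jitter = pmin(pmax(stats::rnorm(2L * n, 1, radius_cv),
                       1 - 2 * radius_cv), 1 + 2 * radius_cv)))
  make <- function(cfg, i, j) {
    cfg$nucleus_radius <- cfg$nucleus_radius * draws$jitter[j]
    cfg$seed <- draws$seeds[j]
    sc <- generate_nucleus_scene(cfg)
    sc$nucleus_id <- sprintf("%s_%03d", cfg$condition, i)
    sc
  }
  scenes_A <- lapply(seq_len(n), function(i) make(config_A, i, i))
  scenes_B <- lapply(seq_len(n), function(i) make(config_B, i, n + i))
  c(scenes_A, scenes_B)
}
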