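#' Optical configuration
#'
#' Constants of the imaging system shared by the simulator, the
#' reconstruction and the sectioning theory. Defaults describe the
#' reference setup: a 1.4 NA, 60x oil objective (n = 1.515), 488/525 nm
#' excitation/emission and a 6.5-um camera pixel, giving a 108.3-nm
#' object-space pixel.
#'
#' The defocus model is an isotropic normalized Gaussian whose width grows
#' with defocus dz as `sigma(dz)^2 = sigma0^2 + (m dz)^2`, with
#' `sigma0 = 0.21 lambda / NA` (Gaussian-Airy matching) and defocus slope
#' `m`. By default `m = tan(asin(NA/n)) / sqrt(2)`, the geometric growth of
#' the marginal-ray cone moderated for the average over aperture angles;
#' [calibrate_defocus_slope()] replaces it with a value matched to a
#' measured single-element axial illumination width.
#'
#' @param na numerical aperture (0 < na < n_medium).
#' @param n_medium immersion refractive index.
#' @param lambda_ex,lambda_em excitation/emission wavelengths, micrometers.
#' @param magnification objective-to-camera magnification.
#' @param camera_pixel_pitch camera pixel pitch, micrometers.
#' @param defocus_slope Gaussian width growth per micrometer defocus, or
#'   NULL for the geometric default.
#' @return an object of class `optical_config` with derived field
#'   `object_pixel = camera_pixel_pitch / magnification` (um).
#' @export
optical_config <- function(na = 1.4, n_medium = 1.515, lambda_ex = 0.488,
                           lambda_em = 0.525, magnification = 60,
                           camera_pixel_pitch = 6.5, defocus_slope = NULL) {
  stopifnot_scalar(na, "na", positive = TRUE)
  stopifnot_scalar(n_medium, "n_medium", positive = TRUE)
  if (na >= n_medium) stop("na must be < n_medium")
  stopifnot_scalar(lambda_ex, "lambda_ex", positive = TRUE)
  stopifnot_scalar(lambda_em, "lambda_em", positive = TRUE)
  stopifnot_scalar(magnification, "magnification", positive = TRUE)
  stopifnot_scalar(camera_pixel_pitch, "camera_pixel_pitch", positive = TRUE)
  if (is.null(defocus_slope))
    defocus_slope <- tan(asin(na / n_medium)) / sqrt(2)
  stopifnot_scalar(defocus_slope, "defocus_slope", positive = TRUE)
  structure(list(na = na, n_medium = n_medium, lambda_ex = lambda_ex,
                 lambda_em = lambda_em, magnification = magnification,
                 camera_pixel_pitch = camera_pixel_pitch,
                 object_pixel = camera_pixel_pitch / magnification,
                 defocus_slope = defocus_slope),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "Optical config: NA %.2f, n %.3f, lambda ex/em %.0f/%.0f nm, %gx, %.2f um px (%.1f nm object), defocus slope %.3f/um\n",
    x$na, x$n_medium, 1e3 * x$lambda_ex, 1e3 * x$lambda_em, x$magnification,
    x$camera_pixel_pitch, 1e3 * x$object_pixel, x$defocus_slope))
  invisible(x)
}

#' Camera noise model
#'
#' Shot noise plus Gaussian read noise. Expected counts are
#' `noiseless_intensity * photon_scale * exposure`; counts are Poisson
#' draws with that mean, plus read noise, rounded to integers and clamped
#' at zero. Identical seeds reproduce identical images.
#'
#' @param photon_scale expected counts per unit emitted intensity per
#'   second (>= 0; 0 gives a noiseless, un-discretized image).
#' @param read_noise_sd read noise standard deviation, counts.
#' @param seed integer RNG seed, or NULL.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 0, read_noise_sd = 0, seed = NULL) {
  if (photon_scale < 0 || read_noise_sd < 0)
    stop("photon_scale and read_noise_sd must be >= 0")
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 seed = seed),
            class = "noise_model")
}

# Gaussian defocus width (um) at defocus dz for a given wavelength.
sigma_defocus <- function(config, dz, wavelength) {
  sigma0 <- 0.21 * wavelength / config$na
  sqrt(sigma0^2 + (config$defocus_slope * dz)^2)
}

#' Defocus point-spread kernel
#'
#' Discrete isotropic Gaussian kernel at defocus `dz`, sampled at spacing
#' `dx` (um) and normalized to sum exactly to 1: defocus conserves power,
#' so the peak falls as the footprint area grows. Support is chosen so the
#' truncated mass is below 1e-4 before renormalization.
#'
#' @param config an [optical_config()].
#' @param dz defocus in micrometers.
#' @param wavelength wavelength in micrometers (> 0).
#' @param dx sample spacing in micrometers (default: the simulation pixel,
#'   `object_pixel / 4`).
#' @return square matrix of odd side, summing to 1, with attribute
#'   `sigma_um`.
#' @export
defocus_kernel <- function(config, dz, wavelength, dx = config$object_pixel / 4) {
  stopifnot_scalar(wavelength, "wavelength", positive = TRUE)
  stopifnot_scalar(dx, "dx", positive = TRUE)
  sig <- sigma_defocus(config, dz, wavelength)
  half <- max(2L, ceiling(4.5 * sig / dx))   # 4.5 sigma: truncated mass < 1e-4
  x <- (-half:half) * dx
  g1 <- exp(-x^2 / (2 * sig^2))
  k <- outer(g1, g1)
  k <- k / sum(k)
  attr(k, "sigma_um") <- sig
  k
}

#' Calibrate the defocus slope against a measured axial illumination width
#'
#' The axial illumination response of a single transmitting element (the
#' on-axis excitation intensity as the focal plane is swept through a point
#' sample, the quantity measured with isolated sub-diffraction beads) has a
#' closed form under the Gaussian defocus model: the on-axis intensity of
#' the element's active rectangle blurred by `sigma(dz)` is
#' `erf(ax / (2 sqrt(2) sigma)) * erf(ay / (2 sqrt(2) sigma))`. This
#' function solves for the defocus slope `m` such that the full width at
#' half maximum of that response equals `target_fwhm` (default 0.61 um, the
#' measured single-element value on the reference instrument, whose LED
#' illumination underfills the aperture and defocuses far more slowly than
#' the marginal-ray geometry predicts).
#'
#' @param config an [optical_config()].
#' @param grid an [slm_grid()] (supplies the element active size).
#' @param target_fwhm measured single-element axial illumination FWHM, um.
#' @return `config` with `defocus_slope` replaced by the calibrated value.
#' @export
calibrate_defocus_slope <- function(config, grid, target_fwhm = 0.61) {
  stopifnot_scalar(target_fwhm, "target_fwhm", positive = TRUE)
  ax <- grid$active_frac_x * grid$element_pitch_obj
  ay <- grid$active_frac_y * grid$element_pitch_obj
  on_axis <- function(sig) {
    # erf via pnorm
    erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
    erf(ax / (2 * sqrt(2) * sig)) * erf(ay / (2 * sqrt(2) * sig))
  }
  sigma0 <- 0.21 * config$lambda_ex / config$na
  half_target <- on_axis(sigma0) / 2
  f <- function(sig) on_axis(sig) - half_target
  sig_half <- stats::uniroot(f, c(sigma0 * (1 + 1e-9), 100 * sigma0))$root
  z_half <- target_fwhm / 2
  config$defocus_slope <- sqrt(sig_half^2 - sigma0^2) / z_half
  config
}

#' Excitation intensity volume under a transmission pattern
#'
#' Propagates an object-space transmission map through defocus: at each
#' depth z the excitation intensity is the map convolved with the
#' excitation defocus kernel. Per-plane integrated power is constant in z
#' (the kernels are normalized), so a laterally uniform (widefield) map
#' yields a z-independent intensity: widefield illumination has no axial
#' confinement.
#'
#' @param tmap transmission map on the simulation grid.
#' @param config an [optical_config()].
#' @param z_list depths in micrometers (nonempty).
#' @param dx map sample spacing in micrometers.
#' @param boundary `"periodic"` (exact for a repeating dot array spanning
#'   the field) or `"pad"` (zero-padded, for isolated patterns).
#' @return 3D array, `dim(tmap) x length(z_list)`.
#' @export
illumination_volume <- function(tmap, config, z_list, dx,
                                boundary = c("periodic", "pad")) {
  if (length(z_list) == 0) stop("z_list must be nonempty")
  boundary <- match.arg(boundary)
  out <- array(0, c(dim(tmap), length(z_list)))
  tf <- if (boundary == "periodic") fft2(tmap) else NULL
  for (i in seq_along(z_list)) {
    sig_px <- sigma_defocus(config, z_list[i], config$lambda_ex) / dx
    out[, , i] <- if (boundary == "periodic")
      gauss_blur_periodic(tmap, sig_px, img_fft = tf)
    else gauss_blur_padded(tmap, sig_px)
  }
  out
}

# Apply the camera noise model to a noiseless intensity image.
apply_noise <- function(noiseless, noise, exposure) {
  expected <- noiseless * noise$photon_scale * exposure
  if (noise$photon_scale == 0) return(noiseless * exposure)
  counts <- with_seed(noise$seed, {
    x <- stats::rpois(length(expected), pmax(expected, 0))
    if (noise$read_noise_sd > 0)
      x <- x + stats::rnorm(length(expected), 0, noise$read_noise_sd)
    x
  })
  matrix(pmax(0, round(counts)), nrow(expected), ncol(expected))
}

#' Form one camera sub-image
#'
#' Incoherent fluorescence image formation for one transmission pattern and
#' focal position: each phantom slab at depth z is excited by the
#' defocus-blurred transmission map, emits in proportion to excitation
#' times fluorophore density times slab thickness, is blurred by the
#' emission defocus kernel, and the slab contributions sum on the camera
#' after area-binning the simulation grid to camera pixels. Counts follow
#' the [noise_model()].
#'
#' @param phantom an [phantom()] whose lateral grid matches `geom`.
#' @param tmap transmission map on the simulation grid of `geom`.
#' @param geom a [scan_geometry()].
#' @param focal_z focal-plane depth, micrometers.
#' @param exposure exposure time, seconds (> 0).
#' @param noise a [noise_model()].
#' @param boundary see [illumination_volume()].
#' @return camera image matrix (`geom$fov`).
#' @export
form_subimage <- function(phantom, tmap, geom, focal_z, exposure = 0.1,
                          noise = noise_model(),
                          boundary = c("periodic", "pad")) {
  boundary <- match.arg(boundary)
  stopifnot_scalar(exposure, "exposure", positive = TRUE)
  d <- dim(phantom$density)
  if (!all(d[1:2] == geom$sim_dim))
    stop(sprintf("phantom lateral grid %d x %d does not match simulation grid %d x %d",
                 d[1], d[2], geom$sim_dim[1], geom$sim_dim[2]))
  if (!all(dim(tmap) == geom$sim_dim))
    stop(sprintf("transmission map %d x %d does not match simulation grid %d x %d",
                 nrow(tmap), ncol(tmap), geom$sim_dim[1], geom$sim_dim[2]))
  config <- geom$config
  cam_sim <- matrix(0, geom$sim_dim[1], geom$sim_dim[2])
  tf <- if (boundary == "periodic") fft2(tmap) else NULL
  for (i in seq_len(d[3])) {
    dz <- phantom$z[i] - focal_z
    sl <- phantom$density[, , i]
    if (all(sl == 0)) next
    sig_ex <- sigma_defocus(config, dz, config$lambda_ex) / geom$dx_sim
    sig_em <- sigma_defocus(config, dz, config$lambda_em) / geom$dx_sim
    w <- phantom$z_weight[i]
    uniform <- length(unique(as.vector(sl))) == 1L
    if (boundary == "periodic" && uniform) {
      # uniform slab: excitation and detection blurs commute into one
      cam_sim <- cam_sim + sl[1, 1] * w *
        gauss_blur_periodic(tmap, sqrt(sig_ex^2 + sig_em^2), img_fft = tf)
    } else if (boundary == "periodic") {
      illum <- gauss_blur_periodic(tmap, sig_ex, img_fft = tf)
      cam_sim <- cam_sim + w * gauss_blur_periodic(sl * illum, sig_em)
    } else {
      illum <- gauss_blur_padded(tmap, sig_ex)
      cam_sim <- cam_sim + w * gauss_blur_padded(sl * illum, sig_em)
    }
  }
  # FFT convolution can leave tiny negative ripples; intensity is nonnegative
  noiseless <- pmax(bin_mean(cam_sim, geom$oversample), 0)
  apply_noise(noiseless, noise, exposure)
}

#' Sub-image stack
#'
#' Container for the F camera frames of one focal plane (one frame per
#' scan position, ordered as the scan sequence) plus acquisition metadata.
#'
#' @param frames 3D array `H x W x F` of nonnegative counts.
#' @param focal_z focal-plane depth, um.
#' @param sequence the [scan_sequence()] used.
#' @param map the [element_pixel_map()] used (or NULL).
#' @param exposure seconds.
#' @param seed RNG seed used, or NULL.
#' @param extra named list of additional metadata.
#' @return an object of class `subimage_stack`.
#' @export
subimage_stack <- function(frames, focal_z, sequence, map = NULL,
                           exposure = NA_real_, seed = NULL, extra = list()) {
  if (length(dim(frames)) != 3) stop("frames must be an H x W x F array")
  if (dim(frames)[3] != n_frames(sequence))
    stop(sprintf("stack has %d frames but the sequence defines %d",
                 dim(frames)[3], n_frames(sequence)))
  if (any(frames < 0)) stop("counts must be nonnegative")
  structure(list(frames = frames, focal_z = focal_z, sequence = sequence,
                 map = map, exposure = exposure, seed = seed, extra = extra),
            class = "subimage_stack")
}

#' @export
print.subimage_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Sub-image stack: %d x %d px, %d frames, focal z %.3f um\n",
              d[1], d[2], d[3], x$focal_z))
  invisible(x)
}

#' Acquire a full patterned-illumination scan
#'
#' Simulates the acquisition loop: for each focal plane, one sub-image per
#' scan position, in sequence order. Frame k of every stack is seeded
#' deterministically from `noise$seed`, the focal index and k, so a rerun
#' with the same seed is bit-identical.
#'
#' @param phantom an [phantom()].
#' @param grid an [slm_grid()].
#' @param sequence a [scan_sequence()].
#' @param map an [element_pixel_map()].
#' @param geom a [scan_geometry()].
#' @param focal_z_list focal-plane depths, um.
#' @param exposure seconds.
#' @param noise a [noise_model()].
#' @param boundary see [illumination_volume()].
#' @return list of [subimage_stack()] objects, one per focal plane.
#' @export
acquire_scan <- function(phantom, grid, sequence, map, geom, focal_z_list,
                         exposure = 0.1, noise = noise_model(),
                         boundary = c("periodic", "pad")) {
  boundary <- match.arg(boundary)
  tmaps <- lapply(seq_len(n_frames(sequence)), function(k)
    frame_transmission_map(grid, sequence, k, geom, map))
  out <- vector("list", length(focal_z_list))
  for (zi in seq_along(focal_z_list)) {
    fr <- array(0, c(geom$fov, n_frames(sequence)))
    for (k in seq_len(n_frames(sequence))) {
      nm <- noise
      if (!is.null(noise$seed))
        nm$seed <- (noise$seed + 1009L * zi + k) %% .Machine$integer.max
      fr[, , k] <- form_subimage(phantom, tmaps[[k]], geom,
                                 focal_z_list[zi], exposure, nm, boundary)
    }
    out[[zi]] <- subimage_stack(fr, focal_z_list[zi], sequence, map,
                                exposure, noise$seed)
  }
  out
}

#' Widefield (all-elements-on) transmission map
#'
#' Transmission with every element on: the widefield reference that the
#' scanned acquisition is compared against. Conduit regions still leak at
#' `1/extinction_ratio`.
#'
#' @inheritParams frame_transmission_map
#' @return transmission matrix on the simulation grid.
#' @export
widefield_transmission_map <- function(grid, geom, map) {
  seq1 <- scan_sequence(1, 1)
  frame_transmission_map(grid, seq1, 1, geom, map)
}
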