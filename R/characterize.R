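#' Simulate and measure the thin-film axial sectioning response
#'
#' End-to-end characterization on the standard diffuse target: a uniform
#' optically thin fluorescent film is imaged through a focal sweep with
#' either the unit-cell dot-array scan (reconstructed by the chosen
#' strategy) or plain widefield illumination, and the per-plane mean
#' intensity is fitted for its axial FWHM.
#'
#' The simulation uses periodic lateral boundaries — exact for an extended
#' film under a dot array that tiles the field — and, for the scanned
#' mode, the identity that excitation and detection blurs of a uniform
#' slab compose into a single Gaussian of width
#' `sqrt(sigma_ex^2 + sigma_em^2)` (verified against the general image
#' former in the test suite). By default the defocus slope is calibrated
#' with [calibrate_defocus_slope()] so the single-element axial
#' illumination response matches the instrument's measured 0.61 um.
#'
#' @param mode `"scan"` (dot-array scan + reconstruction) or
#'   `"widefield"`.
#' @param strategy reconstruction strategy for scan mode.
#' @param seed integer seed for the photon noise.
#' @param fov camera field of view `c(H, W)` (default 64 x 64).
#' @param z_max,z_step focal sweep half-range and step, um (defaults 3 and
#'   0.05, the standard film z-stack protocol).
#' @param unit_cell scan unit cell `c(u, v)` (default 6 x 6).
#' @param config an [optical_config()]; default [optical_config()].
#' @param map an [element_pixel_map()]; default [element_pixel_map()].
#' @param oversample simulation sub-pixels per camera pixel.
#' @param exposure seconds per sub-image.
#' @param photon_scale,read_noise_sd camera noise parameters (see
#'   [noise_model()]); `photon_scale = 0` disables noise.
#' @param film_thickness,film_level film thickness (um) and density.
#' @param calibrate if TRUE, calibrate the defocus slope to
#'   `illum_fwhm_um`.
#' @param illum_fwhm_um measured single-element axial illumination FWHM
#'   used for calibration, um.
#' @param fill uncovered-pixel policy for pick reconstruction.
#' @return list of class `film_characterization`: `response` (an
#'   [thin_film_axial_response()] result), `z`, `mean_intensity`, `mode`,
#'   `strategy`, `config`, `grid`, `map`, `seed`.
#' @export
characterize_thin_film <- function(mode = c("scan", "widefield"),
                                   strategy = c("pick", "max", "sum"),
                                   seed = 1, fov = c(64, 64), z_max = 3,
                                   z_step = 0.05, unit_cell = c(6, 6),
                                   config = optical_config(),
                                   map = element_pixel_map(),
                                   oversample = 4, exposure = 0.1,
                                   photon_scale = 2e4, read_noise_sd = 2,
                                   film_thickness = 0.1, film_level = 1,
                                   calibrate = TRUE, illum_fwhm_um = 0.61,
                                   fill = "max") {
  mode <- match.arg(mode)
  strategy <- match.arg(strategy)
  geom <- scan_geometry(config, fov, oversample)
  grid <- slm_grid_for_fov(geom, map)
  if (calibrate) {
    config <- calibrate_defocus_slope(config, grid, illum_fwhm_um)
    geom <- scan_geometry(config, fov, oversample)
  }
  film <- make_thin_film(geom, film_thickness, film_level, z0 = 0)
  z_list <- seq(-z_max, z_max, by = z_step)
  if (mode == "widefield") {
    sequence <- scan_sequence(1, 1)
    assignment <- NULL
  } else {
    sequence <- scan_sequence(unit_cell[1], unit_cell[2])
    assignment <- if (strategy == "pick")
      assign_pixels_to_frames(map, grid, sequence, geom$fov) else NULL
  }
  nf <- n_frames(sequence)
  tmap_ffts <- lapply(seq_len(nf), function(k)
    fft2(frame_transmission_map(grid, sequence, k, geom, map)))
  level <- film_level * film_thickness
  means <- numeric(length(z_list))
  for (zi in seq_along(z_list)) {
    dz <- film$z[1] - z_list[zi]
    sig <- sqrt(sigma_defocus(config, dz, config$lambda_ex)^2 +
                  sigma_defocus(config, dz, config$lambda_em)^2) / geom$dx_sim
    tf <- gauss_transfer(geom$sim_dim, sig)
    frames <- array(0, c(geom$fov, nf))
    for (k in seq_len(nf)) {
      noiseless <- bin_mean(level * ifft2(tmap_ffts[[k]] * tf),
                            geom$oversample)
      nm <- noise_model(photon_scale, read_noise_sd,
                        seed = if (photon_scale > 0)
                          (seed + 1009L * zi + k) %% .Machine$integer.max
                        else NULL)
      frames[, , k] <- apply_noise(noiseless, nm, exposure)
    }
    stack <- subimage_stack(frames, z_list[zi], sequence, map, exposure, seed)
    rec <- switch(strategy,
                  sum = reconstruct_sum(stack),
                  max = reconstruct_max(stack),
                  pick = if (mode == "widefield") reconstruct_sum(stack)
                  else reconstruct_pick(stack, assignment, fill))
    means[zi] <- mean(rec$pixels)
  }
  resp <- thin_film_axial_response(means, z_list)
  structure(list(response = resp, z = z_list, mean_intensity = means,
                 mode = mode, strategy = if (mode == "widefield") "widefield"
                 else strategy,
                 config = config, grid = grid, map = map, seed = seed),
            class = "film_characterization")
}

#' @export
print.film_characterization <- function(x, ...) {
  cat(sprintf("Thin-film characterization (%s): ", x$strategy))
  print(x$response)
  invisible(x)
}
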