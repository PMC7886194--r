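# Shared miniature simulation setups. Everything is generated in code; no
# stored fixtures beyond the bundled reference SBR table.

base_config <- function(...) optical_config(...)

small_geom <- function(fov = c(32, 32), oversample = 4,
                       config = optical_config()) {
  scan_geometry(config, fov, oversample)
}

# calibrated config + matching geometry/grid/map bundle used by the
# simulation-heavy tests
calibrated_setup <- function(fov = c(32, 32), oversample = 4) {
  cfg <- optical_config()
  map <- element_pixel_map()
  geom <- scan_geometry(cfg, fov, oversample)
  grid <- slm_grid_for_fov(geom, map)
  cfg <- calibrate_defocus_slope(cfg, grid)
  geom <- scan_geometry(cfg, fov, oversample)
  list(config = cfg, map = map, geom = geom, grid = grid)
}

# random integer-count stack with a matching trivial sequence
random_stack <- function(h = 16, w = 16, u = 2, v = 2, seed = 1,
                         lambda = 50) {
  sq <- scan_sequence(u, v)
  fr <- slmscope:::with_seed(seed,
    array(stats::rpois(h * w * u * v, lambda), c(h, w, u * v)))
  subimage_stack(fr, 0, sq, element_pixel_map(scale = 4), 0.1, seed)
}

# brute-force per-pixel reconstruction oracles
oracle_sum <- function(frames) {
  out <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (i in seq_len(dim(frames)[1]))
    for (j in seq_len(dim(frames)[2]))
      out[i, j] <- sum(frames[i, j, ])
  out
}
oracle_max <- function(frames) {
  out <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (i in seq_len(dim(frames)[1]))
    for (j in seq_len(dim(frames)[2]))
      out[i, j] <- max(frames[i, j, ])
  out
}
oracle_pick <- function(frames, assignment) {
  d <- dim(frames)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      fs <- assignment$frames_px[i, j, ]
      fs <- fs[!is.na(fs)]
      if (length(fs)) out[i, j] <- max(frames[i, j, fs])
    }
  }
  out
}

# independent per-element rasterization of the pinhole assignment
oracle_assignment_sets <- function(map, grid, sequence, image_shape) {
  ctr <- slmscope:::element_centers_px(map, grid, image_shape)
  r <- map$pinhole_diameter_px / 2
  sets <- vector("list", image_shape[1] * image_shape[2])
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      off_r <- (i - 1) %% sequence$unit_rows
      off_c <- (j - 1) %% sequence$unit_cols
      k <- which(sequence$frames[, "row_offset"] == off_r &
                   sequence$frames[, "col_offset"] == off_c)
      for (py in seq_len(image_shape[1])) {
        dy2 <- (py - ctr$y[i, j])^2
        if (dy2 > r^2) next
        for (px in seq_len(image_shape[2])) {
          if (dy2 + (px - ctr$x[i, j])^2 <= r^2) {
            id <- (px - 1) * image_shape[1] + py
            sets[[id]] <- sort(unique(c(sets[[id]], k)))
          }
        }
      }
    }
  }
  sets
}
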