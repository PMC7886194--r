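test_that("defocus kernels conserve power and decay monotonically", {
  cfg <- optical_config()
  peaks <- c()
  for (dz in c(0, 0.5, 1, 2)) {
    k <- defocus_kernel(cfg, dz, cfg$lambda_ex)
    expect_equal(sum(k), 1, tolerance = 1e-7)
    peaks <- c(peaks, max(k))
  }
  expect_true(all(diff(peaks) < 0))  # focus maximizes intensity
  expect_error(defocus_kernel(cfg, 0, 0), "wavelength")
})

test_that("widefield illumination is axially flat, one element is confined", {
  cfg <- optical_config()
  map <- element_pixel_map(scale = 4)
  geom <- scan_geometry(cfg, c(32, 32), 4)
  grid <- slm_grid_for_fov(geom, map)
  # laterally uniform map: per-plane excitation flat over depth
  uni <- matrix(1, geom$sim_dim[1], geom$sim_dim[2])
  vol <- illumination_volume(uni, cfg, c(-10, -3, 0, 3, 10), geom$dx_sim)
  mns <- apply(vol, 3, mean)
  expect_lt(diff(range(mns)) / mean(mns), 0.01)
  # single transmitting element: on-axis intensity strictly decreasing in |z|
  sq_all <- scan_sequence(grid$n_rows, grid$n_cols)
  kc <- which(sq_all$frames[, 1] == (grid$n_rows - 1) %/% 2 &
                sq_all$frames[, 2] == (grid$n_cols - 1) %/% 2)
  tm <- frame_transmission_map(grid, sq_all, kc, geom, map)
  v2 <- illumination_volume(tm, cfg, c(0, 0.5, 1, 2), geom$dx_sim)
  on_axis <- apply(v2, 3, max)
  expect_true(all(diff(on_axis) < 0))
})

test_that("sectioning strengthens with numerical aperture", {
  width_at_na <- function(na) {
    cfg <- optical_config(na = na)           # geometric defocus slope
    map <- element_pixel_map(scale = 4)
    geom <- scan_geometry(cfg, c(32, 32), 4)
    grid <- slm_grid_for_fov(geom, map)
    sq_all <- scan_sequence(grid$n_rows, grid$n_cols)
    kc <- which(sq_all$frames[, 1] == (grid$n_rows - 1) %/% 2 &
                  sq_all$frames[, 2] == (grid$n_cols - 1) %/% 2)
    tm <- frame_transmission_map(grid, sq_all, kc, geom, map)
    zs <- seq(-0.6, 0.6, 0.02)
    prof <- apply(illumination_volume(tm, cfg, zs, geom$dx_sim), 3, max)
    width_at_fraction(zs, prof, 0.5, offset = 0)
  }
  expect_lt(width_at_na(1.4), width_at_na(1.0))
})

test_that("illumination volumes shift with the pattern", {
  cfg <- optical_config()
  geom <- scan_geometry(cfg, c(16, 16), 2)
  tm <- matrix(0, 32, 32); tm[10, 12] <- 1
  tm_sh <- matrix(0, 32, 32); tm_sh[15, 18] <- 1   # shift (5, 6)
  v <- illumination_volume(tm, cfg, c(0, 0.5), geom$dx_sim)
  vs <- illumination_volume(tm_sh, cfg, c(0, 0.5), geom$dx_sim)
  for (k in 1:2) {
    rolled <- v[, , k][((seq_len(32) - 1 - 5) %% 32) + 1,
                       ((seq_len(32) - 1 - 6) %% 32) + 1]
    expect_equal(vs[, , k], rolled, tolerance = 1e-12)
  }
  expect_error(illumination_volume(tm, cfg, numeric(0), geom$dx_sim),
               "nonempty")
})

test_that("image formation is linear and scales with exposure", {
  su <- calibrated_setup(c(16, 16), 2)
  sq <- scan_sequence(2, 2)
  tm <- frame_transmission_map(su$grid, sq, 1, su$geom, su$map)
  noise0 <- noise_model(0)
  fa <- make_thin_film(su$geom, 0.1, 1)
  fb <- make_thin_film(su$geom, 0.1, 2.5)
  fab <- make_thin_film(su$geom, 0.1, 3.5)
  ia <- form_subimage(fa, tm, su$geom, 0.3, 1, noise0)
  ib <- form_subimage(fb, tm, su$geom, 0.3, 1, noise0)
  iab <- form_subimage(fab, tm, su$geom, 0.3, 1, noise0)
  expect_equal(iab, ia + ib, tolerance = 1e-10)
  expect_equal(form_subimage(fa, tm, su$geom, 0.3, 2, noise0), 2 * ia,
               tolerance = 1e-12)
  # zero phantom, no read noise: exactly zero counts
  zero <- phantom(array(0, c(su$geom$sim_dim, 1)), 0, 0.1, su$geom$dx_sim)
  iz <- form_subimage(zero, tm, su$geom, 0, 1, noise_model(1e4, 0, seed = 3))
  expect_true(all(iz == 0))
})

test_that("uniform-slab fast path equals the general image former", {
  su <- calibrated_setup(c(16, 16), 2)
  sq <- scan_sequence(2, 2)
  tm <- frame_transmission_map(su$grid, sq, 2, su$geom, su$map)
  film <- make_thin_film(su$geom, 0.1, 1.7, z0 = 0.2)
  fast <- form_subimage(film, tm, su$geom, -0.4, 1, noise_model(0))
  # explicit two-blur reference (excitation then emission)
  dzv <- 0.2 - (-0.4)
  sig_ex <- slmscope:::sigma_defocus(su$config, dzv, su$config$lambda_ex) /
    su$geom$dx_sim
  sig_em <- slmscope:::sigma_defocus(su$config, dzv, su$config$lambda_em) /
    su$geom$dx_sim
  illum <- slmscope:::gauss_blur_periodic(tm, sig_ex)
  em <- 1.7 * illum
  ref <- slmscope:::gauss_blur_periodic(em, sig_em) * 0.1
  ref <- pmax(slmscope:::bin_mean(ref, su$geom$oversample), 0)
  expect_equal(fast, ref, tolerance = 1e-9)
})

test_that("a full scan acquisition is reproducible and frame-complete", {
  su <- calibrated_setup(c(16, 16), 2)
  sq <- scan_sequence(6, 6)
  film <- make_thin_film(su$geom)
  nm <- noise_model(1e4, 2, seed = 11)
  s1 <- acquire_scan(film, su$grid, sq, su$map, su$geom, c(-0.2, 0.2),
                     0.1, nm)
  s2 <- acquire_scan(film, su$grid, sq, su$map, su$geom, c(-0.2, 0.2),
                     0.1, nm)
  expect_length(s1, 2)
  expect_equal(dim(s1[[1]]$frames)[3], 36)
  expect_identical(s1[[1]]$frames, s2[[1]]$frames)  # seeded determinism
  expect_identical(s1[[2]]$frames, s2[[2]]$frames)
  # different seed differs
  s3 <- acquire_scan(film, su$grid, sq, su$map, su$geom, c(-0.2, 0.2),
                     0.1, noise_model(1e4, 2, seed = 12))
  expect_false(identical(s1[[1]]$frames, s3[[1]]$frames))
})

test_that("summing the scan reproduces widefield up to extinction leakage", {
  su <- calibrated_setup(c(48, 48), 4)
  sq <- scan_sequence(6, 6)
  film <- make_thin_film(su$geom)
  noise0 <- noise_model(0)
  st <- acquire_scan(film, su$grid, sq, su$map, su$geom, 0, 1, noise0)[[1]]
  sum_img <- reconstruct_sum(st)$pixels
  wf <- form_subimage(film, widefield_transmission_map(su$grid, su$geom,
                                                       su$map),
                      su$geom, 0, 1, noise0)
  # leakage bound is relative to the full-transmission image level
  unit <- form_subimage(film,
                        matrix(1, su$geom$sim_dim[1], su$geom$sim_dim[2]),
                        su$geom, 0, 1, noise0)
  rel <- max(abs(sum_img - wf)) / max(unit)
  expect_lt(rel, 36 / su$grid$extinction_ratio)
})
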