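test_that("sum/max reconstructions equal per-pixel loop oracles", {
  for (seed in 1:3) {
    st <- random_stack(16, 16, 2, 2, seed = seed)
    expect_equal(reconstruct_sum(st)$pixels, oracle_sum(st$frames))
    expect_equal(reconstruct_max(st)$pixels, oracle_max(st$frames))
  }
  # single-frame stack: sum is the identity
  st1 <- random_stack(8, 8, 1, 1, seed = 9)
  expect_equal(reconstruct_sum(st1)$pixels, st1$frames[, , 1])
  # frame permutation leaves max unchanged
  st <- random_stack(12, 12, 2, 2, seed = 4)
  stp <- st; stp$frames <- st$frames[, , c(3, 1, 4, 2)]
  expect_equal(reconstruct_max(stp)$pixels, reconstruct_max(st)$pixels)
})

test_that("pick matches its oracle and the pick <= max <= sum ordering", {
  cfg <- optical_config()
  geom <- scan_geometry(cfg, c(24, 24), 2)
  sq <- scan_sequence(2, 2)
  map <- element_pixel_map(scale = 3.5)
  grid <- slm_grid_for_fov(geom, map)
  a <- assign_pixels_to_frames(map, grid, sq, c(24, 24))
  for (seed in 1:3) {
    st <- random_stack(24, 24, 2, 2, seed = seed)
    pk <- reconstruct_pick(st, a, fill = "max")$pixels
    orc <- oracle_pick(st$frames, a)
    orc[a$uncovered] <- oracle_max(st$frames)[a$uncovered]
    expect_equal(pk, orc)
    mx <- reconstruct_max(st)$pixels
    sm <- reconstruct_sum(st)$pixels
    expect_true(all(pk <= mx + 1e-12))
    expect_true(all(mx <= sm + 1e-12))
  }
  # identical frames: pick equals the frame for any assignment
  stc <- random_stack(24, 24, 2, 2, seed = 5)
  stc$frames <- array(rep(stc$frames[, , 1], 4), dim(stc$frames))
  expect_equal(reconstruct_pick(stc, a, fill = "max")$pixels,
               stc$frames[, , 1])
})

test_that("pick honors the frame mosaic and the shared-pixel max rule", {
  cfg <- optical_config()
  geom <- scan_geometry(cfg, c(32, 32), 2)
  sq <- scan_sequence(2, 2)
  map <- element_pixel_map(scale = 4, pinhole_diameter_px = 4)
  grid <- slm_grid_for_fov(geom, map)
  a <- assign_pixels_to_frames(map, grid, sq, c(32, 32))
  # frames nonzero exactly on their own assigned pixels -> pick = mosaic
  fr <- array(0, c(32, 32, 4))
  for (k in 1:4) {
    own <- !is.na(a$frames_px[, , 1]) & a$frames_px[, , 1] == k
    m <- matrix(0, 32, 32); m[own] <- 100 + k
    fr[, , k] <- m
  }
  st <- subimage_stack(fr, 0, sq, map, 0.1, 1)
  pk <- reconstruct_pick(st, a, fill = "zero")$pixels
  for (k in 1:4) {
    own <- !is.na(a$frames_px[, , 1]) & a$frames_px[, , 1] == k &
      !a$shared
    expect_true(all(pk[own] == 100 + k))
  }
  # shared pixels take the max over exactly the claiming frames
  map_shared <- element_pixel_map(scale = 3.5, pinhole_diameter_px = 4)
  grid2 <- slm_grid_for_fov(geom, map_shared)
  a2 <- assign_pixels_to_frames(map_shared, grid2, sq, c(32, 32))
  sh <- which(a2$shared, arr.ind = TRUE)
  expect_gt(nrow(sh), 0)
  st2 <- random_stack(32, 32, 2, 2, seed = 6)
  pk2 <- reconstruct_pick(st2, a2, fill = "zero")$pixels
  i <- sh[1, 1]; j <- sh[1, 2]
  claimers <- a2$frames_px[i, j, ][!is.na(a2$frames_px[i, j, ])]
  expect_equal(pk2[i, j], max(st2$frames[i, j, claimers]))
})

test_that("uncovered pixels follow the configured policy", {
  cfg <- optical_config()
  geom <- scan_geometry(cfg, c(32, 32), 2)
  sq <- scan_sequence(2, 2)
  map <- element_pixel_map(scale = 3.5)
  grid <- slm_grid_for_fov(geom, map)
  a <- assign_pixels_to_frames(map, grid, sq, c(32, 32))
  expect_gt(sum(a$uncovered), 0)
  st <- random_stack(32, 32, 2, 2, seed = 2)
  expect_error(reconstruct_pick(st, a), "no virtual pinhole")
  mx <- reconstruct_max(st)$pixels
  pk <- reconstruct_pick(st, a, fill = "max")$pixels
  expect_equal(pk[a$uncovered], mx[a$uncovered])
  z <- reconstruct_pick(st, a, fill = "zero")$pixels
  expect_true(all(z[a$uncovered] == 0))
  # shape mismatch is refused
  st_small <- random_stack(16, 16, 2, 2, seed = 2)
  expect_error(reconstruct_pick(st_small, a, fill = "max"), "assignment")
})

test_that("z-stack reconstruction preserves plane order and metadata", {
  su <- calibrated_setup(c(16, 16), 2)
  sq <- scan_sequence(2, 2)
  film <- make_thin_film(su$geom)
  zs <- c(-0.4, 0, 0.4)
  stacks <- acquire_scan(film, su$grid, sq, su$map, su$geom, zs, 0.1,
                         noise_model(1e4, 0, seed = 8))
  a <- assign_pixels_to_frames(su$map, su$grid, sq, su$geom$fov)
  zst <- reconstruct_zstack(stacks, "pick", a, fill = "max")
  expect_equal(zst$focal_z, zs)
  expect_equal(dim(zst$volume)[3], 3)
  # one plane equals the 2D reconstruction
  expect_equal(zst$volume[, , 2],
               reconstruct_pick(stacks[[2]], a, "max")$pixels)
  # permuting planes then sorting restores the original
  perm <- c(3, 1, 2)
  zp <- reconstruct_zstack(stacks[perm], "pick", a, fill = "max")
  o <- order(zp$focal_z)
  expect_equal(zp$volume[, , o], zst$volume)
  # film plane is the brightest in a pick z-stack
  means <- apply(zst$volume, 3, mean)
  expect_equal(which.max(means), 2L)
})

test_that("cross calibration recovers a known map", {
  cfg <- optical_config()
  truth <- element_pixel_map(scale = 3.5, offset_x = 1.7, offset_y = -2.3,
                             rotation = 0.5 * pi / 180)
  grid <- slm_grid(25, 25, 3.5 * cfg$object_pixel)
  cross <- render_cross_target(grid, truth, c(128, 128))
  est <- calibrate_alignment(cross, grid, initial_guess = list(scale = 3.5))
  expect_lt(abs(est$offset_x - 1.7), 0.1)
  expect_lt(abs(est$offset_y - (-2.3)), 0.1)
  expect_lt(abs(est$rotation - truth$rotation) * 180 / pi, 0.05)
  expect_lt(abs(est$scale - 3.5) / 3.5, 0.05)
  # identity map recovered as identity
  id <- element_pixel_map(scale = 3.5)
  cross_id <- render_cross_target(grid, id, c(128, 128))
  est_id <- calibrate_alignment(cross_id, grid, list(scale = 3.5))
  expect_lt(abs(est_id$offset_x), 0.05)
  expect_lt(abs(est_id$offset_y), 0.05)
  expect_lt(abs(est_id$rotation) * 180 / pi, 0.02)
})

test_that("cross calibration degrades gracefully under Poisson noise", {
  cfg <- optical_config()
  truth <- element_pixel_map(scale = 3.5, offset_x = 1.7, offset_y = -2.3,
                             rotation = 0.5 * pi / 180)
  grid <- slm_grid(25, 25, 3.5 * cfg$object_pixel)
  cross <- render_cross_target(grid, truth, c(128, 128), amplitude = 100,
                               background = 5, poisson = TRUE, seed = 7)
  est <- calibrate_alignment(cross, grid, list(scale = 3.5))
  expect_lt(abs(est$offset_x - 1.7), 0.3)
  expect_lt(abs(est$offset_y - (-2.3)), 0.3)
  # a blank image is not a cross
  blank <- matrix(5, 128, 128)
  expect_error(calibrate_alignment(blank, grid, list(scale = 3.5)),
               "not detected")
})
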