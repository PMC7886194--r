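test_that("gaussian_fwhm recovers analytic widths and offsets", {
  x <- seq(-6, 6, 0.05)
  f <- gaussian_fwhm(x, exp(-x^2 / 2))
  expect_equal(f$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)
  f2 <- gaussian_fwhm(x, 3 * exp(-(x - 0.7)^2 / 2) + 10)  # offset-invariant
  expect_equal(f2$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)
  expect_equal(f2$offset, 10, tolerance = 1e-6)
  expect_error(gaussian_fwhm(1:4, 1:4), "5 points")
})

test_that("gaussian_fwhm is unbiased under 1% noise (Monte Carlo)", {
  x <- seq(-5, 5, 0.1)
  truth <- 2 * sqrt(2 * log(2)) * 1.3
  got <- slmscope:::with_seed(42, {
    vapply(1:200, function(i) {
      y <- exp(-x^2 / (2 * 1.3^2)) + stats::rnorm(length(x), 0, 0.01)
      gaussian_fwhm(x, y)$fwhm
    }, 0)
  })
  expect_equal(mean(got), truth, tolerance = 0.01)
})

test_that("width_at_fraction handles analytic shapes and bimodality", {
  x <- seq(-8, 8, 0.01)
  y <- exp(-x^2 / 2)
  fwhm <- width_at_fraction(x, y, 0.5, offset = 0)
  fwtm <- width_at_fraction(x, y, 0.1, offset = 0)
  expect_equal(fwtm / fwhm, sqrt(log(10) / log(2)), tolerance = 1e-3)
  # symmetric triangle of half-width w at fraction 0.5 has width w
  w <- 2
  ytri <- pmax(0, 1 - abs(x) / w)
  expect_equal(width_at_fraction(x, ytri, 0.5, offset = 0), w,
               tolerance = 1e-3)
  # bimodal: outermost crossings span both lobes (vs brute-force scan)
  yb <- exp(-(x - 3)^2 / 2) + exp(-(x + 3)^2 / 2)
  lev <- 0.1 * max(yb)
  idx <- which(yb >= lev)
  brute <- x[max(idx)] - x[min(idx)]
  expect_equal(width_at_fraction(x, yb, 0.1, offset = 0), brute,
               tolerance = 0.02)
  # agreement of the two width estimators on a clean unimodal profile
  expect_equal(width_at_fraction(x, y, 0.5), gaussian_fwhm(x, y)$fwhm,
               tolerance = 0.02)
})

test_that("thin-film responses distinguish flat from peaked profiles", {
  z <- seq(-2, 2, 0.05)
  flat <- slmscope:::with_seed(1, 100 + stats::rnorm(length(z), 0, 1))
  r <- thin_film_axial_response(flat, z)
  expect_false(r$measurable)
  expect_true(is.na(r$fwhm))
  peaked <- 10 + 100 * exp(-z^2 / (2 * 0.36^2))
  r2 <- thin_film_axial_response(peaked, z)
  expect_true(r2$measurable)
  expect_equal(r2$fwhm, 2.3548 * 0.36, tolerance = 1e-3)
  # symmetric under z-reversal
  r3 <- thin_film_axial_response(rev(peaked), z)
  expect_equal(r3$fwhm, r2$fwhm, tolerance = 1e-6)
})

test_that("axial illumination profiles subtract background and capture light", {
  # synthetic bead stack: Gaussian spot whose amplitude encodes illumination
  n <- 41; zn <- 21
  amp <- exp(-(seq(-1, 1, length.out = zn))^2 / (2 * 0.3^2))
  mk <- function(bg) {
    arr <- array(bg, c(n, n, zn))
    sp <- outer(exp(-((1:n) - 21)^2 / 8), exp(-((1:n) - 21)^2 / 8))
    for (k in 1:zn) arr[, , k] <- arr[, , k] + 50 * amp[k] * sp
    arr
  }
  st <- mk(7)
  prof_raw <- axial_illumination_profile(st, roi_radius_um = 1.5,
                                         pixel_size_um = 0.108)
  bg <- array(7, c(n, n, zn))
  prof <- axial_illumination_profile(st, 1.5, 0.108, background_stack = bg)
  expect_equal(prof / max(prof), amp, tolerance = 1e-6)
  # zero background stack leaves raw sums untouched
  prof0 <- axial_illumination_profile(st, 1.5, 0.108,
                                      background_stack = array(0, dim(st)))
  expect_equal(prof0, prof_raw)
  # ROI already captures all bead light: enlarging changes < 1%
  prof_big <- axial_illumination_profile(st, 2.1, 0.108,
                                         background_stack = bg)
  expect_lt(max(abs(prof_big - prof) / max(prof)), 0.01)
})

test_that("average_beads recovers sub-pixel centers and averages", {
  # one synthetic bead with known sub-pixel offset
  n <- 33; zn <- 9
  mk_bead <- function(cy, cx) {
    arr <- array(2, c(n, n, zn))
    for (k in 1:zn) {
      a <- 100 * exp(-((k - 5)^2) / 4)
      arr[, , k] <- arr[, , k] +
        a * outer(exp(-((1:n) - cy)^2 / (2 * 2.2^2)),
                  exp(-((1:n) - cx)^2 / (2 * 2.2^2)))
    }
    arr
  }
  av <- average_beads(mk_bead(17.3, 16.6), expected_diameter_px = 5)
  expect_equal(av$n_beads, 1)
  expect_lt(abs(av$centers[1, "row"] - 17.3), 0.1)
  expect_lt(abs(av$centers[1, "col"] - 16.6), 0.1)
  # two identical beads average to either one
  one <- mk_bead(10.2, 10.2)
  two <- one
  sh <- mk_bead(24.2, 24.2)
  two <- two + sh - 2   # keep background at 2
  av2 <- average_beads(two, expected_diameter_px = 5)
  expect_equal(av2$n_beads, 2)
  prof_mid <- av2$axial_profile / max(av2$axial_profile)
  ref <- average_beads(one, expected_diameter_px = 5)
  expect_equal(prof_mid, ref$axial_profile / max(ref$axial_profile),
               tolerance = 0.05)
  expect_error(average_beads(array(0, c(8, 8, 3)), 4), "no beads")
})

test_that("profile SBR applies the two-sided background band rules", {
  px <- 0.1   # um per sample
  prof <- rep(1, 60); prof[30] <- 3
  r <- profile_sbr(prof, px, peak_indices = 30)
  expect_equal(r$sbr, 3)
  expect_equal(r$sides_used, "both")
  # constant profile: peak equals background, sbr 1
  r1 <- profile_sbr(rep(2, 60), px, peak_indices = 30)
  expect_equal(r1$sbr, 1)
  # two peaks 1.2 um apart exclude each other's side
  prof2 <- rep(1, 80); prof2[30] <- 5; prof2[42] <- 4
  r2 <- profile_sbr(prof2, px, peak_indices = c(30, 42))
  expect_equal(r2$sides_used, c("left", "right"))
  # scale invariance, offset sensitivity
  r3 <- profile_sbr(prof2 * 7, px, peak_indices = c(30, 42))
  expect_equal(r3$sbr, r2$sbr)
  r4 <- profile_sbr(prof2 + 5, px, peak_indices = c(30, 42))
  expect_false(isTRUE(all.equal(r4$sbr, r2$sbr)))
  # both sides excluded is an error
  prof3 <- rep(1, 40); prof3[19] <- 5; prof3[20] <- 4.9; prof3[21] <- 5.2
  expect_error(profile_sbr(prof3, px, peak_indices = c(19, 20, 21)),
               "both background sides")
})

test_that("fiber counting is a strict threshold and monotone", {
  sbr <- c(2.0, 1.5, 1.51, 0.9, 7)
  expect_equal(count_clear_fibers(sbr), 3)        # 1.5 fails strictly
  cnt <- vapply(c(0.5, 1, 1.5, 2, 5), function(t)
    count_clear_fibers(sbr, t), 0)
  expect_true(all(diff(cnt) <= 0))
})

test_that("SBR table summaries recompute means, SDs and ratios", {
  tab <- data.frame(peak = 1:2, widefield = c(2, 4), slm = c(6, 8),
                    confocal = c(12, 8))
  s <- sbr_table_summary(tab)
  expect_equal(unname(s$column_mean["widefield"]), 3)
  expect_equal(unname(s$column_sd["slm"]), stats::sd(c(6, 8)))
  expect_equal(s$ratio_rows[["slm/widefield"]], c(3, 2))
  expect_equal(unname(s$ratio_mean["slm/widefield"]), 2.5)
  # single-row table: mean = row, sd = 0 (NA-free contract)
  s1 <- sbr_table_summary(data.frame(widefield = 2, slm = 5, confocal = 9))
  expect_equal(unname(s1$column_mean), c(2, 5, 9))
  expect_equal(s1$n, 1)
})

test_that("pinhole arithmetic and the sectioning formula are exact", {
  expect_equal(pinhole_object_diameter(4, 6.5, 60), 4 * 6.5 / 60)
  expect_equal(pinhole_object_diameter(1, 6.5, 1), 6.5)
  expect_equal(pinhole_object_diameter(2, 6.5, 60), 13 / 60)
  # zero pinhole leaves the diffraction-limited term
  d0 <- theoretical_axial_fwhm(0.525, 1.515, 1.4, 0)
  expect_equal(d0, 0.88 * 0.525 / (1.515 - sqrt(1.515^2 - 1.4^2)),
               tolerance = 1e-12)
  # strictly increasing in pinhole diameter
  ph <- seq(0, 2, 0.05)
  v <- vapply(ph, function(p) theoretical_axial_fwhm(0.525, 1.515, 1.4, p), 0)
  expect_true(all(diff(v) > 0))
  expect_error(theoretical_axial_fwhm(0.525, 1.4, 1.5, 0.4), "na must be")
})

test_that("rounding for reports is half away from zero", {
  expect_equal(round_half_up(0.835, 2), 0.84)
  expect_equal(round_half_up(6.25, 1), 6.3)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(95.83333), 96)
})
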