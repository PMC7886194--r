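#' Gaussian fit and full width at half maximum
#'
#' Least-squares fit of `y = A exp(-(x - mu)^2 / (2 sigma^2)) + c0` with
#' FWHM `2 sqrt(2 ln 2) sigma = 2.3548 sigma`. Fit failure is reported in
#' the returned object, never silently.
#'
#' @param x strictly increasing abscissa (>= 5 points).
#' @param y ordinate; must attain its maximum in the interior of `x`.
#' @return an object of class `gauss_fit`: `fwhm`, `amplitude`, `center`,
#'   `sigma`, `offset`, `residual_sd`, `converged`.
#' @examples
#' x <- seq(-5, 5, 0.1)
#' gaussian_fwhm(x, exp(-x^2 / 2))$fwhm  # 2.3548
#' @export
gaussian_fwhm <- function(x, y) {
  if (length(x) < 5) stop("need at least 5 points")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  c00 <- min(y)
  A0 <- max(y) - c00
  mu0 <- x[which.max(y)]
  above <- y - c00 >= A0 / 2
  sig0 <- max(diff(range(x[above])) / 2.3548, diff(range(x)) / 50)
  resid_fn <- function(p)
    y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A0, mu0, sig0, c00), fn = resid_fn,
                       lower = c(0, min(x), 1e-9, -Inf),
                       upper = c(Inf, max(x), diff(range(x)) * 5, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # nls.lm info codes 1..4 indicate convergence
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(structure(list(fwhm = NA_real_, amplitude = NA_real_,
                          center = NA_real_, sigma = NA_real_,
                          offset = NA_real_, residual_sd = NA_real_,
                          converged = FALSE),
                     class = "gauss_fit"))
  }
  cf <- fit$par
  structure(list(fwhm = 2 * sqrt(2 * log(2)) * cf[3],
                 amplitude = cf[1], center = cf[2],
                 sigma = cf[3], offset = cf[4],
                 residual_sd = stats::sd(fit$fvec),
                 converged = TRUE),
            class = "gauss_fit")
}

#' @export
print.gauss_fit <- function(x, ...) {
  if (!x$converged) cat("Gaussian fit: did not converge\n")
  else cat(sprintf(
    "Gaussian fit: FWHM %.4f, center %.4f, amplitude %.4g, offset %.4g\n",
    x$fwhm, x$center, x$amplitude, x$offset))
  invisible(x)
}

#' Width of a profile at a fraction of its maximum
#'
#' Subtracts a constant offset (the fitted Gaussian offset when the fit
#' succeeds, otherwise the profile minimum), then linearly interpolates
#' the outermost crossings of `fraction * max` — so a full width at 10%
#' maximum (FWTM) on a bimodal profile spans both lobes.
#'
#' @param x strictly increasing abscissa.
#' @param y ordinate.
#' @param fraction fraction of the (offset-subtracted) maximum, in (0, 1).
#' @param offset constant to subtract; default as described.
#' @return width in units of `x`.
#' @export
width_at_fraction <- function(x, y, fraction, offset = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (is.null(offset)) {
    f <- tryCatch(gaussian_fwhm(x, y), error = function(e) NULL)
    offset <- if (!is.null(f) && isTRUE(f$converged)) f$offset else min(y)
  }
  y0 <- y - offset
  cr <- outer_crossings(x, y0, fraction * max(y0))
  if (is.null(cr)) return(NA_real_)
  diff(cr)
}

#' Axial sectioning response of a thin film
#'
#' Per-depth mean intensity over the field of view of a reconstructed
#' thin-film z-stack, with a Gaussian fit of the peak. A peak is
#' "measurable" only when the fitted amplitude exceeds 3x the fit residual
#' standard deviation; otherwise (the widefield case, flat within noise)
#' the FWHM is reported as NA.
#'
#' @param volume H x W x nz reconstructed array, or an nz-length vector of
#'   per-plane intensities.
#' @param z_list depths, um (strictly increasing, length nz).
#' @return an object of class `axial_response`: `z`, `intensity`, `fit`
#'   (a `gauss_fit`), `fwhm` (um or NA), `measurable`.
#' @export
thin_film_axial_response <- function(volume, z_list) {
  if (is.unsorted(z_list, strictly = TRUE))
    stop("z_list must be strictly increasing")
  intensity <- if (is.array(volume) && length(dim(volume)) == 3) {
    if (dim(volume)[3] != length(z_list))
      stop("volume planes and z_list lengths differ")
    apply(volume, 3, mean)
  } else {
    v <- as.numeric(volume)
    if (length(v) != length(z_list)) stop("profile and z_list lengths differ")
    v
  }
  fit <- tryCatch(gaussian_fwhm(z_list, intensity), error = function(e)
    structure(list(fwhm = NA_real_, amplitude = NA_real_, center = NA_real_,
                   sigma = NA_real_, offset = NA_real_,
                   residual_sd = NA_real_, converged = FALSE),
              class = "gauss_fit"))
  measurable <- isTRUE(fit$converged) &&
    is.finite(fit$amplitude) && is.finite(fit$residual_sd) &&
    fit$amplitude > 3 * fit$residual_sd &&
    fit$fwhm < diff(range(z_list))
  structure(list(z = z_list, intensity = intensity, fit = fit,
                 fwhm = if (measurable) fit$fwhm else NA_real_,
                 measurable = measurable),
            class = "axial_response")
}

#' @export
print.axial_response <- function(x, ...) {
  if (x$measurable)
    cat(sprintf("Axial response: FWHM %.3f um over z [%.2f, %.2f] um\n",
                x$fwhm, min(x$z), max(x$z)))
  else
    cat(sprintf("Axial response: no measurable peak over z [%.2f, %.2f] um\n",
                min(x$z), max(x$z)))
  invisible(x)
}

#' @export
plot.axial_response <- function(x, ...) {
  graphics::plot(x$z, x$intensity, type = "b", xlab = "z (um)",
                 ylab = "mean intensity", ...)
  if (x$measurable) {
    zz <- seq(min(x$z), max(x$z), length.out = 400)
    graphics::lines(zz, x$fit$amplitude *
                      exp(-(zz - x$fit$center)^2 / (2 * x$fit$sigma^2)) +
                      x$fit$offset, col = 2)
    graphics::abline(h = x$fit$offset + x$fit$amplitude / 2, lty = 3)
  }
  invisible(x)
}

#' Axial illumination profile from a bead z-stack
#'
#' Per-depth sum of pixel intensities within a fixed-radius region of
#' interest centered on an isolated sub-diffraction bead, minus the
#' matching sum from a background stack. The ROI radius (object-space um)
#' is chosen to capture the bead's largest defocus ring; the background
#' subtraction leaves the bead emission, proportional to the illumination
#' intensity at each depth.
#'
#' @param bead_zstack H x W x nz array of camera counts.
#' @param roi_radius_um ROI radius in object-space micrometers.
#' @param pixel_size_um object-space camera pixel size, um.
#' @param background_stack optional matching array (or single plane) of
#'   background counts.
#' @param center bead center `c(row, col)`; default: brightest pixel of
#'   the through-focus maximum projection.
#' @return numeric vector of per-depth background-subtracted ROI sums.
#' @export
axial_illumination_profile <- function(bead_zstack, roi_radius_um,
                                       pixel_size_um,
                                       background_stack = NULL,
                                       center = NULL) {
  d <- dim(bead_zstack)
  if (is.null(center)) {
    mp <- apply(bead_zstack, c(1, 2), max)
    center <- which(mp == max(mp), arr.ind = TRUE)[1, ]
  }
  r_px <- roi_radius_um / pixel_size_um
  mask <- outer((seq_len(d[1]) - center[1])^2,
                (seq_len(d[2]) - center[2])^2, "+") <= r_px^2
  prof <- apply(bead_zstack, 3, function(p) sum(p[mask]))
  if (!is.null(background_stack)) {
    bg <- if (length(dim(background_stack)) == 3)
      apply(background_stack, 3, function(p) sum(p[mask]))
    else rep(sum(background_stack[mask]), d[3])
    prof <- prof - bg
  }
  prof
}

# 2D Gaussian fit of a spot; returns center (row, col), sigma, amplitude.
fit_spot_2d <- function(img) {
  d <- dim(img)
  zz <- as.vector(img)
  yy <- as.vector(row(img)); xx <- as.vector(col(img))
  c00 <- min(img)
  A0 <- max(img) - c00
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  resid_fn <- function(p)
    zz - (p[1] * exp(-((xx - p[2])^2 + (yy - p[3])^2) / (2 * p[4]^2)) + p[5])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A0, unname(pk[2]), unname(pk[1]), max(d) / 6, c00),
      fn = resid_fn,
      lower = c(0, 1, 1, 0.3, -Inf), upper = c(Inf, d[2], d[1], max(d), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  cf <- fit$par
  list(row = cf[3], col = cf[2], sigma = cf[4],
       amplitude = cf[1], offset = cf[5])
}

# 3D connected components (6-connectivity) of a logical array; small-scale
# BFS labelling sufficient for bead detection.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      k <- (p - 1) %/% (d[1] * d[2])
      rest <- (p - 1) %% (d[1] * d[2])
      j <- rest %/% d[1]; i <- rest %% d[1]
      for (nb in list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                      c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))) {
        if (nb[1] < 0 || nb[1] >= d[1] || nb[2] < 0 || nb[2] >= d[2] ||
            nb[3] < 0 || nb[3] >= d[3]) next
        q <- nb[1] + d[1] * nb[2] + d[1] * d[2] * nb[3] + 1
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# shift a matrix by (dy, dx) sub-pixels via bilinear interpolation,
# replicating edges
shift_bilinear <- function(img, dy, dx) {
  d <- dim(img)
  ys <- pmin(pmax(seq_len(d[1]) + dy, 1), d[1])
  xs <- pmin(pmax(seq_len(d[2]) + dx, 1), d[2])
  y0 <- floor(ys); y1 <- pmin(y0 + 1, d[1]); fy <- ys - y0
  x0 <- floor(xs); x1 <- pmin(x0 + 1, d[2]); fx <- xs - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  cc <- img[y1, x0, drop = FALSE]; dd <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, d[1], d[2]); wx <- matrix(fx, d[1], d[2], byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + cc * wy * (1 - wx) +
    dd * wy * wx
}

#' Detect, align and average beads in a volume
#'
#' Locates beads by thresholding and 3D connected components, finds each
#' bead's center z from its brightest plane, its lateral center from a 2D
#' Gaussian fit of that plane, aligns the beads by sub-pixel lateral
#' shifting (integer z), and averages them. Transverse and axial profiles
#' are sampled through the mean center.
#'
#' @param volume H x W x nz array of counts.
#' @param expected_diameter_px expected bead diameter in pixels (sets the
#'   crop window and minimum component size).
#' @param threshold detection threshold; default halfway between the
#'   volume median and maximum.
#' @return list: `mean_image` (cropped average bead, brightest plane
#'   aligned), `centers` (per-bead row/col/z), `transverse_profile`,
#'   `axial_profile`, `n_beads`.
#' @export
average_beads <- function(volume, expected_diameter_px,
                          threshold = NULL) {
  d <- dim(volume)
  if (is.null(threshold))
    threshold <- stats::median(volume) + (max(volume) - stats::median(volume)) / 2
  comp <- label_components_3d(volume >= threshold)
  if (comp$n == 0) stop("no beads detected above threshold")
  min_vox <- max(4, round((expected_diameter_px / 4)^2))
  win <- ceiling(expected_diameter_px * 1.5)
  crops <- list(); centers <- NULL
  for (b in seq_len(comp$n)) {
    sel <- which(comp$labels == b, arr.ind = TRUE)
    if (nrow(sel) < min_vox) next
    # center z: brightest plane of the component
    zvals <- vapply(sort(unique(sel[, 3])), function(k) {
      pix <- sel[sel[, 3] == k, , drop = FALSE]
      sum(volume[pix])
    }, 0)
    z0 <- sort(unique(sel[, 3]))[which.max(zvals)]
    ctr0 <- round(colMeans(sel[, 1:2, drop = FALSE]))
    y0 <- max(1, ctr0[1] - win); y1 <- min(d[1], ctr0[1] + win)
    x0 <- max(1, ctr0[2] - win); x1 <- min(d[2], ctr0[2] + win)
    sp <- fit_spot_2d(volume[y0:y1, x0:x1, z0])
    if (is.null(sp)) next
    cy <- y0 + sp$row - 1; cx <- x0 + sp$col - 1
    yy0 <- round(cy) - win; yy1 <- round(cy) + win
    xx0 <- round(cx) - win; xx1 <- round(cx) + win
    if (yy0 < 1 || xx0 < 1 || yy1 > d[1] || xx1 > d[2]) next
    zz <- pmin(pmax(z0 + (-win):win, 1), d[3])
    crop <- volume[yy0:yy1, xx0:xx1, zz, drop = FALSE]
    # shift so the fitted center lands on the crop center
    dy <- cy - round(cy); dx <- cx - round(cx)
    for (k in seq_len(dim(crop)[3]))
      crop[, , k] <- shift_bilinear(crop[, , k], dy, dx)
    crops[[length(crops) + 1]] <- crop
    centers <- rbind(centers, c(row = cy, col = cx, z = z0))
  }
  if (length(crops) == 0) stop("no beads detected above threshold")
  mean_img <- Reduce(`+`, crops) / length(crops)
  cwin <- (dim(mean_img)[1] + 1) / 2
  mid_z <- (dim(mean_img)[3] + 1) / 2
  list(mean_image = mean_img, centers = centers,
       transverse_profile = mean_img[cwin, , mid_z],
       axial_profile = mean_img[cwin, cwin, ],
       n_beads = length(crops))
}

#' Signal-to-background ratios of profile peaks
#'
#' For each peak in an intensity line profile, the SBR is the peak pixel
#' intensity divided by the mean intensity of pixels 1.0-1.5 um away from
#' the peak on both sides; a side is excluded when another peak lies
#' within `exclusion_um` (default 1.5 um) on that side, in which case only
#' the opposite side is averaged. Both sides excluded is an error.
#'
#' @param profile numeric intensity profile.
#' @param pixel_size_um spacing of profile samples, um.
#' @param peak_indices indices of the peaks; if NULL, local maxima above
#'   `median + 3 * mad` are detected.
#' @param band_um background band distances, um (default `c(1, 1.5)`).
#' @param exclusion_um a side is dropped when another peak is nearer than
#'   this, um.
#' @return data.frame with columns `peak_index`, `position_um`,
#'   `peak_value`, `background`, `sbr`, `sides_used`.
#' @export
profile_sbr <- function(profile, pixel_size_um, peak_indices = NULL,
                        band_um = c(1, 1.5), exclusion_um = 1.5) {
  n <- length(profile)
  if (is.null(peak_indices)) {
    thr <- stats::median(profile) + 3 * stats::mad(profile)
    peak_indices <- which(
      profile > thr &
        profile >= c(-Inf, profile[-n]) &
        profile >= c(profile[-1], -Inf))
  }
  if (length(peak_indices) == 0) stop("no peaks to evaluate")
  out <- NULL
  for (p in peak_indices) {
    dist_px <- abs(seq_len(n) - p) * pixel_size_um
    others <- setdiff(peak_indices, p)
    blocked_left <- any(others < p &
                          (p - others) * pixel_size_um <= exclusion_um)
    blocked_right <- any(others > p &
                           (others - p) * pixel_size_um <= exclusion_um)
    in_band <- dist_px >= band_um[1] & dist_px <= band_um[2]
    left <- in_band & seq_len(n) < p
    right <- in_band & seq_len(n) > p
    use <- (if (blocked_left) rep(FALSE, n) else left) |
      (if (blocked_right) rep(FALSE, n) else right)
    if (!any(use))
      stop(sprintf("peak at index %d: both background sides excluded", p))
    sides <- if (blocked_left && !blocked_right) "right"
    else if (blocked_right && !blocked_left) "left"
    else "both"
    bgv <- mean(profile[use])
    if (bgv <= 0) stop(sprintf("peak at index %d: nonpositive background", p))
    out <- rbind(out, data.frame(
      peak_index = p, position_um = (p - 0.5) * pixel_size_um,
      peak_value = profile[p], background = bgv,
      sbr = profile[p] / bgv, sides_used = sides))
  }
  out
}

#' Count clearly detected fibers
#'
#' A fiber counts as clearly detected when its SBR strictly exceeds the
#' threshold (default 1.5).
#'
#' @param sbr_values numeric SBR values.
#' @param threshold detection threshold.
#' @return integer count.
#' @export
count_clear_fibers <- function(sbr_values, threshold = 1.5) {
  sum(sbr_values > threshold)
}

#' Summarize a fiber SBR table across modalities
#'
#' Column means and standard deviations, per-fiber cross-modality ratios,
#' and ratio means, for a table of per-fiber SBR values under several
#' imaging modalities.
#'
#' @param rows data.frame with one row per fiber and one numeric column
#'   per modality (e.g. `widefield`, `slm`, `confocal`).
#' @param ratios list of 2-element character vectors naming
#'   numerator/denominator columns; default SLM/widefield and
#'   SLM/confocal when those columns exist.
#' @return list: `column_mean`, `column_sd`, `ratio_rows` (data.frame),
#'   `ratio_mean`, `ratio_sd`, `n`.
#' @export
sbr_table_summary <- function(rows, ratios = NULL) {
  num <- rows[vapply(rows, is.numeric, TRUE)]
  num <- num[setdiff(names(num), c("peak", "peak_index"))]
  if (is.null(ratios)) {
    ratios <- list()
    if (all(c("slm", "widefield") %in% names(num)))
      ratios <- c(ratios, list(c("slm", "widefield")))
    if (all(c("slm", "confocal") %in% names(num)))
      ratios <- c(ratios, list(c("slm", "confocal")))
  }
  rr <- as.data.frame(lapply(ratios, function(r) num[[r[1]]] / num[[r[2]]]))
  if (length(ratios))
    names(rr) <- vapply(ratios, function(r) paste(r, collapse = "/"), "")
  list(column_mean = vapply(num, mean, 0),
       column_sd = vapply(num, stats::sd, 0),
       ratio_rows = rr,
       ratio_mean = if (length(ratios)) vapply(rr, mean, 0) else numeric(),
       ratio_sd = if (length(ratios)) vapply(rr, stats::sd, 0) else numeric(),
       n = nrow(num))
}

#' Object-side virtual-pinhole diameter
#'
#' The image-side pinhole (a disk of `n_pixels` camera pixels) referred to
#' object space: `n_pixels * camera_pixel_pitch / magnification`. The
#' unrounded value is retained; round only for reporting.
#'
#' @param n_pixels pinhole diameter in camera pixels.
#' @param camera_pixel_pitch camera pixel pitch, um.
#' @param magnification system magnification.
#' @return diameter in micrometers.
#' @examples
#' pinhole_object_diameter(4, 6.5, 60)  # 0.4333...
#' @export
pinhole_object_diameter <- function(n_pixels, camera_pixel_pitch,
                                    magnification) {
  n_pixels * camera_pixel_pitch / magnification
}

#' Theoretical axial sectioning FWHM of a pinhole system
#'
#' Closed-form full width at half maximum of the axial sectioning response
#' for emission wavelength `lambda_em`, immersion index `n_medium`,
#' numerical aperture `na` and object-side pinhole diameter `ph` (all
#' micrometers):
#' `sqrt( (0.88 lambda_em / (n - sqrt(n^2 - NA^2)))^2 + (sqrt(2) n ph / NA)^2 )`.
#' The first term is the diffraction-limited depth response; the second is
#' the geometric broadening by a finite pinhole.
#'
#' @param lambda_em emission wavelength, um.
#' @param n_medium refractive index.
#' @param na numerical aperture (< n_medium).
#' @param ph object-side pinhole diameter, um (>= 0).
#' @return FWHM in micrometers.
#' @examples
#' theoretical_axial_fwhm(0.525, 1.515, 1.4, pinhole_object_diameter(4, 6.5, 60))
#' @export
theoretical_axial_fwhm <- function(lambda_em, n_medium, na, ph) {
  if (na >= n_medium) stop("na must be < n_medium")
  if (ph < 0) stop("ph must be >= 0")
  diffr <- 0.88 * lambda_em / (n_medium - sqrt(n_medium^2 - na^2))
  geom <- sqrt(2) * n_medium * ph / na
  sqrt(diffr^2 + geom^2)
}

#' Bundled reference SBR dataset: FLP-neuron fibers
#'
#' Signal-to-background ratios of 24 neuronal fiber peaks traced along a
#' C. elegans FLP neuron, measured on the same specimen with widefield,
#' SLM-pick and laser-scanning confocal microscopes. Distributed with the
#' package as the reference dataset for [sbr_table_summary()] and
#' [count_clear_fibers()].
#'
#' @return data.frame with columns `peak`, `widefield`, `slm`, `confocal`.
#' @export
flp_fiber_sbr <- function() {
  path <- system.file("extdata", "flp_fiber_sbr.tsv", package = "slmscope")
  utils::read.delim(path)
}
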