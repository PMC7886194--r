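#' Reconstructed image
#' @param pixels H x W matrix of nonnegative intensities.
#' @param strategy one of "sum", "max", "pick".
#' @param focal_z focal depth, um.
#' @param provenance named list of stack/assignment metadata.
#' @return object of class `slm_recon`.
#' @keywords internal
slm_recon <- function(pixels, strategy, focal_z = NA_real_,
                      provenance = list()) {
  structure(list(pixels = pixels, strategy = strategy, focal_z = focal_z,
                 provenance = provenance),
            class = "slm_recon")
}

#' @export
print.slm_recon <- function(x, ...) {
  cat(sprintf("SLM-%s reconstruction: %d x %d px, focal z %.3f um\n",
              x$strategy, nrow(x$pixels), ncol(x$pixels), x$focal_z))
  invisible(x)
}

#' Sum reconstruction
#'
#' Per-pixel sum of all sub-images. Summing over the full scan recovers a
#' widefield-equivalent image (light is captured sequentially instead of
#' simultaneously), so this strategy serves as the in-register widefield
#' reference.
#'
#' @param stack a [subimage_stack()].
#' @return an `slm_recon`.
#' @export
reconstruct_sum <- function(stack) {
  px <- apply(stack$frames, c(1, 2), sum)
  slm_recon(px, "sum", stack$focal_z)
}

#' Maximum-projection reconstruction
#'
#' Per-pixel maximum over the sub-images: keeps each pixel's value from
#' whichever frame lit it most brightly. Requires no element-to-pixel
#' alignment, at the cost of retaining bright out-of-focus leakage and the
#' noisiest sample of each pixel.
#'
#' @param stack a [subimage_stack()].
#' @return an `slm_recon`.
#' @export
reconstruct_max <- function(stack) {
  px <- apply(stack$frames, c(1, 2), max)
  slm_recon(px, "max", stack$focal_z)
}

#' Virtual-pinhole ("pick") reconstruction
#'
#' Each pixel takes its value from the sub-image in which its sample
#' location was illuminated — the digital analogue of a confocal pinhole.
#' Pixels inside two pinhole disks (the non-integer element-to-pixel scale
#' makes some pixels partially illuminated by two elements) take the
#' maximum over exactly their claiming frames. Pixels covered by no
#' pinhole are an error under the default strict policy; `fill = "max"`
#' fills them from the maximum projection (flagged in provenance) and
#' `fill = "zero"` zeroes them.
#'
#' @param stack a [subimage_stack()].
#' @param assignment an [assign_pixels_to_frames()] result matching the
#'   stack dimensions.
#' @param fill uncovered-pixel policy: "error", "max" or "zero".
#' @return an `slm_recon`; pixelwise `pick <= max`.
#' @export
reconstruct_pick <- function(stack, assignment,
                             fill = c("error", "max", "zero")) {
  fill <- match.arg(fill)
  d <- dim(stack$frames)
  if (!all(assignment$image_shape == d[1:2]))
    stop(sprintf("assignment is %d x %d but stack frames are %d x %d",
                 assignment$image_shape[1], assignment$image_shape[2],
                 d[1], d[2]))
  if (any(assignment$frames_px > d[3], na.rm = TRUE))
    stop("assignment references frames beyond the stack")
  H <- d[1]; W <- d[2]
  out <- matrix(-Inf, H, W)
  for (l in seq_len(dim(assignment$frames_px)[3])) {
    f <- assignment$frames_px[, , l]
    ok <- !is.na(f)
    if (!any(ok)) next
    idx <- cbind(row(f)[ok], col(f)[ok], f[ok])
    vals <- matrix(-Inf, H, W)
    vals[ok] <- stack$frames[idx]
    out <- pmax(out, vals)
  }
  if (any(assignment$uncovered)) {
    if (fill == "error")
      stop(sprintf("%d pixels are covered by no virtual pinhole; use fill = 'max' or 'zero'",
                   sum(assignment$uncovered)))
    if (fill == "max") {
      mx <- apply(stack$frames, c(1, 2), max)
      out[assignment$uncovered] <- mx[assignment$uncovered]
    } else out[assignment$uncovered] <- 0
  }
  slm_recon(out, "pick", stack$focal_z,
            provenance = list(fill = fill,
                              n_shared = sum(assignment$shared),
                              n_uncovered = sum(assignment$uncovered)))
}

#' Reconstruct a z-stack
#'
#' Applies one reconstruction strategy to every focal plane of a scan,
#' preserving plane order and metadata.
#'
#' @param stacks list of [subimage_stack()] objects.
#' @param strategy "sum", "max" or "pick".
#' @param assignment required for "pick".
#' @param fill uncovered-pixel policy for "pick".
#' @return list with `volume` (H x W x nz array), `focal_z` (vector) and
#'   `strategy`.
#' @export
reconstruct_zstack <- function(stacks, strategy = c("pick", "max", "sum"),
                               assignment = NULL, fill = "error") {
  strategy <- match.arg(strategy)
  recon1 <- function(s) switch(strategy,
    sum = reconstruct_sum(s),
    max = reconstruct_max(s),
    pick = {
      if (is.null(assignment)) stop("pick reconstruction requires an assignment")
      reconstruct_pick(s, assignment, fill)
    })
  rs <- lapply(stacks, recon1)
  vol <- array(0, c(dim(rs[[1]]$pixels), length(rs)))
  for (i in seq_along(rs)) vol[, , i] <- rs[[i]]$pixels
  list(volume = vol, focal_z = vapply(stacks, function(s) s$focal_z, 0),
       strategy = strategy)
}

#' Render a synthetic cross-alignment target
#'
#' Simulated camera image of the alignment cross: only the center row and
#' center column of SLM elements transmit onto a uniform thin film at
#' focus, producing two bright ridges of merged element spots. Used to
#' exercise [calibrate_alignment()] with a known ground-truth map.
#'
#' @param grid an [slm_grid()] with odd `n_rows` and `n_cols`.
#' @param map the ground-truth [element_pixel_map()].
#' @param image_shape camera image `c(height, width)`.
#' @param spot_sigma_px Gaussian spot width per element, camera pixels.
#' @param amplitude peak counts per spot.
#' @param background constant background counts.
#' @param poisson if TRUE, Poisson noise is applied.
#' @param seed RNG seed for the noise.
#' @return camera image matrix.
#' @export
render_cross_target <- function(grid, map, image_shape, spot_sigma_px = 1.4,
                                amplitude = 1000, background = 0,
                                poisson = FALSE, seed = 1) {
  if (grid$n_rows %% 2 == 0 || grid$n_cols %% 2 == 0)
    stop("cross target needs odd grid dimensions (a center row/column)")
  ctr <- element_centers_px(map, grid, image_shape)
  rc <- (grid$n_rows + 1) / 2; cc <- (grid$n_cols + 1) / 2
  H <- image_shape[1]; W <- image_shape[2]
  img <- matrix(background, H, W)
  add_spot <- function(img, ex, ey) {
    x0 <- max(1, floor(ex - 5 * spot_sigma_px))
    x1 <- min(W, ceiling(ex + 5 * spot_sigma_px))
    y0 <- max(1, floor(ey - 5 * spot_sigma_px))
    y1 <- min(H, ceiling(ey + 5 * spot_sigma_px))
    if (x0 > x1 || y0 > y1) return(img)
    g <- amplitude * outer(exp(-((y0:y1) - ey)^2 / (2 * spot_sigma_px^2)),
                           exp(-((x0:x1) - ex)^2 / (2 * spot_sigma_px^2)))
    img[y0:y1, x0:x1] <- img[y0:y1, x0:x1] + g
    img
  }
  for (j in seq_len(grid$n_cols)) img <- add_spot(img, ctr$x[rc, j], ctr$y[rc, j])
  for (i in seq_len(grid$n_rows)) {
    if (i == rc) next
    img <- add_spot(img, ctr$x[i, cc], ctr$y[i, cc])
  }
  if (poisson) img <- with_seed(seed, matrix(stats::rpois(length(img), img), H, W))
  img
}

#' Calibrate the element-to-pixel map from a cross image
#'
#' Estimates offset, rotation and scale from a camera image acquired while
#' transmitting only the center row and column of SLM elements onto a thin
#' film. The two ridges are traced by intensity-weighted centroids in
#' sliding windows, fitted with weighted least-squares lines; rotation
#' comes from the line angles, the offset from their intersection, and the
#' scale from the ridge half-maximum length against the known element
#' count (corrected for the spot width). The ridge trace is iterated so
#' the windows follow the current line estimate.
#'
#' @param cross_image camera image matrix.
#' @param grid the [slm_grid()] that produced the cross (odd dimensions).
#' @param initial_guess list with at least `scale` (camera px per element);
#'   optionally `pinhole_diameter_px` for the returned map.
#' @return an [element_pixel_map()] with attributes `residual_px` (RMS
#'   centroid-to-line distance) and `n_columns_used`.
#' @export
calibrate_alignment <- function(cross_image, grid,
                                initial_guess = list(scale = 3.5)) {
  if (is.null(initial_guess$scale)) stop("initial_guess must supply scale")
  H <- nrow(cross_image); W <- ncol(cross_image)
  bg <- stats::median(cross_image)
  img <- pmax(cross_image - bg, 0)
  noise_sd <- stats::mad(cross_image)
  if (max(img) <= max(5 * noise_sd, 1e-12))
    stop("cross not detected: no ridge rises above the background")
  s <- initial_guess$scale
  theta <- 0; ox <- 0; oy <- 0
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  w <- max(4, ceiling(s))
  excl <- max(2 * s, 5)
  trace_ridge <- function(img, a, b, excl_center, HH, WW) {
    # ridge y = a + b x over columns x; returns centroids and window sums
    xs <- seq_len(WW)
    keep <- abs(xs - excl_center) > excl
    res <- matrix(NA_real_, 0, 3)
    for (x in xs[keep]) {
      yp <- a + b * x
      y0 <- round(yp) - w; y1 <- round(yp) + w
      if (y0 < 1 || y1 > HH) next
      col <- img[y0:y1, x]
      tot <- sum(col)
      if (tot <= 0) next
      res <- rbind(res, c(x, sum((y0:y1) * col) / tot, tot))
    }
    res
  }
  fit_line <- function(tr) {
    # weighted LS fit y = a + b x
    ft <- stats::lm.wfit(cbind(1, tr[, 1]), tr[, 2], tr[, 3])
    ft$coefficients
  }
  for (it in 1:4) {
    b_h <- tan(theta); a_h <- cy + oy - b_h * (cx + ox)
    tr_h <- trace_ridge(img, a_h, b_h, cx + ox, H, W)
    b_v <- -tan(theta); a_v <- cx + ox - b_v * (cy + oy)
    tr_v <- trace_ridge(t(img), a_v, b_v, cy + oy, W, H)
    if (nrow(tr_h) < 5 || nrow(tr_v) < 5)
      stop("cross not detected: ridges too short to fit")
    ch <- fit_line(tr_h); cv <- fit_line(tr_v)
    theta <- (atan(ch[2]) + atan(-cv[2])) / 2
    xi <- (cv[1] + cv[2] * ch[1]) / (1 - cv[2] * ch[2])
    yi <- ch[1] + ch[2] * xi
    ox <- xi - cx; oy <- yi - cy
  }
  resid <- function(tr, cf) sqrt(sum(tr[, 3] * (tr[, 2] - cf[1] - cf[2] * tr[, 1])^2) /
                                   sum(tr[, 3]))
  # spot width from pooled perpendicular spread
  spread <- function(tr, cf, img_t, HH) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(tr))) {
      x <- tr[i, 1]; yp <- cf[1] + cf[2] * x
      y0 <- round(yp) - w; y1 <- round(yp) + w
      col <- img_t[y0:y1, x]
      num <- num + sum(col * ((y0:y1) - yp)^2)
      den <- den + sum(col)
    }
    sqrt(num / den)
  }
  sig_h <- spread(tr_h, ch, img, H)
  sig_v <- spread(tr_v, cv, t(img), W)
  fw_spot <- 2 * sqrt(2 * log(2)) * mean(c(sig_h, sig_v))
  ridge_len <- function(tr) {
    o <- order(tr[, 1])
    cr <- outer_crossings(tr[o, 1], tr[o, 3], max(tr[, 3]) / 2)
    if (is.null(cr)) NA_real_ else diff(cr)
  }
  L_h <- ridge_len(tr_h) / cos(theta)
  L_v <- ridge_len(tr_v) / cos(theta)
  # half-max ridge length spans the outer element centers plus one spot
  # width; requires the projected grid to lie inside the camera frame
  est_scale <- function(L, n) (L - fw_spot) / (n - 1)
  scales <- c(est_scale(L_h, grid$n_cols), est_scale(L_v, grid$n_rows))
  scale_hat <- mean(scales, na.rm = TRUE)
  if (!is.finite(scale_hat) || scale_hat <= 0) scale_hat <- s
  ph <- if (!is.null(initial_guess$pinhole_diameter_px))
    initial_guess$pinhole_diameter_px else 4
  out <- element_pixel_map(scale = scale_hat, offset_x = ox, offset_y = oy,
                           rotation = theta, pinhole_diameter_px = ph)
  attr(out, "residual_px") <- mean(c(resid(tr_h, ch), resid(tr_v, cv)))
  attr(out, "n_columns_used") <- nrow(tr_h) + nrow(tr_v)
  out
}
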