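#' SLM element grid
#'
#' Describes the spatial light modulator as a rectangular grid of
#' transmissive elements. Each element has a centered active (modulating)
#' rectangle covering `active_frac_x` x `active_frac_y` of its pitch; the
#' rest of the cell is the conduit region. Off elements (and conduits) leak
#' light at `1/extinction_ratio` of the on-state transmission.
#'
#' Consumer transmissive SLMs have fill factors slightly above 60% and a
#' rectangular active region (a measured 11.1 x 13.0 um aspect, i.e. 0.85,
#' is typical); the defaults `0.80 x 0.94` of the pitch reproduce that
#' aspect with a 75% simulated fill. The default extinction ratio is 200:1.
#'
#' @param n_rows,n_cols element counts (>= 1).
#' @param element_pitch_obj object-space element pitch in micrometers.
#' @param active_frac_x,active_frac_y transmissive fraction of the pitch in
#'   x (columns) and y (rows), each in (0, 1].
#' @param extinction_ratio on/off transmission ratio (> 1; `Inf` allowed
#'   for an ideal modulator).
#' @return an object of class `slm_grid`.
#' @seealso [scan_sequence()], [frame_transmission_map()]
#' @export
slm_grid <- function(n_rows, n_cols, element_pitch_obj,
                     active_frac_x = 0.80, active_frac_y = 0.94,
                     extinction_ratio = 200) {
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) ||
      n_cols != round(n_cols))
    stop("n_rows and n_cols must be integers >= 1")
  stopifnot_scalar(element_pitch_obj, "element_pitch_obj", positive = TRUE)
  if (active_frac_x <= 0 || active_frac_x > 1 ||
      active_frac_y <= 0 || active_frac_y > 1)
    stop("active fractions must lie in (0, 1]")
  if (!(extinction_ratio > 1)) stop("extinction_ratio must be > 1")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 element_pitch_obj = element_pitch_obj,
                 active_frac_x = active_frac_x, active_frac_y = active_frac_y,
                 extinction_ratio = extinction_ratio),
            class = "slm_grid")
}

#' @export
print.slm_grid <- function(x, ...) {
  cat(sprintf(
    "SLM grid: %d x %d elements, pitch %.4f um, active %.2f x %.2f, extinction %s:1\n",
    x$n_rows, x$n_cols, x$element_pitch_obj, x$active_frac_x,
    x$active_frac_y, format(x$extinction_ratio)))
  invisible(x)
}

#' Unit-cell raster scan sequence
#'
#' Builds the ordered dot-array raster scan over a `unit_rows` x `unit_cols`
#' unit cell. Frame k transmits exactly those elements whose
#' `(row - 1) mod unit_rows` and `(col - 1) mod unit_cols` equal the frame's
#' offsets, so over the full sequence every element transmits in exactly one
#' frame. Frames are ordered row-major (row offset slowest); the order is an
#' explicit convention stored with the sequence so reconstruction never
#' depends on an implicit one.
#'
#' @param unit_rows,unit_cols unit-cell dimensions (>= 1). The default 6 x 6
#'   cell separates transmitting elements by five dark elements, enough to
#'   suppress crosstalk between illuminated spots while keeping the frame
#'   count at 36.
#' @return an object of class `scan_sequence` with a `frames` matrix of
#'   0-based `(row_offset, col_offset)` pairs.
#' @examples
#' s <- scan_sequence(6, 6)
#' nrow(s$frames)  # 36
#' @export
scan_sequence <- function(unit_rows = 6, unit_cols = 6) {
  if (unit_rows < 1 || unit_cols < 1 || unit_rows != round(unit_rows) ||
      unit_cols != round(unit_cols))
    stop("unit cell dimensions must be integers >= 1")
  off <- expand.grid(col_offset = seq_len(unit_cols) - 1L,
                     row_offset = seq_len(unit_rows) - 1L)
  frames <- cbind(row_offset = off$row_offset, col_offset = off$col_offset)
  structure(list(unit_rows = as.integer(unit_rows),
                 unit_cols = as.integer(unit_cols),
                 frames = frames, order = "row-major"),
            class = "scan_sequence")
}

#' @export
print.scan_sequence <- function(x, ...) {
  cat(sprintf("Scan sequence: %d x %d unit cell, %d frames (%s)\n",
              x$unit_rows, x$unit_cols, nrow(x$frames), x$order))
  invisible(x)
}

#' Number of frames in a scan sequence
#' @param sequence a [scan_sequence()].
#' @return integer frame count (`unit_rows * unit_cols`).
#' @export
n_frames <- function(sequence) nrow(sequence$frames)

#' Element-to-camera-pixel map
#'
#' Similarity transform taking SLM element indices to camera pixel
#' coordinates: an element `scale` in camera pixels per element pitch
#' (~3.5 for an off-the-shelf SLM projected through typical optics), a
#' rotation about the optical axis and a translation of the grid center
#' from the image center. `pinhole_diameter_px` is the diameter of the
#' digital virtual-pinhole disk used by the pick reconstruction; the
#' effective image-side pinhole of the reference setup is 4 camera pixels.
#'
#' @param scale camera pixels per element (> 0).
#' @param offset_x,offset_y translation in camera pixels.
#' @param rotation radians about the optical axis.
#' @param pinhole_diameter_px virtual-pinhole diameter in camera pixels
#'   (>= 1).
#' @return an object of class `element_pixel_map`.
#' @export
element_pixel_map <- function(scale = 3.5, offset_x = 0, offset_y = 0,
                              rotation = 0, pinhole_diameter_px = 4) {
  stopifnot_scalar(scale, "scale", positive = TRUE)
  if (pinhole_diameter_px < 1) stop("pinhole_diameter_px must be >= 1")
  structure(list(scale = scale, offset_x = offset_x, offset_y = offset_y,
                 rotation = rotation,
                 pinhole_diameter_px = pinhole_diameter_px),
            class = "element_pixel_map")
}

#' @export
print.element_pixel_map <- function(x, ...) {
  cat(sprintf(
    "Element-pixel map: scale %.4f px/element, offset (%.3f, %.3f) px, rotation %.4f deg, pinhole %g px\n",
    x$scale, x$offset_x, x$offset_y, 180 / pi * x$rotation,
    x$pinhole_diameter_px))
  invisible(x)
}

# Projected camera-pixel center of each element (1-based pixel-center
# coordinates: pixel j spans [j-1/2, j+1/2]). Returns a list of matrices
# x, y indexed [row, col].
element_centers_px <- function(map, grid, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  u <- seq_len(grid$n_cols) - (grid$n_cols + 1) / 2
  v <- seq_len(grid$n_rows) - (grid$n_rows + 1) / 2
  ct <- cos(map$rotation); st <- sin(map$rotation)
  U <- matrix(u, grid$n_rows, grid$n_cols, byrow = TRUE)
  V <- matrix(v, grid$n_rows, grid$n_cols)
  list(x = (W + 1) / 2 + map$offset_x + map$scale * (U * ct - V * st),
       y = (H + 1) / 2 + map$offset_y + map$scale * (U * st + V * ct))
}

#' Simulation geometry for a camera field of view
#'
#' Bundles the camera field of view with the object-space sampling used by
#' the forward model: the simulation grid is `oversample` times finer than
#' the camera pixel (default 4, about 27 nm object-space for a 6.5-um
#' camera pixel at 60x) and is area-binned back to camera pixels after
#' image formation.
#'
#' @param config an [optical_config()].
#' @param fov camera field of view, `c(height, width)` in pixels.
#' @param oversample integer sub-pixels per camera pixel (>= 1).
#' @return an object of class `scan_geometry` with the simulation pixel
#'   size (`dx_sim`, um) and grid dimensions.
#' @export
scan_geometry <- function(config, fov = c(64, 64), oversample = 4) {
  fov <- as.integer(fov)
  if (length(fov) != 2 || any(fov < 4)) stop("fov must be c(height, width), each >= 4")
  if (oversample < 1 || oversample != round(oversample))
    stop("oversample must be a positive integer")
  structure(list(config = config, fov = fov, oversample = as.integer(oversample),
                 dx_cam = config$object_pixel,
                 dx_sim = config$object_pixel / oversample,
                 sim_dim = fov * as.integer(oversample)),
            class = "scan_geometry")
}

#' Grid sized to cover a field of view
#'
#' Convenience constructor: chooses odd element counts so the projected
#' grid covers the camera field of view with a margin, and sets the
#' object-space pitch from the map scale (`scale` camera pixels x
#' object-space pixel pitch, ~0.379 um for the defaults).
#'
#' @param geom a [scan_geometry()].
#' @param map an [element_pixel_map()].
#' @param margin extra elements beyond each edge (default 2).
#' @param ... passed to [slm_grid()] (active fractions, extinction ratio).
#' @return an [slm_grid()].
#' @export
slm_grid_for_fov <- function(geom, map, margin = 2, ...) {
  n <- ceiling(geom$fov / map$scale) + 2 * margin
  n <- n + (1 - n %% 2)                  # odd, so a center row/col exists
  slm_grid(n_rows = n[1], n_cols = n[2],
           element_pitch_obj = map$scale * geom$dx_cam, ...)
}

#' Object-space transmission map of one scan frame
#'
#' Renders the SLM transmission for frame `frame_index` of a scan sequence
#' on the simulation grid: transmitting elements carry 1.0 over their
#' centered active rectangle and `1/extinction_ratio` over their conduit
#' region; non-transmitting elements carry `1/extinction_ratio` everywhere,
#' as do sample points outside the grid.
#'
#' @param grid an [slm_grid()].
#' @param sequence a [scan_sequence()].
#' @param frame_index 1-based frame index.
#' @param geom a [scan_geometry()]; must sample the element pitch with at
#'   least 4 points.
#' @param map an [element_pixel_map()] giving the projection.
#' @return transmission matrix (`sim_dim` of `geom`), values in
#'   `[1/extinction_ratio, 1]`.
#' @export
frame_transmission_map <- function(grid, sequence, frame_index, geom, map) {
  if (frame_index < 1 || frame_index > n_frames(sequence))
    stop(sprintf("frame_index %d out of range 1..%d", frame_index,
                 n_frames(sequence)))
  if (map$scale * geom$oversample < 4)
    stop("sampling coarser than 4 points per element pitch; increase oversample")
  off <- sequence$frames[frame_index, ]
  leak <- 1 / grid$extinction_ratio
  H <- geom$sim_dim[1]; W <- geom$sim_dim[2]
  os <- geom$oversample
  # sample-point centers in camera-pixel coordinates
  xs <- (seq_len(W) - 0.5) / os + 0.5
  ys <- (seq_len(H) - 0.5) / os + 0.5
  cx <- (geom$fov[2] + 1) / 2 + map$offset_x
  cy <- (geom$fov[1] + 1) / 2 + map$offset_y
  ct <- cos(map$rotation); st <- sin(map$rotation)
  dx <- xs - cx
  dy <- ys - cy
  # inverse rotation, then element coordinates
  Ecol <- (outer(rep(1, H), dx * ct) + outer(dy * st, rep(1, W))) / map$scale +
    (grid$n_cols + 1) / 2
  Erow <- (outer(rep(1, H), -dx * st) + outer(dy * ct, rep(1, W))) / map$scale +
    (grid$n_rows + 1) / 2
  col_i <- round(Ecol); row_i <- round(Erow)
  frac_x <- Ecol - col_i; frac_y <- Erow - row_i
  inside <- col_i >= 1 & col_i <= grid$n_cols & row_i >= 1 & row_i <= grid$n_rows
  transmitting <- inside &
    ((row_i - 1) %% sequence$unit_rows) == off[["row_offset"]] &
    ((col_i - 1) %% sequence$unit_cols) == off[["col_offset"]]
  active <- abs(frac_x) <= grid$active_frac_x / 2 &
    abs(frac_y) <= grid$active_frac_y / 2
  out <- matrix(leak, H, W)
  out[transmitting & active] <- 1
  out
}

#' Assign camera pixels to scan frames (virtual pinholes)
#'
#' For every camera pixel, finds the scan frames whose transmitting
#' element's projected virtual-pinhole disk (diameter
#' `map$pinhole_diameter_px`, centered on the projected element center)
#' contains the pixel center. With an integer scale and aligned offset each
#' pixel belongs to exactly one frame; with the non-integer ~3.5 px/element
#' geometry some pixels fall inside two pinholes (flagged `shared`) and the
#' corners of element cells may fall inside none (flagged `uncovered`).
#'
#' @param map an [element_pixel_map()].
#' @param grid an [slm_grid()].
#' @param sequence a [scan_sequence()].
#' @param image_shape camera image `c(height, width)` in pixels.
#' @return an object of class `slm_assignment`: integer array `frames_px`
#'   (`H x W x n_claims`, NA-padded), logical matrices `shared` and
#'   `uncovered`, and the inputs as metadata.
#' @export
assign_pixels_to_frames <- function(map, grid, sequence, image_shape) {
  H <- as.integer(image_shape[1]); W <- as.integer(image_shape[2])
  ctr <- element_centers_px(map, grid, c(H, W))
  span_x <- range(ctr$x); span_y <- range(ctr$y)
  r <- map$pinhole_diameter_px / 2
  if (span_x[1] - r > 1 || span_x[2] + r < W || span_y[1] - r > 1 ||
      span_y[2] + r < H)
    stop("projected SLM grid does not cover the image; enlarge the grid")
  frame_of_element <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  for (k in seq_len(n_frames(sequence))) {
    off <- sequence$frames[k, ]
    rows <- which(((seq_len(grid$n_rows) - 1) %% sequence$unit_rows) ==
                    off[["row_offset"]])
    cols <- which(((seq_len(grid$n_cols) - 1) %% sequence$unit_cols) ==
                    off[["col_offset"]])
    frame_of_element[rows, cols] <- k
  }
  claims <- array(NA_integer_, c(H, W, 4L))
  n_claim <- matrix(0L, H, W)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      ex <- ctr$x[i, j]; ey <- ctr$y[i, j]
      x0 <- max(1L, ceiling(ex - r)); x1 <- min(W, floor(ex + r))
      y0 <- max(1L, ceiling(ey - r)); y1 <- min(H, floor(ey + r))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      d2 <- outer((ys - ey)^2, (xs - ex)^2, "+")
      hit <- which(d2 <= r^2, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      f <- frame_of_element[i, j]
      for (h in seq_len(nrow(hit))) {
        py <- ys[hit[h, 1]]; px <- xs[hit[h, 2]]
        cur <- claims[py, px, ]
        if (f %in% cur[!is.na(cur)]) next
        nc <- n_claim[py, px] + 1L
        if (nc > 4L) stop("pixel claimed by more than 4 pinholes; pinhole too large")
        claims[py, px, nc] <- f
        n_claim[py, px] <- nc
      }
    }
  }
  uncovered <- n_claim == 0L
  structure(list(frames_px = claims, n_claims = n_claim,
                 shared = n_claim >= 2L, uncovered = uncovered,
                 map = map, grid = grid, sequence = sequence,
                 image_shape = c(H, W)),
            class = "slm_assignment")
}

#' @export
print.slm_assignment <- function(x, ...) {
  cat(sprintf(
    "Pixel-frame assignment: %d x %d image, %d shared, %d uncovered pixels\n",
    x$image_shape[1], x$image_shape[2], sum(x$shared), sum(x$uncovered)))
  invisible(x)
}

#' Serialize a scan sequence or element-pixel map to JSON
#'
#' @param x a [scan_sequence()] or [element_pixel_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_slm_json <- function(x, path) {
  obj <- unclass(x)
  obj$.class <- class(x)
  if (!is.null(obj$frames)) obj$frames <- unname(apply(obj$frames, 1, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scan sequence or element-pixel map from JSON
#' @param path file written by [write_slm_json()].
#' @return the deserialized object.
#' @export
read_slm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "scan_sequence")) {
    s <- scan_sequence(obj$unit_rows, obj$unit_cols)
    return(s)
  }
  if (identical(cls, "element_pixel_map")) {
    return(element_pixel_map(obj$scale, obj$offset_x, obj$offset_y,
                             obj$rotation, obj$pinhole_diameter_px))
  }
  if (identical(cls, "slm_grid")) {
    return(slm_grid(obj$n_rows, obj$n_cols, obj$element_pitch_obj,
                    obj$active_frac_x, obj$active_frac_y,
                    obj$extinction_ratio))
  }
  stop("unrecognized slm JSON object")
}

#' Export a transmission map as a single-page TIFF for inspection
#' @param tmap matrix from [frame_transmission_map()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_transmission_tiff <- function(tmap, path) {
  tiff::writeTIFF(tmap / max(tmap), path, bits.per.sample = 16)
  invisible(path)
}
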