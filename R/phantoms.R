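#' Fluorophore-density phantom
#'
#' A 3D nonnegative fluorophore density sampled on the lateral simulation
#' grid of a [scan_geometry()] and on a list of z slabs. Slabs need not be
#' evenly spaced; each carries its own thickness (`z_weight`, um), so a
#' 100-nm film and a 250-nm-stepped bead volume coexist in one model.
#' Lateral coordinates are in micrometers with x measured from the left
#' field edge and y from the top (pixel centers at `(i - 0.5) * dx`).
#'
#' @param density 3D array `Hs x Ws x nz`, nonnegative.
#' @param z slab center depths, um (length nz).
#' @param z_weight slab thicknesses, um (length nz, > 0).
#' @param voxel_xy lateral sample spacing, um.
#' @param meta named list of ground-truth metadata (bead centers, fiber
#'   centerlines, ...).
#' @return an object of class `phantom`.
#' @export
phantom <- function(density, z, z_weight, voxel_xy, meta = list()) {
  if (length(dim(density)) == 2) density <- array(density, c(dim(density), 1))
  if (length(dim(density)) != 3) stop("density must be a 3D array")
  if (any(density < 0)) stop("density must be nonnegative")
  if (length(z) != dim(density)[3]) stop("length(z) must match dim(density)[3]")
  z_weight <- rep_len(z_weight, length(z))
  if (any(z_weight <= 0)) stop("z_weight must be > 0")
  stopifnot_scalar(voxel_xy, "voxel_xy", positive = TRUE)
  structure(list(density = density, z = z, z_weight = z_weight,
                 voxel_xy = voxel_xy, meta = meta),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf(
    "Phantom: %d x %d x %d voxels, %.1f nm lateral, z in [%.2f, %.2f] um\n",
    d[1], d[2], d[3], 1e3 * x$voxel_xy, min(x$z), max(x$z)))
  invisible(x)
}

# lateral pixel-center coordinates (um) of the simulation grid
sim_coords <- function(geom) {
  list(x = (seq_len(geom$sim_dim[2]) - 0.5) * geom$dx_sim,
       y = (seq_len(geom$sim_dim[1]) - 0.5) * geom$dx_sim)
}

#' Thin fluorescent film phantom
#'
#' Uniform optically thin film: one z slab of thickness `thickness_um` at
#' depth `z0` with density `level`, the standard diffuse target for axial
#' sectioning characterization.
#'
#' @param geom a [scan_geometry()].
#' @param thickness_um film thickness, um (<= 0.2: optically thin).
#' @param level fluorophore density (arbitrary units).
#' @param z0 film depth, um.
#' @return a [phantom()] with one slab.
#' @export
make_thin_film <- function(geom, thickness_um = 0.1, level = 1, z0 = 0) {
  stopifnot_scalar(thickness_um, "thickness_um", positive = TRUE)
  if (thickness_um > 0.2)
    stop("thin film must be optically thin (thickness <= 0.2 um)")
  d <- matrix(level, geom$sim_dim[1], geom$sim_dim[2])
  phantom(array(d, c(dim(d), 1)), z = z0, z_weight = thickness_um,
          voxel_xy = geom$dx_sim)
}

#' Fluorescent bead phantom
#'
#' Solid uniform spheres at seeded-random centers with rejection sampling
#' enforcing a minimum separation; emulates 6-um calibration beads or, for
#' sub-voxel diameters (e.g. 175 nm), point-like beads deposited as a
#' single-slab impulse of the correct total mass.
#'
#' @param geom a [scan_geometry()].
#' @param diameter_um bead diameter, um.
#' @param count number of beads (>= 1).
#' @param min_separation minimum center-to-center distance, um
#'   (> diameter).
#' @param seed RNG seed.
#' @param z_range depth range `c(zmin, zmax)` of bead centers, um.
#' @param voxel_z z slab spacing, um (default 0.25, the standard bead
#'   z-stack step).
#' @param level fluorophore density inside each bead.
#' @param centers optional `count x 3` matrix of (x, y, z) centers in um,
#'   bypassing random placement.
#' @return a [phantom()] with `meta$centers` (um).
#' @export
make_beads <- function(geom, diameter_um = 6, count = 1,
                       min_separation = 1.5 * diameter_um, seed = 1,
                       z_range = c(0, 0), voxel_z = 0.25, level = 1,
                       centers = NULL) {
  if (count < 1) stop("count must be >= 1")
  if (is.null(centers) && min_separation <= diameter_um)
    stop("min_separation must exceed the bead diameter")
  co <- sim_coords(geom)
  fov_um <- c(max(co$x) + geom$dx_sim / 2, max(co$y) + geom$dx_sim / 2)
  r <- diameter_um / 2
  if (is.null(centers)) {
    centers <- with_seed(seed, {
      placed <- matrix(NA_real_, 0, 3)
      tries <- 0
      while (nrow(placed) < count) {
        cand <- c(stats::runif(1, r, fov_um[1] - r),
                  stats::runif(1, r, fov_um[2] - r),
                  stats::runif(1, z_range[1], z_range[2]))
        ok <- nrow(placed) == 0 ||
          all(sqrt(rowSums(sweep(placed, 2, cand)^2)) >= min_separation)
        if (ok) placed <- rbind(placed, cand)
        tries <- tries + 1
        if (tries > 1000 * count)
          stop(sprintf("could not place %d beads at separation %.2f um",
                       count, min_separation))
      }
      placed
    })
  }
  centers <- matrix(centers, ncol = 3)
  sub_voxel <- diameter_um < geom$dx_sim | diameter_um < voxel_z
  if (sub_voxel) {
    # point-source limit: deposit total mass (pi/6) d^3 * level per bead
    zs <- sort(unique(round(centers[, 3] / voxel_z) * voxel_z))
    dens <- array(0, c(geom$sim_dim, length(zs)))
    mass <- level * pi / 6 * diameter_um^3
    for (b in seq_len(nrow(centers))) {
      ix <- which.min(abs(co$x - centers[b, 1]))
      iy <- which.min(abs(co$y - centers[b, 2]))
      iz <- which.min(abs(zs - centers[b, 3]))
      dens[iy, ix, iz] <- dens[iy, ix, iz] +
        mass / (geom$dx_sim^2 * voxel_z)
    }
    return(phantom(dens, z = zs, z_weight = voxel_z, voxel_xy = geom$dx_sim,
                   meta = list(centers = centers, diameter_um = diameter_um)))
  }
  zmin <- min(centers[, 3]) - r; zmax <- max(centers[, 3]) + r
  zs <- seq(zmin + voxel_z / 2, zmax, by = voxel_z)
  dens <- array(0, c(geom$sim_dim, length(zs)))
  for (b in seq_len(nrow(centers))) {
    for (k in seq_along(zs)) {
      rz2 <- r^2 - (zs[k] - centers[b, 3])^2
      if (rz2 <= 0) next
      rz <- sqrt(rz2)
      dx2 <- outer((co$y - centers[b, 2])^2, (co$x - centers[b, 1])^2, "+")
      dens[, , k] <- dens[, , k] + level * (dx2 <= rz2)
    }
  }
  phantom(dens, z = zs, z_weight = voxel_z, voxel_xy = geom$dx_sim,
          meta = list(centers = centers, diameter_um = diameter_um))
}

#' Parallel-fiber bundle phantom
#'
#' Gaussian-profile fibers running along y at given lateral positions,
#' intensities and depths, emulating a bundle of neuronal dendrites. The
#' default positions place four fibers at 3.3, 5.0, 5.8 and 6.9 um from
#' the left field edge, a tightly bundled arrangement in which stray light
#' from neighbors obscures dim fibers under widefield imaging.
#'
#' @param geom a [scan_geometry()].
#' @param fiber_positions_um lateral (x) positions, um.
#' @param fiber_fwhm fiber cross-section FWHM, um (default 0.4, a typical
#'   neurite diameter).
#' @param intensities per-fiber peak densities.
#' @param depth_offsets per-fiber depths, um.
#' @param voxel_z z slab spacing, um.
#' @return a [phantom()] with `meta$positions_um`.
#' @export
make_fiber_bundle <- function(geom,
                              fiber_positions_um = c(3.3, 5.0, 5.8, 6.9),
                              fiber_fwhm = 0.4, intensities = 1,
                              depth_offsets = 0, voxel_z = 0.2) {
  nfib <- length(fiber_positions_um)
  intensities <- rep_len(intensities, nfib)
  depth_offsets <- rep_len(depth_offsets, nfib)
  sig <- fiber_fwhm / (2 * sqrt(2 * log(2)))
  co <- sim_coords(geom)
  zmin <- min(depth_offsets) - 3 * sig; zmax <- max(depth_offsets) + 3 * sig
  zs <- seq(zmin, zmax + voxel_z / 2, by = voxel_z)
  dens <- array(0, c(geom$sim_dim, length(zs)))
  for (f in seq_len(nfib)) {
    gx <- exp(-(co$x - fiber_positions_um[f])^2 / (2 * sig^2))
    for (k in seq_along(zs)) {
      gz <- exp(-(zs[k] - depth_offsets[f])^2 / (2 * sig^2))
      if (gz < 1e-6) next
      dens[, , k] <- dens[, , k] +
        intensities[f] * gz * matrix(gx, geom$sim_dim[1], geom$sim_dim[2],
                                     byrow = TRUE)
    }
  }
  phantom(dens, z = zs, z_weight = voxel_z, voxel_xy = geom$dx_sim,
          meta = list(positions_um = fiber_positions_um,
                      intensities = intensities,
                      depth_offsets = depth_offsets))
}

#' Branched-neuron phantom
#'
#' One spherical soma plus a seeded random branched tree of thin fibers.
#' The default brightness ratios follow the fluorescences typical of the
#' neurons this method targets: soma about 20,000 counts, axon 1,000,
#' dendrites 800, i.e. a cell body 20-30x brighter than its fibers — the
#' regime in which out-of-focus soma light overwhelms nearby dim neurites.
#' Fiber centerlines are returned as ground truth for SBR evaluation.
#'
#' @param geom a [scan_geometry()].
#' @param body_intensity,axon_intensity,dendrite_intensity peak densities.
#' @param geometry_seed seed controlling the tree topology.
#' @param soma_diameter_um soma diameter, um (default 5).
#' @param fiber_fwhm fiber cross-section FWHM, um (default 0.4).
#' @param n_dendrites number of primary dendrites.
#' @param voxel_z z slab spacing, um.
#' @return a [phantom()] with `meta$centerlines` (list of n x 3 matrices,
#'   um) and `meta$soma_center`.
#' @export
make_neuron <- function(geom, body_intensity = 20000, axon_intensity = 1000,
                        dendrite_intensity = 800, geometry_seed = 1,
                        soma_diameter_um = 5, fiber_fwhm = 0.4,
                        n_dendrites = 3, voxel_z = 0.25) {
  co <- sim_coords(geom)
  fov_um <- c(max(co$x), max(co$y))
  soma_c <- c(fov_um[1] * 0.3, fov_um[2] * 0.5, 0)
  rs <- soma_diameter_um / 2
  sig <- fiber_fwhm / (2 * sqrt(2 * log(2)))
  paths <- with_seed(geometry_seed, {
    mk_path <- function(start, dir, len, wiggle = 0.3) {
      n <- max(2, ceiling(len / 0.2))
      pts <- matrix(NA_real_, n, 3)
      p <- start
      d <- dir / sqrt(sum(dir^2))
      for (i in seq_len(n)) {
        pts[i, ] <- p
        d <- d + c(stats::rnorm(2, 0, wiggle * 0.2), stats::rnorm(1, 0, wiggle * 0.1))
        d <- d / sqrt(sum(d^2))
        p <- p + d * 0.2
      }
      pts
    }
    axon <- mk_path(soma_c + c(rs, 0, 0), c(1, 0.2, 0.05),
                    fov_um[1] - soma_c[1] - rs - 0.5)
    dend <- lapply(seq_len(n_dendrites), function(i) {
      ang <- stats::runif(1, pi / 2, 3 * pi / 2)
      dir <- c(cos(ang), sin(ang), stats::runif(1, -0.3, 0.3))
      mk_path(soma_c + rs * dir / sqrt(sum(dir^2)), dir,
              stats::runif(1, 3, 6))
    })
    c(list(axon), dend)
  })
  intens <- c(axon_intensity, rep(dendrite_intensity, length(paths) - 1))
  zmax <- max(abs(c(sapply(paths, function(p) range(p[, 3])), rs))) + 3 * sig
  zs <- seq(-zmax, zmax + voxel_z / 2, by = voxel_z)
  dens <- array(0, c(geom$sim_dim, length(zs)))
  # soma
  for (k in seq_along(zs)) {
    rz2 <- rs^2 - (zs[k] - soma_c[3])^2
    if (rz2 <= 0) next
    d2 <- outer((co$y - soma_c[2])^2, (co$x - soma_c[1])^2, "+")
    dens[, , k] <- dens[, , k] + body_intensity * (d2 <= rz2)
  }
  # fibers: Gaussian blobs deposited along each centerline
  win <- ceiling(3 * sig / geom$dx_sim)
  for (f in seq_along(paths)) {
    pts <- paths[[f]]
    for (i in seq_len(nrow(pts))) {
      px <- pts[i, 1]; py <- pts[i, 2]; pz <- pts[i, 3]
      ix <- which.min(abs(co$x - px)); iy <- which.min(abs(co$y - py))
      xs <- max(1, ix - win):min(geom$sim_dim[2], ix + win)
      ys <- max(1, iy - win):min(geom$sim_dim[1], iy + win)
      g2 <- outer(exp(-(co$y[ys] - py)^2 / (2 * sig^2)),
                  exp(-(co$x[xs] - px)^2 / (2 * sig^2)))
      for (k in seq_along(zs)) {
        gz <- exp(-(zs[k] - pz)^2 / (2 * sig^2))
        if (gz < 1e-3) next
        dens[ys, xs, k] <- pmax(dens[ys, xs, k], intens[f] * gz * g2)
      }
    }
  }
  phantom(dens, z = zs, z_weight = voxel_z, voxel_xy = geom$dx_sim,
          meta = list(centerlines = paths, soma_center = soma_c,
                      intensities = intens))
}
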