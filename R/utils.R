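#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero, the
#' convention used for all printed report values (base [round()] rounds half
#' to even). Unrounded values are always retained in machine-readable
#' outputs; this helper is applied only at the reporting boundary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.835, 2)  # 0.84
#' round_half_up(-0.5)      # -1
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulations do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 2D FFT helpers. stats::fft handles matrices directly; these wrappers keep
# the forward/inverse pairing and normalization in one place.
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# Periodic Gaussian blur with an analytic transfer function
# exp(-2 pi^2 sigma^2 |f|^2). Exact for periodic boundary conditions and
# valid for any sigma (no kernel truncation). `sigma_px` is in pixels of
# `img`; `img_fft` may be supplied to reuse a cached forward transform.
gauss_blur_periodic <- function(img, sigma_px, img_fft = NULL) {
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (is.null(img_fft)) img_fft <- fft2(img)
  d <- dim(img_fft)
  tf <- gauss_transfer(d, sigma_px)
  ifft2(img_fft * tf)
}

# Transfer function of an isotropic Gaussian on a d[1] x d[2] periodic grid.
gauss_transfer <- function(d, sigma_px) {
  fy <- c(0:(d[1] %/% 2), -((d[1] - d[1] %/% 2 - 1):1)) / d[1]
  if (d[1] == 1) fy <- 0
  fx <- c(0:(d[2] %/% 2), -((d[2] - d[2] %/% 2 - 1):1)) / d[2]
  if (d[2] == 1) fx <- 0
  arg <- outer(fy^2, fx^2, "+")
  exp(-2 * pi^2 * sigma_px^2 * arg)
}

# Zero-padded Gaussian blur: pads by `pad` pixels on every side, blurs
# periodically on the padded grid, crops back. Used for localized phantoms
# where wrap-around would alias light across the field edge.
gauss_blur_padded <- function(img, sigma_px, pad = NULL) {
  if (is.null(pad)) pad <- ceiling(4 * sigma_px)
  if (pad <= 0) return(gauss_blur_periodic(img, sigma_px))
  d <- dim(img)
  big <- matrix(0, d[1] + 2 * pad, d[2] + 2 * pad)
  big[pad + seq_len(d[1]), pad + seq_len(d[2])] <- img
  out <- gauss_blur_periodic(big, sigma_px)
  out[pad + seq_len(d[1]), pad + seq_len(d[2])]
}

# Sum-bin a matrix by integer factor `f` in both dimensions (area
# integration onto coarser pixels), then divide by f^2 so intensity units
# are preserved (mean over the sub-pixels).
bin_mean <- function(img, f) {
  d <- dim(img)
  if (any(d %% f != 0)) {
    stop(sprintf("image %d x %d not divisible by bin factor %d",
                 d[1], d[2], f))
  }
  if (f == 1) return(img)
  x <- array(img, c(f, d[1] %/% f, d[2]))
  x <- colSums(x)                       # (d1/f) x d2
  x <- array(t(x), c(f, d[2] %/% f, d[1] %/% f))
  t(colSums(x)) / f^2
}

# Linear interpolation of the outermost crossings of `level` in a sampled
# profile; returns c(left_x, right_x) or NULL when no crossing exists.
outer_crossings <- function(x, y, level) {
  above <- y >= level
  if (!any(above)) return(NULL)
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  left <- if (i1 == 1) x[1] else {
    x[i1 - 1] + (level - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * (x[i1] - x[i1 - 1])
  }
  right <- if (i2 == length(x)) x[length(x)] else {
    x[i2] + (level - y[i2]) / (y[i2 + 1] - y[i2]) * (x[i2 + 1] - x[i2])
  }
  c(left, right)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
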