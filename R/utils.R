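#' @keywords internal
"_PACKAGE"

# Coordinate convention used throughout the package:
#   images are matrices M[row, col] with row = y (downward), col = x (rightward);
#   pixel (x, y) in 0-based px coordinates sits at M[y + 1, x + 1];
#   physical coordinates are x_um = x * pixel_size, y_um = y * pixel_size;
#   angles are measured with atan2(dy, dx) in this y-down frame.

#' Reduce angles into the nematic fundamental domain [0, pi)
#' @param theta angles in radians
#' @return angles mod pi in [0, pi)
#' @export
wrap_nematic <- function(theta) {
  out <- theta %% pi
  # guard against pi returned by floating point (e.g. -1e-18 %% pi)
  out[out >= pi] <- 0
  out
}

#' Smallest nematic angle difference
#'
#' Difference a - b reduced mod pi into (-pi/2, pi/2].
#' @param a,b angles in radians
#' @export
nematic_diff <- function(a, b) {
  d <- (a - b) %% pi
  d[d > pi / 2] <- d[d > pi / 2] - pi
  d
}

# circular (mod 2*pi) difference into (-pi, pi]
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Bilinear interpolation on a matrix
#'
#' Samples `M` at 0-based pixel coordinates (x, y) where x indexes columns and
#' y indexes rows. Points outside the grid return NA.
#' @param M numeric matrix
#' @param x,y coordinates in 0-based pixel units (vectors of equal length)
#' @return numeric vector of sampled values
#' @export
sample_bilinear <- function(M, x, y) {
  nr <- nrow(M); nc <- ncol(M)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 0 & y >= 0 & x <= nc - 1 & y <= nr - 1 &
    is.finite(x) & is.finite(y)
  # clamp all four corner indices into range (out-of-field points are
  # flagged by `ok` and return NA regardless of the values sampled here)
  x1 <- pmin(pmax(x0 + 1, 0), nc - 1); y1 <- pmin(pmax(y0 + 1, 0), nr - 1)
  x0 <- pmin(pmax(x0, 0), nc - 1); y0 <- pmin(pmax(y0, 0), nr - 1)
  idx <- function(yy, xx) yy + 1L + nr * xx # column-major linear index
  v <- (1 - fx) * (1 - fy) * M[idx(y0, x0)] +
    fx * (1 - fy) * M[idx(y0, x1)] +
    (1 - fx) * fy * M[idx(y1, x0)] +
    fx * fy * M[idx(y1, x1)]
  v[!ok] <- NA_real_
  v
}

# clamped bilinear sampling: coordinates outside the grid are clamped to the
# border instead of returning NA (used by the texture renderer)
sample_bilinear_clamp <- function(M, x, y) {
  nr <- nrow(M); nc <- ncol(M)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  sample_bilinear(M, x, y)
}

# Sliding-window box mean with partial windows at the borders.
# w must be a positive odd integer; uses an integral image, O(n) in pixels.
box_mean <- function(M, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  if (w == 1) return(M)
  h <- (w - 1L) / 2L
  nr <- nrow(M); nc <- ncol(M)
  # integral image with a zero first row/col
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(M, 2L, cumsum), 1L, cumsum) |> t()
  r0 <- pmax(0L, seq_len(nr) - 1L - h); r1 <- pmin(nr, seq_len(nr) + h)
  c0 <- pmax(0L, seq_len(nc) - 1L - h); c1 <- pmin(nc, seq_len(nc) + h)
  # sums over [r0+1, r1] x [c0+1, c1]
  sums <- S[r1 + 1L, c1 + 1L, drop = FALSE] - S[r0 + 1L, c1 + 1L, drop = FALSE] -
    S[r1 + 1L, c0 + 1L, drop = FALSE] + S[r0 + 1L, c0 + 1L, drop = FALSE]
  counts <- outer(r1 - r0, c1 - c0)
  sums / counts
}

# 1D Gaussian and Gaussian-derivative kernels, truncated at 3 sigma
gauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}
dgauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  x <- seq(-h, h)
  k <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  # normalize so that response to a unit ramp is 1
  k / sum(-x * k)
}

# separable 2D convolution with replicate borders; ky acts along rows (y),
# kx along columns (x)
conv_sep <- function(M, ky, kx) {
  K <- outer(ky, kx)
  EBImage::filter2(M, K, boundary = "replicate")
}

# run code with a temporary RNG state seeded by `seed`; restores global state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
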