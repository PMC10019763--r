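# S3 containers for the three field types the pipeline passes around.
# All of them use the raster convention: origin at the top-left pixel center,
# x rightward (columns), y downward (rows); angles from atan2(dy, dx).

#' Construct a nematic director field
#'
#' @param theta matrix of director angles in radians; stored mod pi in [0, pi)
#' @param pixel_size pixel calibration in um/px
#' @param coherency optional matrix in [0, 1] (same shape as `theta`);
#'   1 indicates a well-defined local orientation, 0 an isotropic patch
#' @return object of class `director_field` with elements `theta`,
#'   `coherency`, `pixel_size`
#' @export
director_field <- function(theta, pixel_size, coherency = NULL) {
  stopifnot(is.matrix(theta), is.numeric(pixel_size), pixel_size > 0)
  if (is.null(coherency)) coherency <- matrix(1, nrow(theta), ncol(theta))
  stopifnot(all(dim(coherency) == dim(theta)))
  if (any(!is.finite(theta))) stop("director angles must be finite")
  structure(
    list(theta = wrap_nematic(theta), coherency = coherency,
         pixel_size = pixel_size),
    class = "director_field"
  )
}

#' @export
print.director_field <- function(x, ...) {
  cat(sprintf(
    "<director_field> %d x %d px (%.3g um/px), mean coherency %.3f\n",
    nrow(x$theta), ncol(x$theta), x$pixel_size,
    mean(x$coherency, na.rm = TRUE)
  ))
  invisible(x)
}

#' Construct a velocity field on a coarse grid
#'
#' @param vx,vy matrices of velocity components in um/h; rows index y nodes,
#'   columns x nodes
#' @param x,y numeric vectors of node-center coordinates in 0-based px units
#'   (length = ncol(vx) and nrow(vx) respectively)
#' @param pixel_size um/px
#' @param frame_interval h
#' @param valid logical matrix marking trustworthy nodes (defaults to finite
#'   entries of `vx`)
#' @return object of class `velocity_field`
#' @export
velocity_field <- function(vx, vy, x, y, pixel_size, frame_interval,
                           valid = NULL) {
  stopifnot(is.matrix(vx), all(dim(vx) == dim(vy)),
            length(x) == ncol(vx), length(y) == nrow(vx),
            pixel_size > 0, frame_interval > 0)
  if (is.null(valid)) valid <- is.finite(vx) & is.finite(vy)
  structure(
    list(vx = vx, vy = vy, x = x, y = y, pixel_size = pixel_size,
         frame_interval = frame_interval, valid = valid),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- sqrt(x$vx^2 + x$vy^2)
  cat(sprintf(
    "<velocity_field> %d x %d nodes, mean speed %.3g um/h, %d%% valid\n",
    nrow(x$vx), ncol(x$vx), mean(sp[x$valid], na.rm = TRUE),
    round(100 * mean(x$valid))
  ))
  invisible(x)
}

# sample a velocity field at arbitrary px coordinates (bilinear in node space)
sample_velocity <- function(vf, x_px, y_px) {
  dx <- diff(vf$x); dy <- diff(vf$y)
  gx <- if (length(dx)) dx[1] else 1
  gy <- if (length(dy)) dy[1] else 1
  u <- (x_px - vf$x[1]) / gx
  v <- (y_px - vf$y[1]) / gy
  vxm <- vf$vx; vym <- vf$vy
  vxm[!vf$valid] <- NA; vym[!vf$valid] <- NA
  list(vx = sample_bilinear(vxm, u, v), vy = sample_bilinear(vym, u, v))
}

#' Construct a windowed nematic order-parameter field
#'
#' @param q matrix of the local order parameter in [0, 1]
#' @param omega_um window size in um
#' @param pixel_size um/px
#' @return object of class `order_field`
#' @export
order_field <- function(q, omega_um, pixel_size) {
  stopifnot(is.matrix(q), omega_um > 0, pixel_size > 0)
  structure(
    list(q = q, omega_um = omega_um, pixel_size = pixel_size),
    class = "order_field"
  )
}

#' @export
print.order_field <- function(x, ...) {
  cat(sprintf(
    "<order_field> %d x %d px, omega = %.3g um, q in [%.3f, %.3f]\n",
    nrow(x$q), ncol(x$q), x$omega_um, min(x$q), max(x$q)
  ))
  invisible(x)
}
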