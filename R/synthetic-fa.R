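# Synthetic focal-adhesion images and nuclei point sets.

#' Render an image of elliptical focal-adhesion-like blobs
#'
#' Each blob is a filled ellipse of the requested area, aspect ratio and
#' orientation, with intensity well above the background; Gaussian
#' background noise is added on top.
#'
#' @param blobs data.frame with columns `x_um`, `y_um`, `area_um2`,
#'   `aspect` (major/minor axis ratio >= 1), `orientation` (radians,
#'   major-axis angle, nematic). May have zero rows.
#' @param shape pixel grid c(rows, cols)
#' @param pixel_size um/px
#' @param fg_intensity blob intensity (background is 0)
#' @param background_noise_sd Gaussian noise sd
#' @param seed integer seed
#' @return numeric matrix in roughly [0, 1]
#' @export
make_fa_image <- function(blobs, shape = c(256L, 256L), pixel_size = 0.1,
                          fg_intensity = 0.9, background_noise_sd = 0.02,
                          seed = 1) {
  blobs <- as.data.frame(blobs)
  img <- matrix(0, shape[1], shape[2])
  if (nrow(blobs) > 0) {
    X <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]),
                shape[1], shape[2]) * pixel_size
    Y <- matrix(rep(seq_len(shape[1]) - 1, times = shape[2]),
                shape[1], shape[2]) * pixel_size
    for (i in seq_len(nrow(blobs))) {
      a_um2 <- blobs$area_um2[i]
      asp <- if (is.null(blobs$aspect)) 1 else blobs$aspect[i]
      ang <- if (is.null(blobs$orientation)) 0 else blobs$orientation[i]
      a <- sqrt(a_um2 * asp / pi) # semi-major, um
      b <- a / asp                # semi-minor
      dx <- X - blobs$x_um[i]; dy <- Y - blobs$y_um[i]
      u <- cos(ang) * dx + sin(ang) * dy
      v <- -sin(ang) * dx + cos(ang) * dy
      img[(u / a)^2 + (v / b)^2 <= 1] <- fg_intensity
    }
  }
  if (background_noise_sd > 0) {
    img <- img + with_seed(seed, matrix(
      stats::rnorm(length(img), sd = background_noise_sd),
      shape[1], shape[2]
    ))
  }
  pmin(pmax(img, 0), 1)
}

#' Sample nuclei positions with an optional density hotspot
#'
#' Homogeneous Poisson points at `base_density` over a rectangular field,
#' plus an independent Poisson excess of (fold_excess - 1) * base_density
#' inside a disc, so the hotspot density is fold_excess times the
#' background.
#'
#' @param base_density cells/mm^2
#' @param field_um c(width, height) of the field in um
#' @param hotspot NULL or list(center = c(x_um, y_um), radius_um,
#'   fold_excess >= 1)
#' @param seed integer seed
#' @return data.frame with columns x_um, y_um
#' @export
make_nuclei_points <- function(base_density, field_um = c(400, 400),
                               hotspot = NULL, seed = 1) {
  stopifnot(base_density >= 0, all(field_um >= 0))
  area_mm2 <- prod(field_um) / 1e6
  with_seed(seed, {
    n <- stats::rpois(1, base_density * area_mm2)
    pts <- data.frame(x_um = stats::runif(n, 0, field_um[1]),
                      y_um = stats::runif(n, 0, field_um[2]))
    if (!is.null(hotspot) && hotspot$fold_excess > 1) {
      disc_mm2 <- pi * hotspot$radius_um^2 / 1e6
      m <- stats::rpois(1, (hotspot$fold_excess - 1) * base_density * disc_mm2)
      if (m > 0) {
        r <- hotspot$radius_um * sqrt(stats::runif(m))
        a <- stats::runif(m, 0, 2 * pi)
        extra <- data.frame(x_um = hotspot$center[1] + r * cos(a),
                            y_um = hotspot$center[2] + r * sin(a))
        keep <- extra$x_um >= 0 & extra$x_um <= field_um[1] &
          extra$y_um >= 0 & extra$y_um <= field_um[2]
        pts <- rbind(pts, extra[keep, ])
      }
    }
    rownames(pts) <- NULL
    pts
  })
}
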