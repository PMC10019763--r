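# Defect-frame registration and averaging of director and velocity fields.
#
# Each +1/2 observation is translated so its core sits at the origin and
# rotated so its tail lies along +x; director patches are resampled through
# the tensor components (cos 2T, sin 2T) with the angle shifted by -psi
# (angles are never averaged raw — the pi-ambiguity makes raw angle means
# ill-defined), and velocity vectors are rotated by -psi.

#' Register one defect observation into the canonical defect frame
#'
#' @param director a [director_field()] (may be NULL)
#' @param velocity a [velocity_field()] (may be NULL)
#' @param obs one-row data.frame with x_um, y_um, charge (+1/2), axis_rad
#' @param half_size_um patch half-size in um
#' @param step_um patch grid spacing in um
#' @return list of class `defect_patch` with `u`, `v` (defect-frame node
#'   coordinates, um), `c2`, `s2` (director tensor components), `vx`, `vy`
#'   (velocity in the defect frame, um/h); out-of-field nodes are NA
#' @export
register_observation <- function(director, velocity, obs, half_size_um = 150,
                                 step_um = 10) {
  if (!isTRUE(all.equal(obs$charge, 0.5))) {
    stop("defect-frame registration requires a +1/2 observation")
  }
  psi <- obs$axis_rad
  u <- seq(-half_size_um, half_size_um, by = step_um)
  v <- seq(-half_size_um, half_size_um, by = step_um)
  U <- matrix(rep(u, each = length(v)), length(v), length(u))
  V <- matrix(rep(v, times = length(u)), length(v), length(u))
  # lab positions of the patch nodes
  xl <- obs$x_um + cos(psi) * U - sin(psi) * V
  yl <- obs$y_um + sin(psi) * U + cos(psi) * V
  out <- list(u = u, v = v, half_size_um = half_size_um, step_um = step_um)
  if (!is.null(director)) {
    px <- director$pixel_size
    th <- director$theta
    c2l <- matrix(sample_bilinear(cos(2 * th), xl / px, yl / px),
                  nrow(U), ncol(U))
    s2l <- matrix(sample_bilinear(sin(2 * th), xl / px, yl / px),
                  nrow(U), ncol(U))
    # rotate the director into the defect frame: theta' = theta - psi
    out$c2 <- c2l * cos(2 * psi) + s2l * sin(2 * psi)
    out$s2 <- -c2l * sin(2 * psi) + s2l * cos(2 * psi)
  }
  if (!is.null(velocity)) {
    sv <- sample_velocity(velocity, xl / velocity$pixel_size,
                          yl / velocity$pixel_size)
    vxl <- matrix(sv$vx, nrow(U), ncol(U))
    vyl <- matrix(sv$vy, nrow(U), ncol(U))
    out$vx <- cos(psi) * vxl + sin(psi) * vyl
    out$vy <- -sin(psi) * vxl + cos(psi) * vyl
  }
  class(out) <- "defect_patch"
  out
}

#' Average registered defect patches
#'
#' Director patches are averaged through their tensor components and
#' converted back to a half-angle; velocities are averaged per component
#' over unmasked nodes. Nodes observed fewer than `min_n` times are masked.
#'
#' @param patches list of `defect_patch` objects on one grid
#' @param min_n minimum observations per node
#' @return list of class `defect_frame_mean` with `u`, `v`, `theta`,
#'   `order` (resultant length of the tensor mean), `vx`, `vy`, `n`
#' @export
average_frames <- function(patches, min_n = 1) {
  stopifnot(length(patches) >= 1)
  p1 <- patches[[1]]
  acc <- function(name) {
    if (is.null(p1[[name]])) return(NULL)
    s <- array(0, dim(p1[[name]])); n <- s
    for (p in patches) {
      m <- p[[name]]
      ok <- is.finite(m)
      s[ok] <- s[ok] + m[ok]
      n[ok] <- n[ok] + 1
    }
    list(mean = ifelse(n >= max(min_n, 1), s / pmax(n, 1), NA_real_), n = n)
  }
  out <- list(u = p1$u, v = p1$v)
  c2 <- acc("c2"); s2 <- acc("s2")
  if (!is.null(c2)) {
    out$theta <- wrap_nematic(0.5 * atan2(s2$mean, c2$mean))
    out$order <- sqrt(c2$mean^2 + s2$mean^2)
    out$n <- c2$n
  }
  vx <- acc("vx"); vy <- acc("vy")
  if (!is.null(vx)) {
    out$vx <- vx$mean; out$vy <- vy$mean
    if (is.null(out$n)) out$n <- vx$n
  }
  class(out) <- "defect_frame_mean"
  out
}

#' Axial velocity profile in the defect frame
#'
#' Mean x-component of the defect-frame velocity over the band
#' |y| <= `band_halfwidth_um`, binned along x (x = 0 is the core, +x the
#' tail). SEM per bin.
#'
#' @param frame_mean a `defect_frame_mean` (or a single `defect_patch`)
#'   with vx present
#' @param band_halfwidth_um half-width of the averaging band in um (> 0)
#' @param bin_um bin width along x (default: the grid step)
#' @return data.frame with x_um, v_axial_umh, sem, n
#' @export
axial_profile <- function(frame_mean, band_halfwidth_um = 30, bin_um = NULL) {
  if (band_halfwidth_um <= 0) stop("band half-width must be positive")
  if (is.null(frame_mean$vx)) stop("no velocity in this frame average")
  u <- frame_mean$u; v <- frame_mean$v
  if (is.null(bin_um)) bin_um <- diff(u)[1]
  inband <- which(abs(v) <= band_halfwidth_um)
  rows <- list()
  edges <- seq(min(u) - bin_um / 2, max(u) + bin_um / 2, by = bin_um)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  for (bi in seq_along(mids)) {
    cols <- which(u >= edges[bi] & u < edges[bi + 1])
    if (length(cols) == 0) next
    vals <- frame_mean$vx[inband, cols]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      x_um = mids[bi], v_axial_umh = mean(vals),
      sem = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
      n = length(vals)
    )
  }
  do.call(rbind, rows)
}

#' Contractile / extensile signature of the averaged defect-frame flow
#'
#' The mean axial velocity over a core disc decides the sign: flow toward
#' the tail (+x) beyond `noise_floor` is contractile, toward the head
#' extensile, otherwise indeterminate. The antisymmetry of the vorticity
#' about the defect axis is also measured (correlation of omega(u, v) with
#' -omega(u, -v)) and returned as an attribute.
#'
#' @param frame_mean a `defect_frame_mean` with vx/vy
#' @param core_radius_um radius of the core disc in um
#' @param noise_floor_umh minimum |mean axial velocity| to call a sign
#' @return "contractile", "extensile" or "indeterminate"; attributes
#'   `core_axial_umh` and `vorticity_antisymmetry`
#' @export
contractility_sign <- function(frame_mean, core_radius_um = 30,
                               noise_floor_umh = 0.5) {
  u <- frame_mean$u; v <- frame_mean$v
  U <- matrix(rep(u, each = length(v)), length(v), length(u))
  V <- matrix(rep(v, times = length(u)), length(v), length(u))
  core <- U^2 + V^2 <= core_radius_um^2
  vals <- frame_mean$vx[core]
  m <- mean(vals[is.finite(vals)])
  # vorticity d(vy)/du - d(vx)/dv by central differences
  h <- diff(u)[1]
  ddu <- function(M) {
    out <- M * NA
    out[, 2:(ncol(M) - 1)] <- (M[, 3:ncol(M)] - M[, 1:(ncol(M) - 2)]) / (2 * h)
    out
  }
  ddv <- function(M) {
    out <- M * NA
    out[2:(nrow(M) - 1), ] <- (M[3:nrow(M), ] - M[1:(nrow(M) - 2), ]) / (2 * h)
    out
  }
  om <- ddu(frame_mean$vy) - ddv(frame_mean$vx)
  # compare with the mirrored field (v -> -v); grid is symmetric about 0
  om_m <- om[rev(seq_along(v)), ]
  ok <- is.finite(om) & is.finite(om_m) & abs(om) + abs(om_m) > 0
  anti <- if (sum(ok) > 3 && stats::sd(om[ok]) > 0) {
    stats::cor(om[ok], -om_m[ok])
  } else NA_real_
  res <- if (!is.finite(m) || abs(m) <= noise_floor_umh) "indeterminate"
  else if (m > 0) "contractile" else "extensile"
  structure(res, core_axial_umh = m, vorticity_antisymmetry = anti)
}

#' Cell density map from nuclei positions
#'
#' Sliding-window point counts divided by the window area.
#'
#' @param points data.frame with x_um, y_um
#' @param field_um c(width, height) of the field in um
#' @param window_um square counting window side in um
#' @param step_um grid spacing of the output map
#' @return list with `x`, `y` (um) and `density` (cells/mm^2 matrix)
#' @export
density_map <- function(points, field_um, window_um = 50, step_um = 10) {
  xs <- seq(window_um / 2, field_um[1] - window_um / 2, by = step_um)
  ys <- seq(window_um / 2, field_um[2] - window_um / 2, by = step_um)
  D <- matrix(0, length(ys), length(xs))
  if (nrow(points) > 0) {
    for (i in seq_along(ys)) for (j in seq_along(xs)) {
      D[i, j] <- sum(abs(points$x_um - xs[j]) <= window_um / 2 &
                       abs(points$y_um - ys[i]) <= window_um / 2)
    }
  }
  list(x = xs, y = ys, density = D / (window_um^2 / 1e6))
}

#' Cell density profile along the defect axis
#'
#' Transforms nuclei positions into the defect frame of `obs` (tail along
#' +x) and bins counts along x within |y| <= `band_halfwidth_um`,
#' normalized to cells/mm^2.
#'
#' @param points data.frame with x_um, y_um
#' @param obs one-row +1/2 defect observation (x_um, y_um, axis_rad)
#' @param half_size_um profile extent in um
#' @param band_halfwidth_um band half-width in um
#' @param bin_um bin width in um
#' @return data.frame with x_um, n, density_mm2
#' @export
head_density_profile <- function(points, obs, half_size_um = 150,
                                 band_halfwidth_um = 30, bin_um = 20) {
  psi <- obs$axis_rad
  dx <- points$x_um - obs$x_um
  dy <- points$y_um - obs$y_um
  u <- cos(psi) * dx + sin(psi) * dy
  v <- -sin(psi) * dx + cos(psi) * dy
  keep <- abs(v) <= band_halfwidth_um & abs(u) <= half_size_um
  u <- u[keep]
  edges <- seq(-half_size_um, half_size_um, by = bin_um)
  n <- tabulate(findInterval(u, edges, rightmost.closed = TRUE),
                nbins = length(edges) - 1)
  area_mm2 <- bin_um * 2 * band_halfwidth_um / 1e6
  data.frame(x_um = (edges[-1] + edges[-length(edges)]) / 2,
             n = n, density_mm2 = n / area_mm2)
}
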