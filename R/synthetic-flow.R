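# Parametric ground-truth flow fields around a +1/2 defect.
#
# motile_contractile: in the defect frame (tail along +x, core at the
# center) v = v0 * exp(-r/l) * x_hat. The core flow points toward the tail
# (the contractile signature) and the vorticity, -d(vx)/dy, forms two
# counter-rotating lobes antisymmetric about the defect axis.
#
# stationary_asymmetric: zero velocity on the tail half-plane (x > 0); on
# the head half-plane (x < 0) the flow points toward the core with
# magnitude v0 * exp(-r/l), emulating a defect whose head cells converge on
# a pinned core.

#' Synthetic velocity field around a +1/2 defect
#'
#' @param kind "motile_contractile" or "stationary_asymmetric"
#' @param axis_angle tail direction of the defect in radians
#' @param v0 peak speed in um/h (> 0)
#' @param decay_length exponential decay length in um (> 0)
#' @param shape pixel grid c(rows, cols) the field refers to
#' @param pixel_size um/px
#' @param center_um defect core position c(x, y) in um (default grid center)
#' @param grid_step_px node spacing of the returned coarse grid in px
#' @param frame_interval h (metadata carried by the field)
#' @return a [velocity_field()]
#' @export
make_defect_flow <- function(kind = c("motile_contractile",
                                      "stationary_asymmetric"),
                             axis_angle = 0, v0 = 20, decay_length = 60,
                             shape = c(256L, 256L), pixel_size = 1.5,
                             center_um = NULL, grid_step_px = 8,
                             frame_interval = 0.25) {
  kind <- match.arg(kind)
  stopifnot(v0 > 0, decay_length > 0)
  if (is.null(center_um)) {
    center_um <- c((shape[2] - 1) / 2, (shape[1] - 1) / 2) * pixel_size
  }
  xs <- seq(0, shape[2] - 1, by = grid_step_px)
  ys <- seq(0, shape[1] - 1, by = grid_step_px)
  X <- matrix(rep(xs, each = length(ys)), length(ys), length(xs)) * pixel_size
  Y <- matrix(rep(ys, times = length(xs)), length(ys), length(xs)) * pixel_size
  # defect-frame coordinates (u along the tail, v across)
  dx <- X - center_um[1]; dy <- Y - center_um[2]
  u <- cos(axis_angle) * dx + sin(axis_angle) * dy
  v <- -sin(axis_angle) * dx + cos(axis_angle) * dy
  r <- sqrt(u^2 + v^2)
  if (kind == "motile_contractile") {
    fu <- v0 * exp(-r / decay_length)
    fv <- 0 * r
  } else {
    mag <- v0 * exp(-r / decay_length)
    rr <- pmax(r, 1e-9)
    fu <- ifelse(u < 0, mag * (-u / rr), 0)
    fv <- ifelse(u < 0, mag * (-v / rr), 0)
  }
  # rotate back to the lab frame
  vx <- cos(axis_angle) * fu - sin(axis_angle) * fv
  vy <- sin(axis_angle) * fu + cos(axis_angle) * fv
  velocity_field(vx, vy, xs, ys, pixel_size, frame_interval)
}

#' Trajectory specification for synthetic defect tracks
#'
#' @param start_um c(x, y) start position in um
#' @param velocity_umh c(vx, vy) in um/h
#' @param frame_interval h (> 0)
#' @param n_frames number of frames (>= 2)
#' @param jitter_sd isotropic Gaussian positional jitter per frame, um
#' @param charge defect charge carried by the observations
#' @export
trajectory_spec <- function(start_um, velocity_umh, frame_interval = 0.25,
                            n_frames = 20, jitter_sd = 0, charge = 0.5) {
  stopifnot(n_frames >= 2, frame_interval > 0, jitter_sd >= 0)
  structure(
    list(start_um = start_um, velocity_umh = velocity_umh,
         frame_interval = frame_interval, n_frames = n_frames,
         jitter_sd = jitter_sd, charge = charge),
    class = "trajectory_spec"
  )
}

#' Generate per-frame defect observations from trajectory specs
#'
#' Positions follow start + velocity * t plus Gaussian jitter of the given
#' standard deviation; deterministic under a fixed seed.
#'
#' @param specs list of [trajectory_spec()] objects (sharing frame_interval
#'   and n_frames)
#' @param seed integer seed
#' @return data.frame with columns frame (0-based), x_um, y_um, charge,
#'   axis_rad (0), q_core (NA), spec_id
#' @export
make_tracks <- function(specs, seed = 1) {
  stopifnot(length(specs) >= 1)
  nf <- specs[[1]]$n_frames
  dt <- specs[[1]]$frame_interval
  stopifnot(all(vapply(specs, function(s) s$n_frames, 1) == nf),
            all(vapply(specs, function(s) s$frame_interval, 1) == dt))
  with_seed(seed, {
    rows <- lapply(seq_along(specs), function(i) {
      s <- specs[[i]]
      t <- (seq_len(nf) - 1) * dt
      jx <- if (s$jitter_sd > 0) stats::rnorm(nf, sd = s$jitter_sd) else 0
      jy <- if (s$jitter_sd > 0) stats::rnorm(nf, sd = s$jitter_sd) else 0
      data.frame(
        frame = seq_len(nf) - 1L,
        x_um = s$start_um[1] + s$velocity_umh[1] * t + jx,
        y_um = s$start_um[2] + s$velocity_umh[2] * t + jy,
        charge = s$charge, axis_rad = 0, q_core = NA_real_, spec_id = i
      )
    })
    do.call(rbind, rows)
  })
}
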