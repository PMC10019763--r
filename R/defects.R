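# Defect detection from a director field: windowed nematic order parameter,
# winding-number charge on virtual loops, and axis orientation.

#' Windowed nematic order parameter
#'
#' Q_local(Omega) = sqrt(<cos 2T>^2 + <sin 2T>^2) with the means taken over
#' a sliding square window of side Omega. Equals 1 iff all angles in the
#' window coincide (mod pi); minima mark defect cores.
#'
#' @param director a [director_field()]
#' @param omega_um window side in um (default 27.8); converted to the
#'   nearest odd pixel count, at least 4 px before rounding
#' @return an [order_field()]
#' @export
local_order_parameter <- function(director, omega_um = 27.8) {
  stopifnot(inherits(director, "director_field"))
  w_px <- omega_um / director$pixel_size
  if (w_px < 4) stop("window smaller than 4 px")
  w <- as.integer(2 * floor(w_px / 2) + 1) # odd
  th <- director$theta
  if (w > nrow(th) || w > ncol(th)) stop("window larger than the field")
  c2 <- box_mean(cos(2 * th), w)
  s2 <- box_mean(sin(2 * th), w)
  q <- sqrt(c2^2 + s2^2)
  order_field(pmin(q, 1), omega_um, director$pixel_size)
}

# sample director angles along a circular loop (tensor-bilinear, so the
# pi-ambiguity never crosses an interpolation)
loop_theta <- function(director, center_px, radius_px, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- center_px[1] + radius_px * cos(t)
  y <- center_px[2] + radius_px * sin(t)
  th <- director$theta
  c2 <- sample_bilinear(cos(2 * th), x, y)
  s2 <- sample_bilinear(sin(2 * th), x, y)
  if (any(is.na(c2))) stop("loop exits the field")
  list(phi = t, theta = 0.5 * atan2(s2, c2))
}

#' Winding number of the director around a point
#'
#' Samples the director at `n_points` on a circle and accumulates
#' successive nematic angle differences (each reduced into (-pi/2, pi/2]);
#' the total divided by 2*pi is the charge. The raw value is snapped to the
#' nearest multiple of 1/2 when within `snap_tol`; otherwise the unsnapped
#' value is returned with attribute `valid = FALSE`.
#'
#' @param director a [director_field()]
#' @param center_px c(x, y) loop center in 0-based px
#' @param radius_px loop radius in px (>= 3)
#' @param n_points samples on the loop (>= 16)
#' @param snap_tol snapping tolerance on the raw winding
#' @return half-integer charge (attribute `valid`)
#' @export
winding_number <- function(director, center_px, radius_px, n_points = 64,
                           snap_tol = 0.1) {
  stopifnot(radius_px >= 3, n_points >= 16)
  lp <- loop_theta(director, center_px, radius_px, n_points)
  th <- c(lp$theta, lp$theta[1])
  k_raw <- sum(nematic_diff(th[-1], th[-length(th)])) / (2 * pi)
  k_snap <- round(k_raw * 2) / 2
  if (abs(k_raw - k_snap) <= snap_tol) {
    structure(k_snap, valid = TRUE)
  } else {
    structure(k_raw, valid = FALSE)
  }
}

#' Winding number along the image boundary
#'
#' Accumulates nematic angle differences along a rectangular loop `margin`
#' px inside the border; equals the total charge enclosed.
#'
#' @param director a [director_field()]
#' @param margin_px inset from the border in px
#' @param step_px sampling step along the rectangle
#' @return half-integer total charge (attribute `valid`)
#' @export
boundary_winding <- function(director, margin_px = 3, step_px = 2) {
  th <- director$theta
  nr <- nrow(th); nc <- ncol(th)
  x0 <- margin_px; x1 <- nc - 1 - margin_px
  y0 <- margin_px; y1 <- nr - 1 - margin_px
  stopifnot(x1 > x0, y1 > y0)
  sx <- seq(x0, x1, by = step_px); sy <- seq(y0, y1, by = step_px)
  xs <- c(sx, rep(x1, length(sy)), rev(sx), rep(x0, length(sy)))
  ys <- c(rep(y0, length(sx)), sy, rep(y1, length(sx)), rev(sy))
  c2 <- sample_bilinear(cos(2 * th), xs, ys)
  s2 <- sample_bilinear(sin(2 * th), xs, ys)
  ang <- 0.5 * atan2(s2, c2)
  ang <- c(ang, ang[1])
  k_raw <- sum(nematic_diff(ang[-1], ang[-length(ang)])) / (2 * pi)
  k_snap <- round(k_raw * 2) / 2
  structure(k_snap, valid = abs(k_raw - k_snap) <= 0.1)
}

#' Axis orientation of a half-integer defect
#'
#' For a defect of charge k at `core_px` the director near the core is
#' Theta = k*phi + c; the axis follows from the local phase constant c.
#' Two estimators are provided:
#' \describe{
#'   \item{loop}{(default) phase demodulation: c is recovered from the
#'     argument of mean(exp(i*(2*Theta - 2*k*phi))) sampled on circles of
#'     `radii_px`. Exact on the ideal one-defect solution; perturbations
#'     from distant defects average out on a full circle (mean-value
#'     property of harmonic functions).}
#'   \item{divq}{divergence of the nematic tensor Q = (cos 2T, sin 2T),
#'     averaged over an annulus (demodulated by exp(2*i*phi) for
#'     k = -1/2).}
#' }
#' For k = +1/2 the returned angle is the TAIL direction in [0, 2*pi); for
#' k = -1/2 it is the canonical symmetry axis in [0, 2*pi/3).
#'
#' @param director a [director_field()]
#' @param core_px c(x, y) core position, 0-based px
#' @param charge +1/2 or -1/2
#' @param radii_px loop radii (loop method) or annulus radii span (divq)
#' @param method "loop" or "divq"
#' @return axis angle in radians
#' @export
defect_axis <- function(director, core_px, charge, radii_px = c(5, 8, 11),
                        method = c("loop", "divq")) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(abs(charge), 0.5))) stop("axis undefined")
  if (method == "loop") {
    ms <- vapply(radii_px, function(r) {
      lp <- loop_theta(director, core_px, r, n = 96)
      mean(exp(1i * (2 * lp$theta - 2 * charge * lp$phi)))
    }, complex(1))
    two_c <- Arg(mean(ms))
  } else {
    th <- director$theta
    q11 <- cos(2 * th); q12 <- sin(2 * th)
    # central differences
    ddx <- function(M) {
      out <- M * 0
      out[, 2:(ncol(M) - 1)] <- (M[, 3:ncol(M)] - M[, 1:(ncol(M) - 2)]) / 2
      out
    }
    ddy <- function(M) {
      out <- M * 0
      out[2:(nrow(M) - 1), ] <- (M[3:nrow(M), ] - M[1:(nrow(M) - 2), ]) / 2
      out
    }
    p1 <- ddx(q11) + ddy(q12)
    p2 <- ddx(q12) - ddy(q11)
    t <- seq(0, 2 * pi, length.out = 97)[-97]
    acc <- complex(real = 0, imaginary = 0)
    for (r in seq(min(radii_px), max(radii_px), by = 1)) {
      x <- core_px[1] + r * cos(t); y <- core_px[2] + r * sin(t)
      pv <- complex(real = sample_bilinear(p1, x, y),
                    imaginary = sample_bilinear(p2, x, y))
      if (any(is.na(pv))) stop("loop exits the field")
      if (charge > 0) acc <- acc + mean(pv) * r
      else acc <- acc + mean(pv * exp(2i * t)) * r
    }
    two_c <- if (charge > 0) Arg(acc) else Arg(acc) - pi
  }
  period <- if (charge > 0) 2 * pi else 2 * pi / 3
  out <- (if (charge > 0) two_c else two_c / 3) %% period
  if (out >= period - 1e-12) out <- 0 # floating-point boundary guard
  out
}

#' Detect topological defects in a director field
#'
#' Candidates are local minima of the windowed order parameter below
#' `q_threshold`, suppressed to a minimum pairwise separation (keeping the
#' deepest minimum), localized to sub-node precision by a quadratic fit,
#' then charged by [winding_number()] on loops of `radii_px` (majority vote
#' over radii). Candidates whose winding does not snap to a non-zero
#' half-integer are dropped (with a warning when `verbose`).
#'
#' @param order an [order_field()] from [local_order_parameter()]
#' @param director the underlying [director_field()]
#' @param q_threshold detection threshold on Q_local (0 < t < 1)
#' @param min_separation_um minimum distance between detections (default:
#'   the order-parameter window)
#' @param radii_px loop radii for charge and axis measurement
#' @param frame frame index stored in the output
#' @param verbose warn on dropped candidates
#' @return data.frame with columns frame, x_um, y_um, charge, axis_rad,
#'   q_core (zero rows when nothing is found)
#' @export
detect_defects <- function(order, director, q_threshold = 0.5,
                           min_separation_um = NULL, radii_px = c(5, 8, 11),
                           frame = 0L, verbose = TRUE) {
  stopifnot(inherits(order, "order_field"),
            inherits(director, "director_field"),
            q_threshold > 0, q_threshold < 1)
  if (is.null(min_separation_um)) min_separation_um <- order$omega_um
  q <- order$q
  nr <- nrow(q); nc <- ncol(q)
  px <- director$pixel_size
  empty <- data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), charge = numeric(0),
                      axis_rad = numeric(0), q_core = numeric(0))

  # strict interior local minima of the 3x3 neighborhood
  inner <- q[2:(nr - 1), 2:(nc - 1)]
  ismin <- inner < q_threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismin <- ismin & (inner <= q[2:(nr - 1) + dy, 2:(nc - 1) + dx])
  }
  idx <- which(ismin, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
  cand$q <- q[cbind(cand$row, cand$col)]
  cand <- cand[order(cand$q), ]

  # non-maximum suppression at min_separation
  sep_px <- min_separation_um / px
  keep <- logical(nrow(cand))
  kept_xy <- matrix(numeric(0), 0, 2)
  dropped <- 0L
  for (i in seq_len(nrow(cand))) {
    xy <- c(cand$col[i] - 1, cand$row[i] - 1)
    if (nrow(kept_xy) == 0 ||
        min(sqrt(rowSums((kept_xy - matrix(xy, nrow(kept_xy), 2,
                                           byrow = TRUE))^2))) >= sep_px) {
      keep[i] <- TRUE
      kept_xy <- rbind(kept_xy, xy)
    } else {
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0 && verbose) {
    warning(sprintf("%d candidate minima suppressed within min_separation",
                    dropped))
  }
  cand <- cand[keep, , drop = FALSE]

  out <- empty
  for (i in seq_len(nrow(cand))) {
    r <- cand$row[i]; cl <- cand$col[i]
    # sub-node localization by separable quadratic fit
    dx <- dy <- 0
    if (cl > 1 && cl < nc) {
      den <- q[r, cl - 1] - 2 * q[r, cl] + q[r, cl + 1]
      if (den > 0) dx <- 0.5 * (q[r, cl - 1] - q[r, cl + 1]) / den
    }
    if (r > 1 && r < nr) {
      den <- q[r - 1, cl] - 2 * q[r, cl] + q[r + 1, cl]
      if (den > 0) dy <- 0.5 * (q[r - 1, cl] - q[r + 1, cl]) / den
    }
    dx <- max(min(dx, 1), -1); dy <- max(min(dy, 1), -1)
    core <- c(cl - 1 + dx, r - 1 + dy)

    # charge: majority vote over loop radii (radii shrunk to stay in-field)
    ks <- c()
    for (rad in radii_px) {
      k <- tryCatch(winding_number(director, core, rad),
                    error = function(e) NULL)
      if (!is.null(k) && attr(k, "valid")) ks <- c(ks, as.numeric(k))
    }
    if (length(ks) == 0) { if (verbose) warning("candidate with no valid winding dropped"); next }
    tab <- sort(table(ks), decreasing = TRUE)
    k <- as.numeric(names(tab)[1])
    if (k == 0 || abs(k) > 1 || tab[1] <= length(ks) / 2 && length(tab) > 1) {
      if (verbose) warning("candidate with inconsistent winding dropped")
      next
    }
    psi <- if (abs(k) == 0.5) {
      tryCatch(defect_axis(director, core, k, radii_px), error = function(e) NA_real_)
    } else NA_real_
    out <- rbind(out, data.frame(
      frame = as.integer(frame), x_um = core[1] * px, y_um = core[2] * px,
      charge = k, axis_rad = psi, q_core = cand$q[i]
    ))
  }
  rownames(out) <- NULL
  out
}
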