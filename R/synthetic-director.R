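# Ground-truth director fields and textures.
#
# A defect of charge k at the origin has director angle theta = k*phi + c
# with phi = atan2(y, x). Superposing defects adds their phi terms; a single
# global constant then fixes the orientation of the whole configuration.
# For k = +1/2, theta = phi/2 + psi/2 puts the comet TAIL along the
# direction psi (director parallel to the axis on the tail ray, and the
# polarity vector div Q = (cos(2c), sin(2c))/r points along psi). For
# k = -1/2, theta = -phi/2 + c has its three symmetry axes at
# phi = (2c/3) mod (2pi/3); the canonical axis is the representative in
# [0, 2pi/3), and axis_angle = a is realized by c = 3a/2.

# phase constant that realizes a requested axis for a single defect
axis_to_phase <- function(charge, axis_angle) {
  if (charge == 0.5) axis_angle / 2
  else if (charge == -0.5) 1.5 * axis_angle
  else 0
}

# realized canonical axis given a local phase constant c (known mod pi)
phase_to_axis <- function(charge, c) {
  if (charge == 0.5) (2 * c) %% (2 * pi)
  else if (charge == -0.5) ((2 * c) / 3) %% (2 * pi / 3)
  else NA_real_
}

#' Generate a director field containing prescribed topological defects
#'
#' Builds the harmonic nematic solution Theta(x, y) = sum_i k_i * phi_i + c0
#' on a pixel grid. Charges must be non-zero half-integers with |k| <= 1.
#' With several defects a single global phase cannot realize every requested
#' axis; the phase is chosen so the FIRST defect's axis is honored exactly,
#' and the realized axis of every defect (from the effective local phase,
#' which includes the contribution of all other defects at its core) is
#' returned in the truth table.
#'
#' @param defects data.frame with columns `x_um`, `y_um`, `charge` and
#'   optionally `axis_angle` (radians; tail direction for +1/2, canonical
#'   symmetry axis for -1/2). May have zero rows.
#' @param background_angle uniform angle added to the field (radians)
#' @param shape integer c(rows, cols) of the pixel grid
#' @param pixel_size um/px
#' @return a list of class `synthetic_director_scene` with elements
#'   `director` (a [director_field()]) and `truth` (data.frame with columns
#'   x_um, y_um, charge, axis_rad — the realized axes)
#' @export
make_defect_director <- function(defects, background_angle = 0,
                                 shape = c(256L, 256L), pixel_size = 1.5) {
  stopifnot(length(shape) == 2, pixel_size > 0)
  if (is.null(defects) || nrow(as.data.frame(defects)) == 0) {
    defects <- data.frame(x_um = numeric(0), y_um = numeric(0),
                          charge = numeric(0), axis_angle = numeric(0))
  }
  defects <- as.data.frame(defects)
  n <- nrow(defects)
  if (n > 0) {
    k <- defects$charge
    if (any(abs(k * 2 - round(k * 2)) > 1e-9) || any(k == 0) ||
        any(abs(k) > 1)) {
      stop("charges must be non-zero half-integer multiples with |k| <= 1")
    }
    if (is.null(defects$axis_angle)) defects$axis_angle <- 0
    xs_px <- defects$x_um / pixel_size
    ys_px <- defects$y_um / pixel_size
    if (any(xs_px < 0 | xs_px > shape[2] - 1 | ys_px < 0 | ys_px > shape[1] - 1)) {
      stop("defect positions must lie inside the grid")
    }
    if (n > 1) {
      dm <- as.matrix(stats::dist(cbind(xs_px, ys_px)))
      if (min(dm[upper.tri(dm)]) < 2) stop("degenerate configuration")
    }
  }

  xs <- seq_len(shape[2]) - 1
  ys <- seq_len(shape[1]) - 1
  X <- matrix(rep(xs, each = shape[1]), shape[1], shape[2])
  Y <- matrix(rep(ys, times = shape[2]), shape[1], shape[2])

  theta <- matrix(background_angle, shape[1], shape[2])
  if (n > 0) {
    for (i in seq_len(n)) {
      theta <- theta + defects$charge[i] *
        atan2(Y - ys_px[i], X - xs_px[i])
    }
    # phase each other defect contributes at core i (constant to 1st order)
    cross_phase <- vapply(seq_len(n), function(i) {
      if (n == 1) return(0)
      j <- setdiff(seq_len(n), i)
      sum(defects$charge[j] *
            atan2(ys_px[i] - ys_px[j], xs_px[i] - xs_px[j]))
    }, numeric(1))
    # pick c0 so defect 1 realizes its requested axis
    c0 <- axis_to_phase(defects$charge[1], defects$axis_angle[1]) -
      background_angle - cross_phase[1]
    theta <- theta + c0
    axis_real <- vapply(seq_len(n), function(i) {
      ci <- background_angle + c0 + cross_phase[i]
      phase_to_axis(defects$charge[i], ci %% pi)
    }, numeric(1))
    truth <- data.frame(
      x_um = defects$x_um, y_um = defects$y_um,
      charge = defects$charge, axis_rad = axis_real
    )
  } else {
    truth <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        charge = numeric(0), axis_rad = numeric(0))
  }

  structure(
    list(director = director_field(theta, pixel_size), truth = truth),
    class = "synthetic_director_scene"
  )
}

#' Randomly placed defect scene with guaranteed pairwise separation
#'
#' Places `n_defects` defects with random +/-1/2 charges and random axis
#' angles inside a centered disc, rejecting draws closer than
#' `min_separation_um`. Used as the ground truth for round-trip detection
#' checks.
#'
#' @param n_defects number of defects (>= 1)
#' @param shape pixel grid c(rows, cols)
#' @param pixel_size um/px
#' @param min_separation_um minimum pairwise separation in um
#' @param margin_um keep-out distance from the image border
#' @param seed integer seed (generator is bit-reproducible given the seed)
#' @param charges optional vector to draw charges from (default c(-0.5, 0.5))
#' @return same structure as [make_defect_director()]
#' @export
random_defect_scene <- function(n_defects, shape = c(256L, 256L),
                                pixel_size = 1.5, min_separation_um = 85,
                                margin_um = 45, seed = 1,
                                charges = c(-0.5, 0.5)) {
  w_um <- (shape[2] - 1) * pixel_size
  h_um <- (shape[1] - 1) * pixel_size
  with_seed(seed, {
    pos <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pos) < n_defects) {
      cand <- c(stats::runif(1, margin_um, w_um - margin_um),
                stats::runif(1, margin_um, h_um - margin_um))
      ok <- nrow(pos) == 0 ||
        min(sqrt(rowSums((pos - matrix(cand, nrow(pos), 2,
                                       byrow = TRUE))^2))) >= min_separation_um
      if (ok) pos <- rbind(pos, cand)
      tries <- tries + 1L
      if (tries > 20000L) stop("could not place defects at this separation")
    }
    defects <- data.frame(
      x_um = pos[, 1], y_um = pos[, 2],
      charge = sample(charges, n_defects, replace = TRUE),
      axis_angle = stats::runif(n_defects, 0, 2 * pi)
    )
    make_defect_director(defects, background_angle = stats::runif(1, 0, pi),
                         shape = shape, pixel_size = pixel_size)
  })
}

#' Render a texture whose local ridge orientation follows a director field
#'
#' Smooths seeded white noise along the local director (a fixed-kernel
#' line-integral convolution): the result has elongated intensity streaks
#' whose dominant orientation equals the director angle, giving a
#' ground-truth image for the structure-tensor estimator. Deterministic for
#' a fixed seed.
#'
#' @param director a [director_field()]
#' @param stripe_period streak length scale in px (>= 4)
#' @param noise_sd additive Gaussian noise applied after rendering
#'   (fraction of the texture's unit standard deviation)
#' @param seed integer seed for the underlying white noise
#' @param noise optional pre-drawn noise matrix (same shape as the field);
#'   overrides `seed` for the base noise. Useful for grid-exact rotation
#'   checks, since the base noise — not the seed — is what rotates with
#'   the scene.
#' @return numeric matrix (float intensities, zero mean, unit sd before the
#'   additive noise)
#' @export
render_texture <- function(director, stripe_period = 8, noise_sd = 0,
                           seed = 1, noise = NULL) {
  stopifnot(inherits(director, "director_field"), stripe_period >= 4)
  th <- director$theta
  nr <- nrow(th); nc <- ncol(th)
  with_seed(seed, {
    if (is.null(noise)) noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    stopifnot(all(dim(noise) == dim(th)))
    X <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
    Y <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
    ct <- cos(th); st <- sin(th)
    # streaks ~2 periods long and 1 px thin: many independent streaks per
    # estimator window, which is what keeps the orientation error small
    L <- round(2 * stripe_period)
    ts <- seq(-L, L)
    w <- exp(-ts^2 / (2 * stripe_period^2))
    acc <- matrix(0, nr, nc)
    for (i in seq_along(ts)) {
      acc <- acc + w[i] *
        matrix(sample_bilinear_clamp(noise, X + ts[i] * ct, Y + ts[i] * st),
               nr, nc)
    }
    acc <- (acc - mean(acc)) / stats::sd(acc)
    if (noise_sd > 0) acc <- acc + matrix(stats::rnorm(nr * nc, sd = noise_sd),
                                          nr, nc)
    acc
  })
}
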