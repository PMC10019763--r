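# Director-field estimation by the local gradient structure tensor.

#' Estimate the nematic director field of a textured image
#'
#' Computes Gaussian-derivative gradients, forms the structure tensor
#' J = smooth(grad I grad I^T) with a Gaussian window, and returns the
#' orientation of the eigenvector of the SMALLEST eigenvalue (the dominant
#' texture direction, perpendicular to the mean gradient), mapped into
#' [0, pi). Coherency is (l1 - l2)/(l1 + l2) with l1 >= l2, set to 0 where
#' the tensor trace vanishes (e.g. constant image).
#'
#' Gaussian derivatives (rather than finite differences) are used for
#' rotation robustness. The default gradient scale is kept at 1 px so that
#' thin ridges contribute many independent orientation samples per window;
#' the window scale (8 px) matches the defect-core scale of the
#' order-parameter window used downstream.
#'
#' @param image numeric matrix (finite values), at least 16 x 16 px
#' @param pixel_size um/px
#' @param gradient_sigma sigma of the derivative-of-Gaussian kernels, px
#' @param window_sigma sigma of the tensor-smoothing window, px
#' @return a [director_field()] with per-pixel theta and coherency
#' @export
structure_tensor_director <- function(image, pixel_size = 1.5,
                                      gradient_sigma = 1, window_sigma = 8) {
  stopifnot(is.matrix(image), nrow(image) >= 16, ncol(image) >= 16,
            gradient_sigma > 0, window_sigma > 0)
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  g <- gauss_kernel(gradient_sigma)
  dg <- dgauss_kernel(gradient_sigma)
  Ix <- conv_sep(image, g, dg)  # derivative along x (columns)
  Iy <- conv_sep(image, dg, g)  # derivative along y (rows)
  w <- gauss_kernel(window_sigma)
  Jxx <- conv_sep(Ix * Ix, w, w)
  Jyy <- conv_sep(Iy * Iy, w, w)
  Jxy <- conv_sep(Ix * Iy, w, w)
  tr <- Jxx + Jyy
  # largest-eigenvalue eigenvector of [[Jxx, Jxy], [Jxy, Jyy]] lies along
  # the mean gradient; the texture direction is perpendicular to it
  theta <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) + pi / 2
  coh <- ifelse(tr > .Machine$double.eps,
                sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / tr, 0)
  director_field(theta, pixel_size, pmin(pmax(coh, 0), 1))
}

#' Coarse-grain a director field by nematic block averaging
#'
#' Blocks of `block` x `block` pixels are averaged through the tensor
#' components (cos 2T, sin 2T) weighted by coherency; the block angle is
#' half the argument of the resultant, and the block coherency is the
#' resultant length (0 when orientations cancel, e.g. orthogonal halves).
#'
#' @param field a [director_field()]
#' @param block block size in px
#' @return a [director_field()] on the coarse grid; the `grid_x`/`grid_y`
#'   attributes give block-center px coordinates
#' @export
coarse_grain_director <- function(field, block) {
  stopifnot(inherits(field, "director_field"), block >= 1)
  th <- field$theta; w <- field$coherency
  if (all(w == 0)) w <- w + 1
  nr <- nrow(th) %/% block; nc <- ncol(th) %/% block
  stopifnot(nr >= 1, nc >= 1)
  bsum <- function(M) {
    M <- M[seq_len(nr * block), seq_len(nc * block), drop = FALSE]
    # sum within blocks: collapse rows then columns
    rowg <- rowsum(M, rep(seq_len(nr), each = block))
    t(rowsum(t(rowg), rep(seq_len(nc), each = block)))
  }
  sw <- bsum(w)
  c2 <- bsum(w * cos(2 * th)) / pmax(sw, .Machine$double.eps)
  s2 <- bsum(w * sin(2 * th)) / pmax(sw, .Machine$double.eps)
  theta_b <- wrap_nematic(0.5 * atan2(s2, c2))
  coh_b <- sqrt(c2^2 + s2^2)
  out <- director_field(theta_b, field$pixel_size * block, coh_b)
  attr(out, "grid_x") <- (seq_len(nc) - 0.5) * block - 0.5
  attr(out, "grid_y") <- (seq_len(nr) - 0.5) * block - 0.5
  out
}
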