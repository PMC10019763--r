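# Velocity fields by single-pass window cross-correlation PIV.
#
# Displacements per window come from the peak of the FFT cross-correlation
# of the mean-subtracted windows, refined by a 3-point Gaussian fit in each
# direction. Validity range is |d| < window/3 (documented single-pass
# limit). Outliers are flagged by the normalized median test against the
# 3x3 neighborhood.

# Pearson correlation of the overlapping parts of two windows under an
# integer displacement (dx, dy) of b relative to a
overlap_cor <- function(a, b, dx, dy) {
  n1 <- nrow(a); n2 <- ncol(a)
  ra <- max(1, 1 - dy):min(n1, n1 - dy)
  ca <- max(1, 1 - dx):min(n2, n2 - dx)
  if (length(ra) < 4 || length(ca) < 4) return(0)
  av <- a[ra, ca]; bv <- b[ra + dy, ca + dx]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  stats::cor(as.vector(av), as.vector(bv))
}

# cross-correlation peak with 3-point Gaussian subpixel fit; a and b are
# equal-size matrices (window contents)
xcorr_peak <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa == 0 || sb == 0) return(NULL)
  C <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  C <- C / (length(a) * sa * sb)
  n1 <- nrow(C); n2 <- ncol(C)
  pk <- which(C == max(C), arr.ind = TRUE)[1, ]
  # circular 3-point neighborhoods around the peak
  rm1 <- (pk[1] - 2) %% n1 + 1; rp1 <- pk[1] %% n1 + 1
  cm1 <- (pk[2] - 2) %% n2 + 1; cp1 <- pk[2] %% n2 + 1
  sub <- function(cm, c0, cp) {
    if (cm > 0 && cp > 0 && c0 > 0) {
      lm <- log(cm); l0 <- log(c0); lp <- log(cp)
      den <- lm + lp - 2 * l0
      if (den < 0) return(0.5 * (lm - lp) / den)
    }
    den <- cm + cp - 2 * c0
    if (den < 0) 0.5 * (cm - cp) / den else 0
  }
  dy <- unname(pk[1] - 1); dx <- unname(pk[2] - 1)
  if (dy > n1 / 2) dy <- dy - n1
  if (dx > n2 / 2) dx <- dx - n2
  # an exact integer match (overlap correlation 1) needs no refinement;
  # this keeps pure integer shifts exact
  if (overlap_cor(a, b, dx, dy) < 1 - 1e-9) {
    dy <- dy + sub(C[rm1, pk[2]], C[pk[1], pk[2]], C[rp1, pk[2]])
    dx <- dx + sub(C[pk[1], cm1], C[pk[1], pk[2]], C[pk[1], cp1])
  }
  c(dx = dx, dy = dy)
}

# normalized median test (threshold on the normalized residual against the
# 3x3 neighbor median); returns a logical matrix of outliers
nmt_outliers <- function(dx, dy, threshold = 2, eps = 0.1) {
  nr <- nrow(dx); nc <- ncol(dx)
  flag <- matrix(FALSE, nr, nc)
  for (comp in list(dx, dy)) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ii <- max(1, i - 1):min(nr, i + 1)
      jj <- max(1, j - 1):min(nc, j + 1)
      nbm <- comp[ii, jj, drop = FALSE]
      center <- (which(jj == j) - 1L) * nrow(nbm) + which(ii == i)
      nb <- nbm[-center]
      nb <- nb[is.finite(nb)]
      if (length(nb) < 3) next
      med <- stats::median(nb)
      res <- stats::median(abs(nb - med))
      if (is.finite(comp[i, j]) &&
          abs(comp[i, j] - med) / (res + eps) > threshold) {
        flag[i, j] <- TRUE
      }
    }
  }
  flag
}

#' PIV between one image pair
#'
#' @param imageA,imageB numeric matrices of equal shape
#' @param window interrogation window side in px (default 16)
#' @param overlap window overlap fraction in [0, 1) (default 0.5)
#' @param frame_interval h between the two images
#' @param pixel_size um/px
#' @param outlier_threshold normalized-median-test threshold (2 = standard)
#' @param replace_outliers replace flagged vectors by the neighbor median
#'   (they stay marked invalid)
#' @return a [velocity_field()]; flat (zero-variance) windows are masked
#' @export
piv_pair <- function(imageA, imageB, window = 16, overlap = 0.5,
                     frame_interval = 0.25, pixel_size = 1.5,
                     outlier_threshold = 2, replace_outliers = TRUE) {
  stopifnot(all(dim(imageA) == dim(imageB)), window >= 4,
            overlap >= 0, overlap < 1, frame_interval > 0, pixel_size > 0)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  nr <- nrow(imageA); nc <- ncol(imageA)
  r0 <- seq(1L, nr - window + 1L, by = step)
  c0 <- seq(1L, nc - window + 1L, by = step)
  if (length(r0) < 2 || length(c0) < 2) stop("fewer than 2 windows per side")
  dxm <- matrix(NA_real_, length(r0), length(c0))
  dym <- dxm
  for (i in seq_along(r0)) for (j in seq_along(c0)) {
    rows <- r0[i]:(r0[i] + window - 1L)
    cols <- c0[j]:(c0[j] + window - 1L)
    pk <- xcorr_peak(imageA[rows, cols], imageB[rows, cols])
    if (!is.null(pk)) { dxm[i, j] <- pk["dx"]; dym[i, j] <- pk["dy"] }
  }
  valid <- is.finite(dxm) & is.finite(dym)
  out <- nmt_outliers(dxm, dym, outlier_threshold)
  if (replace_outliers && any(out)) {
    fx <- dxm; fy <- dym
    fx[out] <- NA; fy[out] <- NA
    bad <- which(out, arr.ind = TRUE)
    for (b in seq_len(nrow(bad))) {
      i <- bad[b, 1]; j <- bad[b, 2]
      ii <- max(1, i - 1):min(nrow(dxm), i + 1)
      jj <- max(1, j - 1):min(ncol(dxm), j + 1)
      dxm[i, j] <- stats::median(fx[ii, jj], na.rm = TRUE)
      dym[i, j] <- stats::median(fy[ii, jj], na.rm = TRUE)
    }
  }
  valid <- valid & !out
  scale <- pixel_size / frame_interval
  velocity_field(
    vx = dxm * scale, vy = dym * scale,
    x = (c0 - 1) + (window - 1) / 2, y = (r0 - 1) + (window - 1) / 2,
    pixel_size = pixel_size, frame_interval = frame_interval, valid = valid
  )
}

#' PIV over a movie
#'
#' Applies [piv_pair()] to each pair of consecutive frames.
#'
#' @param stack list of matrices (frames), length >= 2
#' @param ... passed to [piv_pair()]
#' @param verbose log the masked-node fraction per pair
#' @return list of [velocity_field()], one per consecutive pair
#' @export
piv_movie <- function(stack, ..., verbose = FALSE) {
  if (!is.list(stack) || length(stack) < 2) {
    stop("need at least 2 frames")
  }
  out <- vector("list", length(stack) - 1)
  for (i in seq_len(length(stack) - 1)) {
    vf <- piv_pair(stack[[i]], stack[[i + 1]], ...)
    if (verbose) {
      message(sprintf("pair %d: %.1f%% masked", i,
                      100 * (1 - mean(vf$valid))))
    }
    out[[i]] <- vf
  }
  out
}
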