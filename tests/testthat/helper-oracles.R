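# Shared helpers: independent oracles and small constructors.

# circular integer shift of a matrix (whole image)
int_shift <- function(M, dx, dy) {
  nr <- nrow(M); nc <- ncol(M)
  M[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# exact subpixel shift via the Fourier shift theorem (even dims)
spec_shift <- function(M, dx, dy) {
  nr <- nrow(M); nc <- ncol(M)
  ky <- c(0:(nr / 2), -((nr / 2 - 1):1)) * 2 * pi / nr
  kx <- c(0:(nc / 2), -((nc / 2 - 1):1)) * 2 * pi / nc
  ph <- outer(ky, rep(1, nc)) * dy + outer(rep(1, nr), kx) * dx
  Re(stats::fft(stats::fft(M) * exp(-1i * ph), inverse = TRUE) / length(M))
}

# 90 deg counter-clockwise rotation of a matrix in the raster frame
# (x -> y, y -> -x): out[y', x'] with x' = y, y' = nc - 1 - x
rot90_raster <- function(M) {
  t(M)[ncol(M):1, , drop = FALSE]
}

# Ramanujan perimeter of an ellipse with semi-axes a, b
ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# greedy match of detections to truth within tol_um; returns per-truth row
# index into det (NA = missed)
match_detections <- function(det, truth, tol_um) {
  used <- rep(FALSE, nrow(det))
  out <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (nrow(det) == 0) break
    d <- sqrt((det$x_um - truth$x_um[i])^2 + (det$y_um - truth$y_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol_um) {
      out[i] <- j
      used[j] <- TRUE
    }
  }
  out
}

# absolute angular difference on the circle (degrees)
circ_err_deg <- function(a, b) {
  abs(((a - b + pi) %% (2 * pi)) - pi) * 180 / pi
}

# angular RMS between two defect patches over well-ordered nodes
patch_angle_rms_deg <- function(p1, p2, min_order = 0.2) {
  th1 <- 0.5 * atan2(p1$s2, p1$c2)
  th2 <- 0.5 * atan2(p2$s2, p2$c2)
  ord <- pmin(sqrt(p1$c2^2 + p1$s2^2), sqrt(p2$c2^2 + p2$s2^2))
  ok <- is.finite(th1) & is.finite(th2) & ord > min_order
  sqrt(mean(nematic_diff(th1[ok], th2[ok])^2)) * 180 / pi
}
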