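# Focal-adhesion segmentation and morphometrics.
#
# Segmentation follows the classic recipe: histogram equalization, one
# global threshold shared across all images of a comparison set (Otsu on
# the pooled equalized histogram), 8-connected components. Shape metrics:
# area from the pixel count, perimeter by a Cauchy-Crofton estimator over
# 4 line directions (a naive boundary-pixel count biases circularity above
# 1 for small discs), circularity = 4*pi*area/perimeter^2, orientation from
# second central moments (major axis, nematic, in [0, pi)).

# merge 4-connected labels that touch diagonally -> 8-connectivity
merge_diagonal <- function(lab) {
  mx <- max(lab)
  if (mx < 2) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), -ncol(lab)]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -ncol(lab)]), as.vector(lab[-nrow(lab), -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(mx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(mx), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment focal adhesions from one or several images
#'
#' All images of a comparison set are equalized and then thresholded at the
#' SAME absolute level (Otsu on their pooled equalized pixels, unless a
#' numeric threshold is given), so head/tail comparisons are not biased by
#' per-image thresholds. Connected components use 8-connectivity.
#'
#' Note: full histogram equalization makes the pooled histogram flat, so
#' the Otsu level on equalized images is close to a fixed percentile; for
#' synthetic panels whose absolute intensities are already calibrated,
#' segment with `equalize = FALSE` and let Otsu act on the bimodal raw
#' histogram.
#'
#' @param images a numeric matrix or a list of matrices
#' @param equalize histogram-equalize before thresholding (default TRUE,
#'   the right choice for microscopy images of varying exposure)
#' @param threshold "otsu" or a numeric level in (0, 1)
#' @return list of integer label matrices (attribute `threshold` gives the
#'   shared level); a single matrix input returns a one-element list
#' @export
segment_fas <- function(images, equalize = TRUE, threshold = "otsu") {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1)
  if (equalize) {
    images <- lapply(images, function(im) {
      if (stats::sd(im) == 0) return(im)
      as.matrix(EBImage::equalize(EBImage::Image(im), range = c(0, 1)))
    })
  }
  if (identical(threshold, "otsu")) {
    pooled <- unlist(lapply(images, as.vector))
    thr <- EBImage::otsu(EBImage::Image(matrix(pooled, ncol = 1)),
                         range = c(0, 1))
  } else {
    thr <- as.numeric(threshold)
  }
  labs <- lapply(images, function(im) {
    bw <- im > thr
    if (!any(bw)) return(matrix(0L, nrow(im), ncol(im)))
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    merge_diagonal(matrix(as.integer(lab), nrow(im), ncol(im)))
  })
  attr(labs, "threshold") <- thr
  labs
}

# Cauchy-Crofton perimeter of a binary mask (4 directions).
# L = (pi/8) * [T0 + T90 + (T45 + T135)/sqrt(2)] where Td is the number of
# fg/bg transitions along the family of digital lines in direction d
# (axis-aligned families spaced 1 px, diagonal families 1/sqrt(2) px).
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  t0 <- sum(m[, -1] != m[, -ncol(m)])            # along rows (x direction)
  t90 <- sum(m[-1, ] != m[-nrow(m), ])           # along columns
  t45 <- sum(m[-1, -1] != m[-nrow(m), -ncol(m)]) # diagonal \
  t135 <- sum(m[-nrow(m), -1] != m[-1, -ncol(m)]) # diagonal /
  (pi / 8) * (t0 + t90 + (t45 + t135) / sqrt(2))
}

#' Measure focal-adhesion shape metrics
#'
#' @param label_image integer label matrix from [segment_fas()]
#' @param pixel_size um/px
#' @param area_bounds_um2 open interval (lo, hi); objects with area exactly
#'   at a bound are excluded (default the (1, 7) um^2 gate)
#' @return data.frame with id, x_um, y_um, area_um2, perimeter_um,
#'   circularity, orientation_rad, n_px. Circularity of a digitized disc
#'   can exceed 1 by a small discretization excess (< ~0.05 at radius
#'   10 px, shrinking with size).
#' @export
fa_metrics <- function(label_image, pixel_size,
                       area_bounds_um2 = c(1, 7)) {
  ids <- setdiff(sort(unique(as.vector(label_image))), 0L)
  rows <- list()
  for (id in ids) {
    w <- which(label_image == id, arr.ind = TRUE)
    n_px <- nrow(w)
    area <- n_px * pixel_size^2
    # open interval: areas exactly at a bound are excluded (the relative
    # epsilon absorbs pixel_size^2 rounding at the boundary)
    if (!is.null(area_bounds_um2) &&
        (area <= area_bounds_um2[1] * (1 + 1e-12) ||
           area >= area_bounds_um2[2] * (1 - 1e-12))) next
    x <- w[, 2] - 1; y <- w[, 1] - 1
    # tight sub-mask for the perimeter estimator
    sub <- matrix(0L, diff(range(w[, 1])) + 1, diff(range(w[, 2])) + 1)
    sub[cbind(w[, 1] - min(w[, 1]) + 1, w[, 2] - min(w[, 2]) + 1)] <- 1L
    per <- crofton_perimeter(sub) * pixel_size
    mu20 <- if (n_px > 1) stats::var(x) * (n_px - 1) / n_px else 0
    mu02 <- if (n_px > 1) stats::var(y) * (n_px - 1) / n_px else 0
    mu11 <- if (n_px > 1) stats::cov(x, y) * (n_px - 1) / n_px else 0
    orient <- wrap_nematic(0.5 * atan2(2 * mu11, mu20 - mu02))
    rows[[length(rows) + 1]] <- data.frame(
      id = id, x_um = mean(x) * pixel_size, y_um = mean(y) * pixel_size,
      area_um2 = area, perimeter_um = per,
      circularity = 4 * pi * area / per^2,
      orientation_rad = orient, n_px = n_px
    )
  }
  if (length(rows) == 0) {
    return(data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      circularity = numeric(0), orientation_rad = numeric(0),
                      n_px = integer(0)))
  }
  do.call(rbind, rows)
}

#' Assign focal adhesions to the head or tail region of a defect
#'
#' In the defect frame (tail along +x) the half-plane x < 0 is the head
#' and x > 0 the tail; adhesions beyond `radius_limit_um` from the core are
#' labeled "other".
#'
#' @param fas data.frame from [fa_metrics()]
#' @param obs one-row +1/2 defect observation (x_um, y_um, axis_rad)
#' @param radius_limit_um maximum distance from the core
#' @return `fas` with added columns u_um, v_um (defect-frame coordinates),
#'   orientation_rel (relative to the axis, in (-pi/2, pi/2]) and region
#' @export
split_by_region <- function(fas, obs, radius_limit_um = 150) {
  psi <- obs$axis_rad
  dx <- fas$x_um - obs$x_um
  dy <- fas$y_um - obs$y_um
  fas$u_um <- cos(psi) * dx + sin(psi) * dy
  fas$v_um <- -sin(psi) * dx + cos(psi) * dy
  fas$orientation_rel <- nematic_diff(fas$orientation_rad, wrap_nematic(psi))
  r <- sqrt(fas$u_um^2 + fas$v_um^2)
  fas$region <- ifelse(r > radius_limit_um, "other",
                       ifelse(fas$u_um < 0, "head", "tail"))
  fas
}

#' Compare focal-adhesion morphometrics between head and tail
#'
#' Mean and SD of area and circularity per region, a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) p-value for the circularity difference
#' (circularity is bounded and non-Gaussian, so a rank test is used), and
#' nematic orientation histograms over [-90, 90) degrees relative to the
#' defect axis at 0.
#'
#' @param head,tail data.frames with `circularity`, optionally `area_um2`
#'   and `orientation_rel`, or bare numeric vectors of circularities
#' @param bin_deg orientation histogram bin width in degrees
#' @return list with `summary` (per-region stats), `p_value`, and
#'   `orientation_hist` (data.frame mid_deg, head, tail) when orientations
#'   are available
#' @export
compare_regions <- function(head, tail, bin_deg = 15) {
  as_df <- function(z) {
    if (is.data.frame(z)) z else data.frame(circularity = z)
  }
  head <- as_df(head); tail <- as_df(tail)
  stat <- function(df, region) {
    data.frame(
      region = region, n = nrow(df),
      area_mean = if (!is.null(df$area_um2)) mean(df$area_um2) else NA_real_,
      area_sd = if (!is.null(df$area_um2)) stats::sd(df$area_um2) else NA_real_,
      circ_mean = mean(df$circularity), circ_sd = stats::sd(df$circularity)
    )
  }
  p <- stats::wilcox.test(head$circularity, tail$circularity,
                          exact = FALSE)$p.value
  out <- list(summary = rbind(stat(head, "head"), stat(tail, "tail")),
              p_value = p)
  if (!is.null(head$orientation_rel) && !is.null(tail$orientation_rel)) {
    # bins centered on multiples of bin_deg so the defect axis (0 deg)
    # falls at a bin center, not an edge
    edges <- seq(-90 - bin_deg / 2, 90 - bin_deg / 2, by = bin_deg)
    hcount <- function(a_deg) {
      a <- ((a_deg + 90 + bin_deg / 2) %% 180) - 90 - bin_deg / 2
      tabulate(findInterval(a, edges, rightmost.closed = TRUE),
               nbins = length(edges) - 1)
    }
    out$orientation_hist <- data.frame(
      mid_deg = (edges[-1] + edges[-length(edges)]) / 2,
      head = hcount(head$orientation_rel * 180 / pi),
      tail = hcount(tail$orientation_rel * 180 / pi)
    )
  }
  out
}
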