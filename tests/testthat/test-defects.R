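# Order parameter, winding numbers, defect axes, detection.

px <- 1.5

test_that("order parameter honors its analytic contracts", {
  u <- director_field(matrix(0.7, 64, 64), px)
  q <- local_order_parameter(u, 27.8)
  expect_true(all(abs(q$q - 1) < 1e-12))

  # half/half orthogonal split: the odd window leaves a one-column
  # imbalance, so the interface value is exactly 1/w (0 in the continuum)
  w <- as.integer(2 * floor(27.8 / px / 2) + 1)
  n <- 4 * w
  th <- cbind(matrix(0, n, n / 2), matrix(pi / 2, n, n / 2))
  qf <- local_order_parameter(director_field(th, px), 27.8)
  mid <- qf$q[n / 2, n / 2 + 1] # window centered one px right of the split
  expect_equal(mid, 1 / w, tolerance = 1e-12)
  expect_lt(min(qf$q), 1 / w + 1e-12)

  expect_error(local_order_parameter(director_field(matrix(1, 8, 8), px),
                                     27.8), "larger")
})

test_that("order parameter of random angles scales as N^(-1/2)", {
  set.seed(31)
  n_draws <- 1000
  mean_q <- vapply(c(7L, 15L), function(w) {
    mean(vapply(seq_len(n_draws), function(i) {
      th <- matrix(stats::runif(w * w, 0, pi), w, w)
      q <- local_order_parameter(director_field(th, 1), w)
      q$q[(w + 1) / 2, (w + 1) / 2]
    }, numeric(1)))
  }, numeric(1))
  # ratio between window populations N = 49 and N = 225 must follow
  # sqrt(225/49) = 15/7
  expect_equal(mean_q[1] / mean_q[2], 15 / 7, tolerance = 0.2)
  # and the absolute level matches the random-walk prediction sqrt(pi)/2/sqrt(N)
  expect_equal(mean_q[2], sqrt(pi) / 2 / 15, tolerance = 0.2)
})

test_that("winding is zero in uniform regions and snaps near defects", {
  u <- director_field(matrix(1.1, 64, 64), px)
  expect_identical(as.numeric(winding_number(u, c(31, 31), 10)), 0)
  expect_error(winding_number(u, c(2, 2), 10), "exits")

  sc <- make_defect_director(
    data.frame(x_um = 140, y_um = 140, charge = 0.5, axis_angle = 2),
    shape = c(192L, 192L), pixel_size = px
  )
  for (r in c(5, 11, 25)) {
    expect_identical(as.numeric(winding_number(sc$director, c(140, 140) / px,
                                               r)), 0.5)
  }
})

test_that("defect axes are recovered and equivariant under rotation", {
  mk <- function(charge, axis) make_defect_director(
    data.frame(x_um = 140, y_um = 140, charge = charge, axis_angle = axis),
    shape = c(192L, 192L), pixel_size = px
  )
  core <- c(140, 140) / px
  # +1/2: tail direction, both estimators, rotated copies
  for (axis in c(0, 40 * pi / 180, 3.5)) {
    sc <- mk(0.5, axis)
    expect_lt(circ_err_deg(defect_axis(sc$director, core, 0.5), axis), 2)
    expect_lt(circ_err_deg(defect_axis(sc$director, core, 0.5,
                                       method = "divq"), axis), 2)
  }
  # -1/2: canonical axis in [0, 2pi/3), 120 deg symmetric
  tr <- mk(-0.5, 0.4)
  ax <- defect_axis(tr$director, core, -0.5)
  expect_equal(ax, 0.4, tolerance = 0.02)
  expect_equal(defect_axis(tr$director, core, -0.5, method = "divq"), ax,
               tolerance = 0.02)
  # requesting the same physical axis via a 120 deg-shifted label gives the
  # same canonical representative
  tr2 <- mk(-0.5, 0.4 + 2 * pi / 3)
  expect_equal(defect_axis(tr2$director, core, -0.5), ax, tolerance = 0.02)

  expect_error(defect_axis(tr$director, core, 1), "undefined")
})

test_that("detection recovers constructed defects and suppresses twins", {
  sc <- make_defect_director(
    data.frame(x_um = c(50, 150), y_um = c(50, 150),
               charge = c(0.5, -0.5), axis_angle = c(1, 0)),
    shape = c(160L, 160L), pixel_size = px
  )
  det <- detect_defects(local_order_parameter(sc$director, 27.8),
                        sc$director, verbose = FALSE)
  expect_equal(nrow(det), 2)
  m <- match_detections(det, sc$truth, 27.8 / 2)
  expect_false(anyNA(m))
  expect_equal(det$charge[m], sc$truth$charge)

  u <- director_field(matrix(0.2, 128, 128), px)
  expect_equal(nrow(detect_defects(local_order_parameter(u, 27.8), u,
                                   verbose = FALSE)), 0)

  # two +1/2 defects closer than min_separation: one detection, warning
  near <- make_defect_director(
    data.frame(x_um = c(105, 120), y_um = c(112, 112),
               charge = c(0.5, 0.5), axis_angle = c(0, 0)),
    shape = c(160L, 160L), pixel_size = px
  )
  expect_warning(
    dn <- detect_defects(local_order_parameter(near$director, 27.8),
                         near$director, min_separation_um = 27.8),
    "suppressed"
  )
  expect_equal(nrow(dn), 1)
})

test_that("detection is translation-equivariant on the pixel grid", {
  base <- data.frame(x_um = c(60, 150), y_um = c(75, 160),
                     charge = c(0.5, -0.5), axis_angle = c(0.7, 0.1))
  shift_px <- c(4, -6)
  shifted <- base
  shifted$x_um <- base$x_um + shift_px[1] * px
  shifted$y_um <- base$y_um + shift_px[2] * px
  d1 <- detect_defects(local_order_parameter(
    make_defect_director(base, shape = c(224L, 224L), pixel_size = px)$director,
    27.8
  ), make_defect_director(base, shape = c(224L, 224L), pixel_size = px)$director,
  verbose = FALSE)
  sc2 <- make_defect_director(shifted, shape = c(224L, 224L), pixel_size = px)
  d2 <- detect_defects(local_order_parameter(sc2$director, 27.8),
                       sc2$director, verbose = FALSE)
  o1 <- order(d1$x_um); o2 <- order(d2$x_um)
  expect_equal(d2$x_um[o2] - d1$x_um[o1], rep(shift_px[1] * px, 2),
               tolerance = 1e-6)
  expect_equal(d2$y_um[o2] - d1$y_um[o1], rep(shift_px[2] * px, 2),
               tolerance = 1e-6)
})

test_that("core order minimum is deeper than anywhere far from the core", {
  sc <- make_defect_director(
    data.frame(x_um = 140, y_um = 140, charge = 0.5, axis_angle = 1),
    shape = c(192L, 192L), pixel_size = px
  )
  od <- local_order_parameter(sc$director, 27.8)
  det <- detect_defects(od, sc$director, verbose = FALSE)
  X <- outer(rep(1, nrow(od$q)), seq_len(ncol(od$q)) - 1) * px
  Y <- outer(seq_len(nrow(od$q)) - 1, rep(1, ncol(od$q))) * px
  far <- sqrt((X - 140)^2 + (Y - 140)^2) > 27.8
  expect_lt(det$q_core, min(od$q[far]))
})
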