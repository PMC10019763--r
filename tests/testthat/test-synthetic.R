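# Ground-truth generators: director fields, textures, flows, tracks,
# focal-adhesion images, nuclei point sets.

px <- 1.5
shape <- c(192L, 192L)
ctr <- (rev(shape) - 1) / 2 * px

test_that("constructed defects carry the requested winding", {
  sc <- make_defect_director(
    data.frame(x_um = ctr[1], y_um = ctr[2], charge = 0.5, axis_angle = 0),
    shape = shape, pixel_size = px
  )
  k <- winding_number(sc$director, ctr / px, radius_px = 10)
  expect_true(attr(k, "valid"))
  expect_identical(as.numeric(k), 0.5)

  tr <- make_defect_director(
    data.frame(x_um = ctr[1], y_um = ctr[2], charge = -0.5, axis_angle = 0.3),
    shape = shape, pixel_size = px
  )
  expect_identical(as.numeric(winding_number(tr$director, ctr / px, 10)), -0.5)

  # charge additivity: a loop enclosing a +/-1/2 pair winds by zero
  pair <- make_defect_director(
    data.frame(x_um = ctr[1] + c(-30, 30), y_um = rep(ctr[2], 2),
               charge = c(0.5, -0.5), axis_angle = c(pi, 0)),
    shape = shape, pixel_size = px
  )
  expect_identical(as.numeric(winding_number(pair$director, ctr / px, 40)), 0)
})

test_that("empty defect list gives a uniform, perfectly ordered field", {
  sc <- make_defect_director(NULL, background_angle = 0.3,
                             shape = c(64L, 64L), pixel_size = px)
  expect_equal(unique(as.vector(sc$director$theta)), 0.3)
  q <- local_order_parameter(sc$director, 27.8)
  expect_true(all(abs(q$q - 1) < 1e-12))
})

test_that("generator rejects bad charges and degenerate configurations", {
  expect_error(make_defect_director(
    data.frame(x_um = 50, y_um = 50, charge = 0.3, axis_angle = 0),
    shape = shape, pixel_size = px
  ), "half-integer")
  expect_error(make_defect_director(
    data.frame(x_um = c(50, 51), y_um = c(50, 50.5),
               charge = c(0.5, -0.5), axis_angle = c(0, 0)),
    shape = shape, pixel_size = px
  ), "degenerate")
  expect_error(make_defect_director(
    data.frame(x_um = 1e5, y_um = 50, charge = 0.5, axis_angle = 0),
    shape = shape, pixel_size = px
  ), "inside")
})

test_that("total truth charge equals the boundary winding (conservation)", {
  for (s in 1:8) {
    sc <- random_defect_scene(2 + s %% 4, shape = c(224L, 224L),
                              pixel_size = px, seed = 400 + s)
    bw <- boundary_winding(sc$director, margin_px = 4)
    expect_true(attr(bw, "valid"))
    expect_equal(as.numeric(bw), sum(sc$truth$charge))
  }
})

test_that("texture rendering is deterministic and orientation-faithful", {
  u <- director_field(matrix(0, 128, 128), px)
  t1 <- render_texture(u, stripe_period = 8, seed = 5)
  t2 <- render_texture(u, stripe_period = 8, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, render_texture(u, stripe_period = 8, seed = 6)))

  est <- structure_tensor_director(t1, pixel_size = px)
  frac <- mean(abs(nematic_diff(est$theta, 0)) < 3 * pi / 180)
  expect_gte(frac, 0.95)
})

test_that("rotating the director by 90 deg rotates the texture", {
  # 90 deg sampling offsets are grid-exact, so with the base noise rotated
  # alongside the director the textures must agree node-for-node
  n <- 96
  u0 <- director_field(matrix(0, n, n), px)
  u90 <- director_field(matrix(pi / 2, n, n), px)
  noise <- matrix(stats::rnorm(n * n), n, n)
  t0 <- render_texture(u0, stripe_period = 8, seed = 1, noise = noise)
  t90 <- render_texture(u90, stripe_period = 8, seed = 1,
                        noise = rot90_raster(noise))
  inner <- 20:(n - 20)
  expect_lt(max(abs(rot90_raster(t0)[inner, inner] - t90[inner, inner])),
            1e-9)
})

test_that("motile contractile flow points tailward with antisymmetric vorticity", {
  # odd grid so the node lattice is symmetric about the core
  shape <- c(193L, 193L)
  fl <- make_defect_flow("motile_contractile", axis_angle = 0, v0 = 20,
                         decay_length = 60, shape = shape, pixel_size = px)
  ctr_px <- (rev(shape) - 1) / 2
  sv <- sample_velocity(fl, ctr_px[1], ctr_px[2])
  expect_gt(sv$vx, 0)           # core flow along the tail (+x)
  expect_equal(sv$vy, 0, tolerance = 1e-9)
  # vorticity antisymmetric about the axis: mirror negates it
  h <- diff(fl$y)[1] * fl$pixel_size
  om <- (fl$vy[, c(2:ncol(fl$vy), ncol(fl$vy))] -
           fl$vy[, c(1, 1:(ncol(fl$vy) - 1))]) / (2 * h) -
    (fl$vx[c(2:nrow(fl$vx), nrow(fl$vx)), ] -
       fl$vx[c(1, 1:(nrow(fl$vx) - 1)), ]) / (2 * h)
  om_in <- om[2:(nrow(om) - 1), 2:(ncol(om) - 1)]
  om_mir <- om[(nrow(om) - 1):2, 2:(ncol(om) - 1)]
  expect_lt(max(abs(om_in + om_mir)), 1e-9)
  expect_gt(max(abs(om_in)), 0)

  expect_error(make_defect_flow("whatever"), "arg")
})

test_that("stationary flow is zero on the tail half-plane, inward at the head", {
  fl <- make_defect_flow("stationary_asymmetric", axis_angle = 0, v0 = 20,
                         decay_length = 60, shape = shape, pixel_size = px)
  ctr_px <- (rev(shape) - 1) / 2
  X <- outer(rep(1, length(fl$y)), fl$x) * px
  tail_side <- X > ctr_px[1] * px
  expect_true(all(abs(fl$vx[tail_side]) < 1e-12))
  expect_true(all(abs(fl$vy[tail_side]) < 1e-12))
  # head-side speed follows v0*exp(-r/l) toward the core (tolerance covers
  # bilinear interpolation of the exponential between grid nodes)
  sv <- sample_velocity(fl, ctr_px[1] - 40, ctr_px[2])
  r <- 40 * px
  expect_equal(sv$vx, 20 * exp(-r / 60), tolerance = 0.01)
  expect_gt(sv$vx, 0)
})

test_that("synthetic tracks follow the specified kinematics", {
  st <- make_tracks(list(trajectory_spec(c(100, 100), c(0, 0),
                                         n_frames = 10, jitter_sd = 0)), 1)
  expect_equal(nrow(unique(st[, c("x_um", "y_um")])), 1)

  mv <- make_tracks(list(trajectory_spec(c(0, 0), c(20, 0),
                                         frame_interval = 0.25,
                                         n_frames = 10, jitter_sd = 0)), 1)
  expect_equal(unique(diff(mv$x_um)), 5) # 20 um/h * 0.25 h

  # Monte-Carlo speed recovery with jitter
  sp <- vapply(1:60, function(s) {
    tr <- make_tracks(list(trajectory_spec(c(0, 0), c(20, 0),
                                           frame_interval = 0.25,
                                           n_frames = 20, jitter_sd = 1)), s)
    track_speed(tr, frame_interval = 0.25, smoothing_window = 5)
  }, numeric(1))
  expect_lt(abs(mean(sp) - 20) / 20, 0.15)
  expect_identical(make_tracks(list(trajectory_spec(c(0, 0), c(1, 1))), 3),
                   make_tracks(list(trajectory_spec(c(0, 0), c(1, 1))), 3))
})

test_that("focal-adhesion images reproduce requested blob geometry", {
  blobs <- data.frame(x_um = c(6, 19), y_um = c(6, 19),
                      area_um2 = c(3, 3), aspect = c(1, 4),
                      orientation = c(0, 30 * pi / 180))
  img <- make_fa_image(blobs, shape = c(256L, 256L), pixel_size = 0.1,
                       seed = 2)
  fas <- fa_metrics(segment_fas(img, equalize = FALSE)[[1]], 0.1,
                    area_bounds_um2 = NULL)
  expect_equal(nrow(fas), 2)
  expect_lt(max(abs(fas$area_um2 - 3) / 3), 0.1)
  ell <- fas[which.min(fas$circularity), ]
  expect_lt(abs(ell$orientation_rad - 30 * pi / 180) * 180 / pi, 5)

  blank <- make_fa_image(blobs[0, ], shape = c(128L, 128L), pixel_size = 0.1,
                         background_noise_sd = 0.02, seed = 3)
  labs <- segment_fas(blank, equalize = FALSE, threshold = 0.5)
  expect_equal(max(labs[[1]]), 0)
})

test_that("nuclei generator reproduces base density and hotspot excess", {
  pts <- make_nuclei_points(1000, field_um = c(1000, 1000), seed = 11)
  expect_equal(nrow(pts) / 1, 1000, tolerance = 0.1) # 1 mm^2 field
  dm <- density_map(pts, c(1000, 1000), window_um = 200, step_um = 100)
  expect_lt(stats::sd(dm$density) / mean(dm$density), 0.25) # flat field

  # hotspot fold recovery, averaged over seeds
  folds <- vapply(1:10, function(s) {
    p <- make_nuclei_points(2000, field_um = c(800, 800),
                            hotspot = list(center = c(400, 400),
                                           radius_um = 150, fold_excess = 2),
                            seed = 100 + s)
    r <- sqrt((p$x_um - 400)^2 + (p$y_um - 400)^2)
    inside <- sum(r <= 150) / (pi * 150^2 / 1e6)
    outside <- sum(r > 150) / ((800 * 800 - pi * 150^2) / 1e6)
    inside / outside
  }, numeric(1))
  expect_equal(mean(folds), 2, tolerance = 0.1)

  expect_equal(nrow(make_nuclei_points(1000, field_um = c(0, 0), seed = 1)), 0)
})
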