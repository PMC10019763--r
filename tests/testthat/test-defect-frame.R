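# Registration into the defect frame, ensemble averaging, profiles,
# contractility, density accumulation.

px <- 1.5
shp <- c(192L, 192L)
ctr <- (rev(shp) - 1) / 2 * px

mk_scene <- function(axis, kind = "motile_contractile", v0 = 20) {
  list(
    director = make_defect_director(
      data.frame(x_um = ctr[1], y_um = ctr[2], charge = 0.5,
                 axis_angle = axis),
      shape = shp, pixel_size = px
    )$director,
    flow = make_defect_flow(kind, axis, v0 = v0, decay_length = 60,
                            shape = shp, pixel_size = px),
    obs = data.frame(x_um = ctr[1], y_um = ctr[2], charge = 0.5,
                     axis_rad = axis)
  )
}

test_that("a canonical comet registers as an identity crop", {
  s <- mk_scene(0)
  p <- register_observation(s$director, s$flow, s$obs, half_size_um = 90,
                            step_um = 6)
  # director angle at patch nodes equals the field angle at those nodes
  i0 <- which(p$v == 0); j_tail <- which(p$u > 10)
  th <- 0.5 * atan2(p$s2, p$c2)
  expect_lt(max(abs(nematic_diff(th[i0, j_tail], 0))), 1e-6) # tail ray at 0
  # core velocity = v0 up to bilinear interpolation of the peaked profile
  expect_equal(p$vx[i0, which(p$u == 0)], 20, tolerance = 0.05)
  expect_error(register_observation(s$director, s$flow,
                                    transform(s$obs, charge = -0.5), 90, 6),
               "\\+1/2")
})

test_that("registration undoes a global rotation of the scene", {
  p0 <- with(mk_scene(0), register_observation(director, flow, obs, 90, 6))
  for (axis in c(70 * pi / 180, 2.8)) {
    pr <- with(mk_scene(axis),
               register_observation(director, flow, obs, 90, 6))
    expect_lt(patch_angle_rms_deg(p0, pr), 3)
    ok <- is.finite(p0$vx) & is.finite(pr$vx)
    vrms <- sqrt(mean((p0$vx[ok] - pr$vx[ok])^2 +
                        (p0$vy[ok] - pr$vy[ok])^2))
    expect_lt(vrms / 20, 0.10)
  }
})

test_that("cores near the border register with masked out-of-field nodes", {
  s <- mk_scene(0)
  corner_obs <- data.frame(x_um = 15, y_um = 15, charge = 0.5, axis_rad = 0)
  p <- register_observation(s$director, s$flow, corner_obs, 90, 6)
  expect_gt(mean(!is.finite(p$c2)), 0.25) # at least a quadrant masked
})

test_that("averaging identities: identical patches, opposite velocities", {
  s <- mk_scene(0)
  p <- register_observation(s$director, s$flow, s$obs, 90, 6)
  avg <- average_frames(list(p, p, p))
  expect_equal(avg$vx, p$vx, tolerance = 1e-12)
  th_p <- wrap_nematic(0.5 * atan2(p$s2, p$c2))
  ok <- is.finite(th_p) & avg$order > 0.2
  expect_lt(max(abs(nematic_diff(avg$theta[ok], th_p[ok]))), 1e-9)

  flip <- p
  flip$vx <- -p$vx; flip$vy <- -p$vy
  avg2 <- average_frames(list(p, flip))
  expect_lt(max(abs(avg2$vx), na.rm = TRUE), 1e-12)
})

test_that("noisy ensembles converge to the truth as 1/sqrt(n)", {
  s <- mk_scene(0)
  clean <- register_observation(s$director, NULL, s$obs, 90, 6)
  th_true <- 0.5 * atan2(clean$s2, clean$c2)
  set.seed(42)
  noisy_patch <- function() {
    p <- clean
    n <- stats::rnorm(length(p$c2), sd = 10 * pi / 180)
    th <- 0.5 * atan2(p$s2, p$c2) + matrix(n, nrow(p$c2))
    p$c2 <- cos(2 * th); p$s2 <- sin(2 * th)
    p
  }
  avg <- average_frames(replicate(50, noisy_patch(), simplify = FALSE))
  ok <- is.finite(th_true) & avg$order > 0.2
  expect_lt(sqrt(mean(nematic_diff(avg$theta[ok], th_true[ok])^2)) *
              180 / pi, 3)
})

test_that("axial profiles read the flow structure along the axis", {
  s <- mk_scene(0, kind = "stationary_asymmetric", v0 = 20)
  p <- register_observation(NULL, s$flow, s$obs, 90, 6)
  prof <- axial_profile(average_frames(list(p)), band_halfwidth_um = 30)
  expect_true(all(abs(prof$v_axial_umh[prof$x_um > 6]) < 1e-9))
  expect_gt(max(prof$v_axial_umh[prof$x_um < -6]), 5)

  # uniform flow: flat profile at the imposed value
  uni <- s$flow
  uni$vx[] <- 7; uni$vy[] <- 0
  pu <- register_observation(NULL, uni, s$obs, 90, 6)
  profu <- axial_profile(average_frames(list(pu)), 30)
  expect_true(all(abs(profu$v_axial_umh - 7) < 1e-9))

  expect_error(axial_profile(average_frames(list(p)), 0), "positive")
})

test_that("contractility sign discriminates the three flow cases", {
  s <- mk_scene(1.1)
  p <- register_observation(NULL, s$flow, s$obs, 90, 6)
  fm <- average_frames(list(p))
  cs <- contractility_sign(fm)
  expect_equal(as.character(cs), "contractile")
  expect_gt(attr(cs, "vorticity_antisymmetry"), 0.95)

  rev_fm <- fm
  rev_fm$vx <- -fm$vx; rev_fm$vy <- -fm$vy
  expect_equal(as.character(contractility_sign(rev_fm)), "extensile")

  zero <- fm
  zero$vx[] <- 0; zero$vy[] <- 0
  expect_equal(as.character(contractility_sign(zero)), "indeterminate")
})

test_that("randomized ensemble recovers the core flow within 10%", {
  set.seed(9)
  patches <- lapply(seq_len(100), function(i) {
    axis <- stats::runif(1, 0, 2 * pi)
    s <- mk_scene(axis)
    obs <- s$obs
    obs$axis_rad <- axis + stats::rnorm(1, sd = 5 * pi / 180)
    register_observation(NULL, s$flow, obs, 90, 6)
  })
  avg <- average_frames(patches)
  cs <- contractility_sign(avg, core_radius_um = 30)
  expect_equal(as.character(cs), "contractile")
  # fixture calibration: disc mean of v0 * exp(-r / l) on the same grid
  U <- matrix(rep(avg$u, each = length(avg$v)), length(avg$v), length(avg$u))
  V <- matrix(rep(avg$v, times = length(avg$u)), length(avg$v), length(avg$u))
  core <- U^2 + V^2 <= 30^2
  expected <- mean(20 * exp(-sqrt(U^2 + V^2)[core] / 60))
  expect_lt(abs(attr(cs, "core_axial_umh") - expected) / expected, 0.10)
})

test_that("head density accumulation is recovered from nuclei points", {
  set.seed(3)
  folds <- vapply(1:8, function(s) {
    pts <- make_nuclei_points(
      3000, field_um = c(400, 400),
      hotspot = list(center = c(150, 200), radius_um = 45, fold_excess = 2),
      seed = 50 + s
    )
    obs <- data.frame(x_um = 200, y_um = 200, charge = 0.5, axis_rad = 0)
    prof <- head_density_profile(pts, obs, half_size_um = 120,
                                 band_halfwidth_um = 40, bin_um = 40)
    head_bin <- prof$density_mm2[prof$x_um < 0 & prof$x_um > -80]
    tail_bin <- prof$density_mm2[prof$x_um > 0 & prof$x_um < 80]
    mean(head_bin) / mean(tail_bin)
  }, numeric(1))
  expect_equal(mean(folds), 2, tolerance = 0.2)

  empty <- density_map(data.frame(x_um = numeric(0), y_um = numeric(0)),
                       c(200, 200), window_um = 50)
  expect_true(all(empty$density == 0))
})
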