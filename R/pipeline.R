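# Configuration, scene I/O and the end-to-end pipeline.
#
# All output tables are CSV with coordinates in um, raster convention
# (origin at the top-left pixel center, y down); frames are 0-based.

#' Analysis configuration
#'
#' Bundles and validates every tunable the pipeline uses. Defaults follow
#' standard practice for confluent monolayers imaged at ~1.9 um/px:
#' order-parameter window 27.8 um, PIV window 16 px with 50% overlap,
#' stationary/motile speed threshold 10 um/h, focal-adhesion area gate
#' (1, 7) um^2.
#'
#' @param pixel_size um/px (required; never guessed from data)
#' @param frame_interval h between frames (required)
#' @param omega_um order-parameter window, um
#' @param piv_window px
#' @param piv_overlap fraction in [0, 1)
#' @param q_threshold detection threshold on Q_local
#' @param min_separation_um NULL = omega_um
#' @param stationary_threshold um/h
#' @param max_disp_um track-linking gate per frame, um
#' @param fa_area_bounds um^2, open interval
#' @param patch_half_size_um defect-frame patch half-size
#' @param patch_step_um defect-frame grid spacing
#' @param band_halfwidth_um axial-profile band half-width
#' @param seed integer seed for any synthesis step
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(pixel_size, frame_interval, omega_um = 27.8,
                            piv_window = 16, piv_overlap = 0.5,
                            q_threshold = 0.5, min_separation_um = NULL,
                            stationary_threshold = 10, max_disp_um = 15,
                            fa_area_bounds = c(1, 7),
                            patch_half_size_um = 150, patch_step_um = 10,
                            band_halfwidth_um = 30, seed = 1L) {
  if (missing(pixel_size) || !is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size (um/px) is required and must be positive")
  }
  if (missing(frame_interval) || !is.numeric(frame_interval) ||
      frame_interval <= 0) {
    stop("frame_interval (h) is required and must be positive")
  }
  stopifnot(omega_um > 0, piv_window >= 4, piv_overlap >= 0, piv_overlap < 1,
            q_threshold > 0, q_threshold < 1, stationary_threshold > 0,
            max_disp_um > 0, length(fa_area_bounds) == 2,
            fa_area_bounds[1] >= 0, diff(fa_area_bounds) > 0)
  if (is.null(min_separation_um)) min_separation_um <- omega_um
  structure(
    list(pixel_size = pixel_size, frame_interval = frame_interval,
         omega_um = omega_um, piv_window = piv_window,
         piv_overlap = piv_overlap, q_threshold = q_threshold,
         min_separation_um = min_separation_um,
         stationary_threshold = stationary_threshold,
         max_disp_um = max_disp_um, fa_area_bounds = fa_area_bounds,
         patch_half_size_um = patch_half_size_um,
         patch_step_um = patch_step_um,
         band_halfwidth_um = band_halfwidth_um, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Write a configuration as a flat key=value text file
#' @param config an [analysis_config()]
#' @param path output file
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(format(config[[k]], digits = 17), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#' @param path file path
#' @return an [analysis_config()] (round-trips losslessly)
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(strsplit(p[2], ",")[[1]])),
    vapply(kv, `[[`, "", 1)
  )
  do.call(analysis_config, vals)
}

#' Read a (multi-page) TIFF stack as a list of matrices
#' @param path TIFF file
#' @return list of numeric matrices
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e) {
                       stop("could not read TIFF '", path, "': ",
                            conditionMessage(e))
                     })
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    f
  })
}

#' Write a list of matrices as a float multi-page TIFF
#' @param frames list of numeric matrices
#' @param path output file
#' @export
write_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  rng <- range(unlist(lapply(frames, range)))
  # store as 32-bit float in [0, 1]
  frames <- lapply(frames, function(f) {
    if (diff(rng) > 0) (f - rng[1]) / diff(rng) else f * 0
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32)
  invisible(path)
}

#' Run the full analysis pipeline on an image stack
#'
#' Stages in order: director estimation (structure tensor), PIV,
#' order-parameter defect detection per frame, track linking and motility
#' classification, and defect-frame averaging over all +1/2 observations.
#' Every table is written as CSV together with a config snapshot; the run
#' is deterministic (no randomness), so outputs are byte-identical across
#' re-runs with the same inputs and config.
#'
#' @param stack list of image matrices, or a TIFF path
#' @param config an [analysis_config()]
#' @param out_dir output directory (created if needed)
#' @param fov_area_mm2 optional field-of-view area for the density series
#'   (computed from the image size if NULL)
#' @return invisibly, a list with the in-memory results (`defects`,
#'   `tracks`, `track_summary`, `density`, `frame_mean`, `profile`)
#' @export
run_pipeline <- function(stack, config, out_dir,
                         fov_area_mm2 = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(is.list(stack), length(stack) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  px <- config$pixel_size
  if (is.null(fov_area_mm2)) {
    fov_area_mm2 <- prod(dim(stack[[1]]) - 1) * px^2 / 1e6
  }

  log_lines <- c(sprintf("frames: %d", length(stack)),
                 sprintf("image: %d x %d px", nrow(stack[[1]]),
                         ncol(stack[[1]])))

  directors <- lapply(stack, structure_tensor_director, pixel_size = px)
  coh <- vapply(directors, function(d) mean(d$coherency), numeric(1))
  utils::write.csv(
    data.frame(frame = seq_along(stack) - 1L, mean_coherency = coh),
    file.path(out_dir, "coherency.csv"), row.names = FALSE
  )

  flows <- NULL
  if (length(stack) >= 2) {
    flows <- piv_movie(stack, window = config$piv_window,
                       overlap = config$piv_overlap,
                       frame_interval = config$frame_interval,
                       pixel_size = px)
    piv_rows <- lapply(seq_along(flows), function(i) {
      vf <- flows[[i]]
      data.frame(
        pair = i - 1L,
        x_px = rep(vf$x, each = length(vf$y)), y_px = rep(vf$y, length(vf$x)),
        vx_umh = as.vector(vf$vx), vy_umh = as.vector(vf$vy),
        valid = as.vector(vf$valid)
      )
    })
    utils::write.csv(do.call(rbind, piv_rows),
                     file.path(out_dir, "velocity.csv"), row.names = FALSE)
    log_lines <- c(log_lines, sprintf("piv pairs: %d", length(flows)))
  }

  defects <- do.call(rbind, lapply(seq_along(directors), function(i) {
    od <- local_order_parameter(directors[[i]], config$omega_um)
    detect_defects(od, directors[[i]], q_threshold = config$q_threshold,
                   min_separation_um = config$min_separation_um,
                   frame = i - 1L, verbose = FALSE)
  }))
  utils::write.csv(defects, file.path(out_dir, "defects.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines, sprintf("defect observations: %d", nrow(defects)))

  linked <- link_tracks(defects, config$max_disp_um)
  summary <- summarize_tracks(linked, config$frame_interval,
                              stationary_threshold = config$stationary_threshold)
  utils::write.csv(linked, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(out_dir, "track_summary.csv"),
                   row.names = FALSE)

  density <- defect_density_timeseries(defects, fov_area_mm2,
                                       charge_filter = 0.5)
  utils::write.csv(density, file.path(out_dir, "defect_density.csv"),
                   row.names = FALSE)

  frame_mean <- NULL; profile <- NULL
  plus <- defects[defects$charge == 0.5 & is.finite(defects$axis_rad), ]
  if (nrow(plus) > 0) {
    patches <- lapply(seq_len(nrow(plus)), function(i) {
      fr <- plus$frame[i]
      vel <- if (!is.null(flows) && fr + 1 <= length(flows)) flows[[fr + 1]]
      else if (!is.null(flows)) flows[[length(flows)]] else NULL
      register_observation(directors[[fr + 1]], vel, plus[i, ],
                           half_size_um = config$patch_half_size_um,
                           step_um = config$patch_step_um)
    })
    frame_mean <- average_frames(patches)
    md <- data.frame(
      u_um = rep(frame_mean$u, each = length(frame_mean$v)),
      v_um = rep(frame_mean$v, length(frame_mean$u)),
      theta = as.vector(frame_mean$theta),
      order = as.vector(frame_mean$order),
      vx_umh = if (!is.null(frame_mean$vx)) as.vector(frame_mean$vx) else NA,
      vy_umh = if (!is.null(frame_mean$vy)) as.vector(frame_mean$vy) else NA,
      n = as.vector(frame_mean$n)
    )
    utils::write.csv(md, file.path(out_dir, "defect_frame_mean.csv"),
                     row.names = FALSE)
    if (!is.null(frame_mean$vx)) {
      profile <- axial_profile(frame_mean, config$band_halfwidth_um)
      utils::write.csv(profile, file.path(out_dir, "axial_profile.csv"),
                       row.names = FALSE)
    }
  }

  write_config(config, file.path(out_dir, "config.txt"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(defects = defects, tracks = linked,
                 track_summary = summary, density = density,
                 frame_mean = frame_mean, profile = profile))
}

#' Write the canonical synthetic fixture set
#'
#' Generates the scenes the tests and the worked examples use: a +1/2 comet
#' and a -1/2 trefoil (texture TIFF + truth CSV), a +/-1/2 pair, a movie of
#' a stationary defect whose head-side texture advects toward the core, a
#' focal-adhesion panel, and a nuclei point set with a head hotspot. A JSON
#' sidecar records parameters and the seed.
#'
#' @param out_dir output directory
#' @param seed integer seed
#' @param pixel_size um/px
#' @return invisibly, the parameter list
#' @export
make_synthetic_suite <- function(out_dir, seed = 1, pixel_size = 1.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  shape <- c(192L, 192L)
  ctr <- (rev(shape) - 1) / 2 * pixel_size
  params <- list(seed = seed, pixel_size = pixel_size, shape = shape,
                 stripe_period = 8, n_frames = 5, frame_interval = 0.25,
                 v0 = 20, decay_length = 60)

  write_scene <- function(name, defects) {
    sc <- make_defect_director(defects, shape = shape,
                               pixel_size = pixel_size)
    tex <- render_texture(sc$director, stripe_period = params$stripe_period,
                          noise_sd = 0.05, seed = seed)
    write_stack(tex, file.path(out_dir, paste0(name, ".tif")))
    truth <- sc$truth
    truth$frame <- 0L
    utils::write.csv(truth, file.path(out_dir, paste0(name, "_truth.csv")),
                     row.names = FALSE)
    sc
  }
  comet <- write_scene("comet", data.frame(
    x_um = ctr[1], y_um = ctr[2], charge = 0.5, axis_angle = 0
  ))
  write_scene("trefoil", data.frame(
    x_um = ctr[1], y_um = ctr[2], charge = -0.5, axis_angle = 0
  ))
  write_scene("pair", data.frame(
    x_um = ctr[1] + c(-60, 60), y_um = ctr[2] + c(0, 0),
    charge = c(0.5, -0.5), axis_angle = c(pi, 0)
  ))

  # stationary-defect movie: texture advected by the head-only flow
  flow <- make_defect_flow("stationary_asymmetric", axis_angle = 0,
                           v0 = params$v0, decay_length = params$decay_length,
                           shape = shape, pixel_size = pixel_size,
                           grid_step_px = 4,
                           frame_interval = params$frame_interval)
  tex0 <- render_texture(comet$director, stripe_period = params$stripe_period,
                         noise_sd = 0, seed = seed + 1)
  frames <- vector("list", params$n_frames)
  frames[[1]] <- tex0
  X <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1], shape[2])
  Y <- matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), shape[1], shape[2])
  sv <- sample_velocity(flow, X, Y)
  dxp <- matrix(sv$vx, shape[1], shape[2]) * params$frame_interval / pixel_size
  dyp <- matrix(sv$vy, shape[1], shape[2]) * params$frame_interval / pixel_size
  dxp[is.na(dxp)] <- 0; dyp[is.na(dyp)] <- 0
  for (i in 2:params$n_frames) {
    frames[[i]] <- matrix(
      sample_bilinear_clamp(frames[[i - 1]], X - dxp, Y - dyp),
      shape[1], shape[2]
    )
  }
  write_stack(frames, file.path(out_dir, "stationary_movie.tif"))

  # focal-adhesion panel: elongated axis-aligned blobs on the tail side
  # (x > center), rounder randomly oriented ones on the head side; one
  # blob per cell of a jittered grid so neighbors never merge
  blobs <- with_seed(seed + 2, {
    gx <- seq(4, 47, by = 7.2); gy <- seq(4, 47, by = 7.2)
    pos <- expand.grid(x_um = gx, y_um = gy)
    n <- nrow(pos)
    pos$x_um <- pos$x_um + stats::runif(n, -1.2, 1.2)
    pos$y_um <- pos$y_um + stats::runif(n, -1.2, 1.2)
    side <- ifelse(pos$x_um > 25.6, 1, -1) # tail = +x half
    data.frame(
      x_um = pos$x_um, y_um = pos$y_um,
      area_um2 = stats::runif(n, 1.5, 6),
      aspect = ifelse(side > 0, stats::runif(n, 2.5, 4),
                      stats::runif(n, 1, 1.6)),
      orientation = ifelse(side > 0, stats::rnorm(n, 0, 0.2),
                           stats::runif(n, 0, pi))
    )
  })
  fa_img <- make_fa_image(blobs, shape = c(512L, 512L), pixel_size = 0.1,
                          seed = seed + 3)
  write_stack(fa_img, file.path(out_dir, "fa_panel.tif"))
  utils::write.csv(blobs, file.path(out_dir, "fa_truth.csv"),
                   row.names = FALSE)

  nuc <- make_nuclei_points(1000, field_um = c(400, 400),
                            hotspot = list(center = c(150, 200),
                                           radius_um = 60, fold_excess = 2),
                            seed = seed + 4)
  utils::write.csv(nuc, file.path(out_dir, "nuclei.csv"), row.names = FALSE)

  jsonlite::write_json(params, file.path(out_dir, "scene_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(params)
}
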