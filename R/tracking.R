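# Linking defect observations into tracks; speed and motility statistics.

#' Link per-frame defect observations into tracks
#'
#' Greedy mutual-nearest-neighbor linking between consecutive frames,
#' restricted to equal charge and displacement <= `max_disp_um`. Unlinked
#' observations start new tracks; there is no gap closing — a missed frame
#' terminates the track. Linking is invariant to the order of observations
#' within a frame.
#'
#' @param obs data.frame with columns frame, x_um, y_um, charge (other
#'   columns are carried through)
#' @param max_disp_um maximum displacement per frame in um
#' @return the input with an added integer `track_id` column, sorted by
#'   track and frame
#' @export
link_tracks <- function(obs, max_disp_um) {
  stopifnot(is.data.frame(obs), max_disp_um > 0)
  if (nrow(obs) == 0) {
    obs$track_id <- integer(0)
    return(obs)
  }
  # canonical in-frame order makes the result permutation-invariant
  obs <- obs[order(obs$frame, obs$x_um, obs$y_um), , drop = FALSE]
  obs$track_id <- NA_integer_
  frames <- sort(unique(obs$frame))
  next_id <- 1L
  first <- which(obs$frame == frames[1])
  obs$track_id[first] <- seq_len(length(first))
  next_id <- length(first) + 1L
  for (fi in seq_along(frames)[-1]) {
    consecutive <- (frames[fi] - frames[fi - 1]) == 1 # no gap closing
    a <- if (consecutive) which(obs$frame == frames[fi - 1]) else integer(0)
    b <- which(obs$frame == frames[fi])
    if (length(a) > 0 && length(b) > 0) {
      D <- outer(seq_along(a), seq_along(b), function(i, j) {
        sqrt((obs$x_um[a[i]] - obs$x_um[b[j]])^2 +
               (obs$y_um[a[i]] - obs$y_um[b[j]])^2)
      })
      same <- outer(obs$charge[a], obs$charge[b], "==")
      D[!same | D > max_disp_um] <- Inf
      if (any(is.finite(D))) {
        # mutual nearest neighbors
        for (i in seq_along(a)) {
          j <- which.min(D[i, ])
          if (is.finite(D[i, j]) && which.min(D[, j]) == i) {
            obs$track_id[b[j]] <- obs$track_id[a[i]]
          }
        }
      }
    }
    new <- b[is.na(obs$track_id[b])]
    if (length(new) > 0) {
      obs$track_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
  }
  obs[order(obs$track_id, obs$frame), , drop = FALSE]
}

#' Mean speed of one track
#'
#' Positions are optionally smoothed by a centered box of
#' `smoothing_window` frames (applied only where the full window fits, so
#' noise-free linear tracks are unchanged); the speed is the mean of
#' |delta position| / delta t over consecutive retained observations.
#'
#' @param track data.frame with frame, x_um, y_um (one track, frames
#'   strictly increasing)
#' @param frame_interval h per frame step
#' @param smoothing_window odd box width in frames (1 = none, default 5)
#' @return speed in um/h (NA for tracks with < 2 observations)
#' @export
track_speed <- function(track, frame_interval, smoothing_window = 5) {
  stopifnot(smoothing_window >= 1, smoothing_window %% 2 == 1)
  n <- nrow(track)
  if (n < 2) return(NA_real_)
  track <- track[order(track$frame), ]
  x <- track$x_um; y <- track$y_um; f <- track$frame
  if (smoothing_window > 1 && n >= smoothing_window + 1) {
    h <- (smoothing_window - 1) / 2
    ix <- (1 + h):(n - h)
    sm <- function(v) vapply(ix, function(i) mean(v[(i - h):(i + h)]), 1)
    x <- sm(x); y <- sm(y); f <- f[ix]
  }
  d <- sqrt(diff(x)^2 + diff(y)^2)
  dt <- diff(f) * frame_interval
  mean(d / dt)
}

#' Classify a track as stationary or motile
#'
#' Stationary if the mean speed is below `stationary_threshold`
#' (default 10 um/h), motile otherwise; tracks observed for less than
#' `min_duration_h` are unclassified.
#'
#' @param track one track data.frame (frame, x_um, y_um)
#' @param frame_interval h
#' @param stationary_threshold um/h
#' @param min_duration_h minimum observed duration for classification
#' @param smoothing_window passed to [track_speed()]
#' @return one of "stationary", "motile", "unclassified"
#' @export
classify_motility <- function(track, frame_interval,
                              stationary_threshold = 10,
                              min_duration_h = 2, smoothing_window = 5) {
  n <- nrow(track)
  if (n < 2) return("unclassified")
  dur <- (max(track$frame) - min(track$frame)) * frame_interval
  if (dur < min_duration_h) return("unclassified")
  sp <- track_speed(track, frame_interval, smoothing_window)
  if (!is.finite(sp)) return("unclassified")
  if (sp < stationary_threshold) "stationary" else "motile"
}

#' Summarize linked tracks
#'
#' @param linked output of [link_tracks()]
#' @param frame_interval h
#' @param ... passed to [classify_motility()]
#' @return data.frame with track_id, charge, n_obs, duration_h, speed_umh,
#'   class
#' @export
summarize_tracks <- function(linked, frame_interval, ...) {
  ids <- sort(unique(linked$track_id))
  rows <- lapply(ids, function(id) {
    tr <- linked[linked$track_id == id, ]
    data.frame(
      track_id = id, charge = tr$charge[1], n_obs = nrow(tr),
      duration_h = (max(tr$frame) - min(tr$frame)) * frame_interval,
      speed_umh = track_speed(tr, frame_interval),
      class = classify_motility(tr, frame_interval, ...)
    )
  })
  do.call(rbind, rows)
}

#' Defect surface density over time
#'
#' @param obs observation data.frame (frame, charge)
#' @param fov_area_mm2 field of view area in mm^2
#' @param charge_filter NULL (all) or a charge value to count
#' @return data.frame with frame, n, density_mm2
#' @export
defect_density_timeseries <- function(obs, fov_area_mm2,
                                      charge_filter = NULL) {
  stopifnot(fov_area_mm2 > 0)
  if (!is.null(charge_filter)) obs <- obs[obs$charge == charge_filter, ]
  frames <- sort(unique(obs$frame))
  n <- vapply(frames, function(f) sum(obs$frame == f), integer(1))
  data.frame(frame = frames, n = n, density_mm2 = n / fov_area_mm2)
}
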