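# 2D cell motility: nucleus tracking across time-lapse frames and
# per-cell speed / path-persistence metrics. The acquisition default
# mirrors the protocol (one frame every 10 min for 18 h).

#' Track nuclei across a time-lapse
#'
#' Detects per-frame nucleus centroids (Otsu threshold after
#' nucleus-scale smoothing) and links them with the same
#' mutual-nearest-neighbour proximity rule used for beads. Tracks
#' shorter than `min_track_len` frames are discarded. Input may also be a
#' precomputed centroid table (`frame`, `x_um`, `y_um`).
#'
#' @param movie `image_stack` (time role) or centroid data.frame.
#' @param max_disp_um maximum displacement per frame, um.
#' @param frame_interval_min frame interval in minutes (default 10).
#' @param min_track_len minimum track length in frames (default 12).
#' @param smooth_sigma_px detection smoothing (default 2 px).
#' @return data.frame(cell_id, frame, t_min, x_um, y_um).
#' @export
track_nuclei <- function(movie, max_disp_um = 50, frame_interval_min = 10,
                         min_track_len = 12L, smooth_sigma_px = 2) {
  if (inherits(movie, "image_stack")) {
    stopifnot(movie$role == "time")
    ps <- movie$pixel_size_um
    per <- lapply(seq_len(n_planes(movie)), function(i) {
      det <- detect_particles(smooth_gaussian(stack_plane(movie, i), smooth_sigma_px))
      data.frame(x = det$x * ps, y = det$y * ps)
    })
    linked <- link_tracks(per, max_disp = max_disp_um, dt = frame_interval_min)
  } else {
    stopifnot(all(c("frame", "x_um", "y_um") %in% names(movie)))
    linked <- link_tracks(data.frame(frame = movie$frame, x = movie$x_um,
                                     y = movie$y_um),
                          max_disp = max_disp_um, dt = frame_interval_min)
  }
  len <- table(linked$particle_id)
  keep <- as.integer(names(len)[len >= min_track_len])
  out <- linked[linked$particle_id %in% keep, ]
  data.frame(cell_id = out$particle_id, frame = out$frame, t_min = out$t,
             x_um = out$x, y_um = out$y)
}

#' Speed and persistence metrics of one trajectory
#'
#' `path_length` sums consecutive step lengths; `mean_speed` is path
#' length over elapsed time; `net_displacement` is |end - start|;
#' `persistence` (directionality ratio) is net displacement over path
#' length, 0 when the path length is 0, and <= 1 by the triangle
#' inequality. `autocorr_persistence`, the mean cosine between
#' consecutive step directions, is reported as an alternative
#' persistence reading.
#'
#' @param traj data.frame with `t_min`, `x_um`, `y_um` (>= 2 rows).
#' @return list(mean_speed_um_min, persistence, path_length_um,
#'   net_displacement_um, autocorr_persistence).
#' @export
trajectory_metrics <- function(traj) {
  n <- nrow(traj)
  if (n < 2L) stop("trajectory_metrics: need >= 2 samples")
  dx <- diff(traj$x_um); dy <- diff(traj$y_um)
  steps <- sqrt(dx^2 + dy^2)
  path <- sum(steps)
  net <- sqrt((traj$x_um[n] - traj$x_um[1L])^2 + (traj$y_um[n] - traj$y_um[1L])^2)
  elapsed <- traj$t_min[n] - traj$t_min[1L]
  if (elapsed <= 0) stop("trajectory_metrics: non-increasing time")
  ok <- steps > 0
  ac <- if (sum(ok) >= 2L) {
    ux <- (dx / ifelse(ok, steps, 1))[ok]; uy <- (dy / ifelse(ok, steps, 1))[ok]
    k <- length(ux)
    mean(ux[-1L] * ux[-k] + uy[-1L] * uy[-k])
  } else NA_real_
  list(mean_speed_um_min = path / elapsed,
       persistence = if (path > 0) net / path else 0,
       path_length_um = path, net_displacement_um = net,
       autocorr_persistence = ac)
}

#' Metrics table for many trajectories
#'
#' @param trajs data.frame with `cell_id`, `t_min`, `x_um`, `y_um`.
#' @return data.frame, one row per cell.
#' @export
motility_metrics <- function(trajs) {
  ids <- sort(unique(trajs$cell_id))
  rows <- lapply(ids, function(id) {
    m <- trajectory_metrics(trajs[trajs$cell_id == id, ])
    data.frame(cell_id = id, mean_speed_um_min = m$mean_speed_um_min,
               persistence = m$persistence,
               path_length_um = m$path_length_um,
               net_displacement_um = m$net_displacement_um)
  })
  do.call(rbind, rows)
}

#' Origin-centred trajectory coordinates for rose plots
#'
#' Translates every trajectory so its first sample sits at (0, 0).
#'
#' @param trajs data.frame with `cell_id`, `t_min`, `x_um`, `y_um`.
#' @return data.frame of the same shape with recentred coordinates.
#' @export
rose_plot_data <- function(trajs) {
  stopifnot(nrow(trajs) >= 1L)
  out <- trajs[order(trajs$cell_id, trajs$t_min), ]
  for (id in unique(out$cell_id)) {
    sel <- out$cell_id == id
    out$x_um[sel] <- out$x_um[sel] - out$x_um[sel][1L]
    out$y_um[sel] <- out$y_um[sel] - out$y_um[sel][1L]
  }
  rownames(out) <- NULL
  out
}
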