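# Particle-tracking microrheology: bead detection by intensity-weighted
# centroids, proximity-principle linking across frames, time-averaged MSD
# and diffusivity fits. Thermal bead motion reports on the local
# viscoelasticity of the cytoplasm; for free diffusion in 2D,
# MSD(tau) = 4 D tau (+ a constant offset from localisation noise).

#' Detect particles in a single frame
#'
#' Thresholds the frame (global Otsu by default), labels 8-connected
#' above-threshold regions and returns the intensity-weighted centroid of
#' each region with integrated intensity >= `min_mass`. Coordinates are
#' 0-based subpixel positions (x = column, y = row).
#'
#' @param frame numeric matrix.
#' @param threshold_mode `"otsu"` or `"absolute"`.
#' @param threshold absolute threshold (required for `"absolute"`).
#' @param min_mass minimum integrated (background-subtracted) intensity.
#' @return data.frame(x, y, mass); empty (with a warning) for flat frames.
#' @export
detect_particles <- function(frame, threshold_mode = c("otsu", "absolute"),
                             threshold = NULL, min_mass = 0) {
  threshold_mode <- match.arg(threshold_mode)
  if (any(!is.finite(frame))) stop("detect_particles: frame must be finite")
  if (max(frame) <= min(frame)) {
    warning("detect_particles: flat frame, no detections")
    return(data.frame(x = numeric(), y = numeric(), mass = numeric()))
  }
  thr <- if (threshold_mode == "otsu") otsu_threshold(frame) else {
    if (is.null(threshold)) stop("detect_particles: absolute mode needs threshold")
    threshold
  }
  bin <- frame > thr
  if (!any(bin)) {
    warning("detect_particles: nothing above threshold")
    return(data.frame(x = numeric(), y = numeric(), mass = numeric()))
  }
  lab <- label_components(bin)
  pr <- region_props(lab, frame - thr)   # centroid on above-threshold signal
  pr <- pr[pr$mass >= min_mass, , drop = FALSE]
  data.frame(x = pr$x, y = pr$y, mass = pr$mass)
}

# greedy mutual-nearest-neighbour matching between two point sets;
# returns integer vector: for each row of a, the matched row of b or NA
.match_mutual_nn <- function(ax, ay, bx, by, max_disp) {
  na <- length(ax); nb <- length(bx)
  if (na == 0L || nb == 0L) return(rep(NA_integer_, na))
  d2 <- outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2
  d2[d2 > max_disp^2] <- Inf
  match_ab <- rep(NA_integer_, na)
  # deterministic tie-break: among equal distances prefer the lower index
  nn_a <- apply(d2, 1L, function(r) if (all(!is.finite(r))) NA_integer_ else which.min(r))
  nn_b <- apply(d2, 2L, function(cl) if (all(!is.finite(cl))) NA_integer_ else which.min(cl))
  for (i in seq_len(na)) {
    j <- nn_a[i]
    if (!is.na(j) && !is.na(nn_b[j]) && nn_b[j] == i) match_ab[i] <- j
  }
  match_ab
}

#' Link per-frame detections into trajectories (proximity principle)
#'
#' Greedy mutual-nearest-neighbour assignment between consecutive frames:
#' a detection pair is linked iff each is the other's nearest neighbour
#' and their distance is <= `max_disp`. Unmatched detections start new
#' tracks; a particle that disappears and reappears gets a new id (no gap
#' closing). Distance ties resolve deterministically to the lower index.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (any
#'   consistent length unit), or a list of per-frame data.frames.
#' @param max_disp maximum link length, same unit as x/y.
#' @param dt frame interval in seconds (for the `t` column).
#' @return data.frame(particle_id, frame, t, x, y, complete) -- one row per
#'   sample; `complete` marks tracks spanning every input frame.
#' @export
link_tracks <- function(detections, max_disp, dt = 1) {
  if (is.data.frame(detections)) {
    frames <- sort(unique(detections$frame))
    per <- lapply(frames, function(f) detections[detections$frame == f, , drop = FALSE])
  } else {
    per <- detections
    frames <- if (!is.null(names(per))) as.numeric(names(per)) else seq_along(per) - 1L
  }
  if (length(per) < 2L) stop("link_tracks: need detections from >= 2 frames")
  next_id <- 0L
  new_ids <- function(n) { ids <- next_id + seq_len(n); next_id <<- next_id + n; ids }
  cur <- per[[1L]]
  cur_ids <- new_ids(nrow(cur))
  rows <- list(data.frame(particle_id = cur_ids, frame = frames[1L],
                          x = cur$x, y = cur$y))
  for (fi in seq_len(length(per) - 1L)) {
    nxt <- per[[fi + 1L]]
    m <- .match_mutual_nn(cur$x, cur$y, nxt$x, nxt$y, max_disp)
    nxt_ids <- rep(NA_integer_, nrow(nxt))
    nxt_ids[m[!is.na(m)]] <- cur_ids[!is.na(m)]
    fresh <- is.na(nxt_ids)
    nxt_ids[fresh] <- new_ids(sum(fresh))
    rows[[fi + 1L]] <- data.frame(particle_id = nxt_ids, frame = frames[fi + 1L],
                                  x = nxt$x, y = nxt$y)
    cur <- nxt; cur_ids <- nxt_ids
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$particle_id, out$frame), ]
  len <- table(out$particle_id)
  out$complete <- out$particle_id %in% as.integer(names(len)[len == length(per)])
  out$t <- out$frame * dt
  rownames(out) <- NULL
  out[, c("particle_id", "frame", "t", "x", "y", "complete")]
}

#' Time-averaged mean squared displacement of one track
#'
#' For each lag tau = k dt, averages the squared displacement
#' `[x(t) - x(t - tau)]^2 + [y(t) - y(t - tau)]^2` over all valid start
#' times t (overlapping windows). Lags are limited to
#' `max_lag_fraction` of the track length.
#'
#' @param track data.frame with columns `x`, `y` (um) and either `t`
#'   (uniform sampling) or nothing (then `dt` spacing is assumed).
#' @param dt sampling interval, s.
#' @param max_lag_fraction largest lag as a fraction of track length.
#' @return an `msd_curve`: data.frame(lag_s, msd_um2, n_pairs) with
#'   attribute `mode = "time"`.
#' @export
compute_msd <- function(track, dt, max_lag_fraction = 0.25) {
  n <- nrow(track)
  if (n < 2L) stop("compute_msd: track needs >= 2 samples")
  if (!is.null(track$t)) {
    dts <- diff(track$t)
    if (max(abs(dts - dts[1L])) > 1e-9 * max(dts[1L], 1))
      stop("compute_msd: non-uniform sampling; resample the track to a ",
           "constant interval first")
  }
  max_k <- max(1L, min(n - 1L, floor(n * max_lag_fraction)))
  lags <- seq_len(max_k)
  msd <- numeric(max_k); np <- integer(max_k)
  for (k in lags) {
    ddx <- track$x[(k + 1L):n] - track$x[1L:(n - k)]
    ddy <- track$y[(k + 1L):n] - track$y[1L:(n - k)]
    msd[k] <- sum(ddx^2 + ddy^2) / (n - k)
    np[k] <- n - k
  }
  structure(data.frame(lag_s = lags * dt, msd_um2 = msd, n_pairs = np),
            mode = "time", class = c("msd_curve", "data.frame"))
}

#' Time-and-ensemble-averaged MSD over many tracks
#'
#' Pools the per-pair squared displacements of all tracks at each lag
#' (weighting every displacement pair equally).
#'
#' @param tracks data.frame with `particle_id`, `x`, `y` columns.
#' @param dt sampling interval, s.
#' @param max_lag_fraction largest lag as fraction of the shortest track.
#' @return `msd_curve` with attribute `mode = "time+ensemble"`.
#' @export
compute_msd_ensemble <- function(tracks, dt, max_lag_fraction = 0.25) {
  ids <- unique(tracks$particle_id)
  nmin <- min(table(tracks$particle_id))
  max_k <- max(1L, floor(nmin * max_lag_fraction))
  ssum <- numeric(max_k); np <- integer(max_k)
  for (id in ids) {
    tr <- tracks[tracks$particle_id == id, ]
    n <- nrow(tr)
    for (k in seq_len(min(max_k, n - 1L))) {
      ddx <- tr$x[(k + 1L):n] - tr$x[1L:(n - k)]
      ddy <- tr$y[(k + 1L):n] - tr$y[1L:(n - k)]
      ssum[k] <- ssum[k] + sum(ddx^2 + ddy^2)
      np[k] <- np[k] + (n - k)
    }
  }
  keep <- np >= 1L
  structure(data.frame(lag_s = seq_len(max_k)[keep] * dt,
                       msd_um2 = ssum[keep] / np[keep], n_pairs = np[keep]),
            mode = "time+ensemble", class = c("msd_curve", "data.frame"))
}

#' Fit diffusivity from an MSD curve
#'
#' Ordinary least squares of `msd = 4 D tau + b` over the chosen lags.
#' The intercept absorbs static localisation noise (b = 4 sigma_loc^2).
#' A negative fitted D is reported as-is with a warning (sub-resolution
#' motion).
#'
#' @param curve `msd_curve`.
#' @param fit_lags indices (into the curve rows) to fit; default all.
#' @return list(D_um2_s, intercept_um2, n_lags).
#' @export
fit_diffusivity <- function(curve, fit_lags = NULL) {
  if (is.null(fit_lags)) fit_lags <- seq_len(nrow(curve))
  cv <- curve[fit_lags, , drop = FALSE]
  if (nrow(cv) < 2L) stop("fit_diffusivity: need >= 2 lags to fit")
  fit <- stats::lm.fit(cbind(1, cv$lag_s), cv$msd_um2)
  D <- unname(fit$coefficients[2L]) / 4
  if (is.finite(D) && D < 0)
    warning("fit_diffusivity: negative fitted D (sub-resolution motion)")
  list(D_um2_s = D, intercept_um2 = unname(fit$coefficients[1L]),
       n_lags = nrow(cv))
}
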