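# Synthetic fixtures with known ground truth for every assay modality.
# Defaults mirror the acquisition regimes of the experimental protocols
# (0.5 um beads filmed at 100 fps for 5 s; 15 emission channels from
# 460 to 600 nm; nuclei tracked every 10 min for 18 h). Every generator
# takes a seed and regenerates bit-identically from it.

.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulate Brownian bead tracks
#'
#' Per-axis displacement per frame is N(0, 2 D dt); independent isotropic
#' Gaussian localisation noise is added to each observed position after
#' the displacement (standard camera-localisation model). Defaults follow
#' the microrheology acquisition regime: 100 fps for 5 s (500 frames).
#'
#' @param D diffusivity, um^2/s. @param n_particles number of beads.
#' @param n_frames frames per track. @param dt frame interval, s.
#' @param loc_noise_um localisation noise sd, um. @param seed RNG seed.
#' @param field_um particles start uniformly in a square field of this side.
#' @return list with `tracks` (particle_id, frame, t_s, x_um, y_um; observed
#'   positions), `truth_tracks` (noise-free positions) and `truth`
#'   (generating parameters).
#' @export
simulate_brownian_tracks <- function(D = 0.1, n_particles = 100L, n_frames = 500L,
                                     dt = 0.01, loc_noise_um = 0, seed = 1L,
                                     field_um = 100) {
  if (D < 0 || dt <= 0 || n_frames < 2L || n_particles < 1L || loc_noise_um < 0)
    stop("simulate_brownian_tracks: invalid parameters")
  .with_seed(seed, {
    sd_step <- sqrt(2 * D * dt)
    x0 <- stats::runif(n_particles, 0, field_um)
    y0 <- stats::runif(n_particles, 0, field_um)
    n <- n_particles * n_frames
    id <- rep(seq_len(n_particles), each = n_frames)
    frame <- rep(seq_len(n_frames) - 1L, n_particles)
    dx <- matrix(stats::rnorm(n, 0, sd_step), n_frames, n_particles)
    dy <- matrix(stats::rnorm(n, 0, sd_step), n_frames, n_particles)
    dx[1L, ] <- 0; dy[1L, ] <- 0
    xt <- sweep(apply(dx, 2L, cumsum), 2L, x0, `+`)
    yt <- sweep(apply(dy, 2L, cumsum), 2L, y0, `+`)
    xo <- xt + stats::rnorm(n, 0, loc_noise_um)
    yo <- yt + stats::rnorm(n, 0, loc_noise_um)
    tracks <- data.frame(particle_id = id, frame = frame, t_s = frame * dt,
                         x_um = as.vector(xo), y_um = as.vector(yo))
    truth_tracks <- data.frame(particle_id = id, frame = frame, t_s = frame * dt,
                               x_um = as.vector(xt), y_um = as.vector(yt))
    list(tracks = tracks, truth_tracks = truth_tracks,
         truth = list(D = D, dt = dt, n_particles = n_particles,
                      n_frames = n_frames, loc_noise_um = loc_noise_um,
                      field_um = field_um, seed = seed))
  })
}

#' Render particle tracks as a noisy movie
#'
#' Each particle becomes a Gaussian spot at its true subpixel position;
#' additive Gaussian read noise on top of a constant background.
#' Positions outside the field are clipped to it with a warning.
#'
#' @param tracks data.frame as from [simulate_brownian_tracks()] (x_um/y_um).
#' @param image_size c(h, w) pixels. @param pixel_size_um um per pixel.
#' @param psf_sigma_px spot sd in px. @param peak_intensity spot amplitude.
#' @param background constant offset. @param noise_sd read-noise sd.
#' @param seed RNG seed.
#' @return `image_stack` (time role).
#' @export
render_particle_movie <- function(tracks, image_size = c(128L, 128L),
                                  pixel_size_um = 0.2, psf_sigma_px = 1.5,
                                  peak_intensity = 200, background = 10,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(psf_sigma_px > 0)
  frames <- sort(unique(tracks$frame))
  h <- image_size[1L]; w <- image_size[2L]
  dt <- if (nrow(tracks) > 1L) stats::median(diff(sort(unique(tracks$t_s)))) else 1
  if (!is.finite(dt) || dt <= 0) dt <- 1
  xs <- tracks$x_um / pixel_size_um
  ys <- tracks$y_um / pixel_size_um
  if (any(xs < 0 | xs > w - 1 | ys < 0 | ys > h - 1)) {
    warning("render_particle_movie: particle outside frame, clipped")
    xs <- pmin(pmax(xs, 0), w - 1)
    ys <- pmin(pmax(ys, 0), h - 1)
  }
  r <- ceiling(6 * psf_sigma_px)   # wide support keeps truncation asymmetry
                                   # of the spot centroid below 1e-6 px
  .with_seed(seed, {
    arr <- array(0, dim = c(length(frames), h, w))
    for (fi in seq_along(frames)) {
      img <- matrix(background, h, w)
      sel <- which(tracks$frame == frames[fi])
      for (s in sel) {
        cx <- xs[s]; cy <- ys[s]
        c0 <- max(0L, floor(cx) - r); c1 <- min(w - 1L, ceiling(cx) + r)
        r0 <- max(0L, floor(cy) - r); r1 <- min(h - 1L, ceiling(cy) + r)
        gx <- exp(-((c0:c1) - cx)^2 / (2 * psf_sigma_px^2))
        gy <- exp(-((r0:r1) - cy)^2 / (2 * psf_sigma_px^2))
        img[(r0:r1) + 1L, (c0:c1) + 1L] <-
          img[(r0:r1) + 1L, (c0:c1) + 1L] + peak_intensity * outer(gy, gx)
      }
      if (noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
      arr[fi, , ] <- pmax(img, 0)
    }
    image_stack(arr, role = "time", pixel_size_um = pixel_size_um,
                frame_interval_s = dt)
  })
}

#' Synthetic spectral emission stack
#'
#' 15 channels on the 460..600 nm grid (10 nm steps). Per-pixel spectrum is
#' the sum of two Gaussian emission bands (donor ~480 nm, acceptor ~530 nm)
#' plus iid Gaussian noise. Regions are square patches tiled over the field,
#' one per amplitude pair; an optional extra patch of pure background offset
#' carries the background label.
#'
#' @param donor_amp,acceptor_amp numeric vectors (recycled to the longer),
#'   one entry per region.
#' @param donor_peak_nm,acceptor_peak_nm band centres (must lie in 460..600).
#' @param peak_sigma_nm band sd in nm. @param noise_sd additive noise sd.
#' @param region_size patch side in px. @param background_offset constant
#'   added to every channel everywhere; when > 0 a background patch (label
#'   n_regions + 1) is appended so callers can subtract it.
#' @param seed RNG seed.
#' @return list(stack, mask (`label_mask`), background_label, truth).
#' @export
synth_spectral_stack <- function(donor_amp = 200, acceptor_amp = 100,
                                 donor_peak_nm = 480, acceptor_peak_nm = 530,
                                 peak_sigma_nm = 12, noise_sd = 0,
                                 region_size = 8L, background_offset = 0,
                                 seed = 1L) {
  wl <- seq(460, 600, by = 10)
  n <- max(length(donor_amp), length(acceptor_amp))
  donor_amp <- rep_len(donor_amp, n); acceptor_amp <- rep_len(acceptor_amp, n)
  if (any(donor_amp < 0) || any(acceptor_amp < 0))
    stop("synth_spectral_stack: amplitudes must be >= 0")
  if (donor_peak_nm < 460 || donor_peak_nm > 600 ||
      acceptor_peak_nm < 460 || acceptor_peak_nm > 600)
    stop("synth_spectral_stack: peak outside captured range 460-600 nm")
  n_regions <- n + (background_offset > 0)
  ncols <- ceiling(sqrt(n_regions))
  nrows <- ceiling(n_regions / ncols)
  h <- nrows * region_size; w <- ncols * region_size
  lab <- matrix(0L, h, w)
  for (k in seq_len(n_regions)) {
    ri <- (k - 1L) %/% ncols; ci <- (k - 1L) %% ncols
    lab[ri * region_size + seq_len(region_size),
        ci * region_size + seq_len(region_size)] <- k
  }
  .with_seed(seed, {
    # vectorised: per-pixel amplitude maps, then one plane per channel
    d_map <- matrix(c(0, donor_amp, 0)[pmin(lab, n + 1L) + 1L], h, w)
    a_map <- matrix(c(0, acceptor_amp, 0)[pmin(lab, n + 1L) + 1L], h, w)
    # emission bands are Gaussians truncated at +/- 3 sigma: compact
    # support keeps the donor and acceptor windows free of cross-talk,
    # so the noiseless peak ratio equals the amplitude ratio exactly
    band <- function(centre) {
      g <- exp(-(wl - centre)^2 / (2 * peak_sigma_nm^2))
      g[abs(wl - centre) > 3 * peak_sigma_nm] <- 0
      g
    }
    gd <- band(donor_peak_nm)
    ga <- band(acceptor_peak_nm)
    arr <- array(background_offset, dim = c(length(wl), h, w))
    for (ci in seq_along(wl))
      arr[ci, , ] <- arr[ci, , ] + d_map * gd[ci] + a_map * ga[ci]
    if (noise_sd > 0)
      arr <- pmax(arr + array(stats::rnorm(length(arr), 0, noise_sd), dim = dim(arr)), 0)
    list(stack = image_stack(arr, role = "spectral", pixel_size_um = 1,
                             channel_wavelengths_nm = wl),
         mask = label_mask(lab, 1),
         background_label = if (background_offset > 0) n_regions else NA_integer_,
         truth = list(donor_amp = donor_amp, acceptor_amp = acceptor_amp,
                      ratio = donor_amp / acceptor_amp,
                      donor_peak_nm = donor_peak_nm,
                      acceptor_peak_nm = acceptor_peak_nm,
                      peak_sigma_nm = peak_sigma_nm, noise_sd = noise_sd,
                      background_offset = background_offset, seed = seed))
  })
}

#' Synthetic TCSPC photon decay histogram
#'
#' Photon arrival times are exponential with mean `tau_ns`, truncated to
#' the acquisition window by rejection, then histogrammed into equal bins.
#'
#' @param tau_ns true lifetime, ns. @param n_photons photons to draw.
#' @param window_ns acquisition window, ns. @param n_bins histogram bins.
#' @param seed RNG seed. @param region_id carried into the histogram.
#' @return list(hist = `decay_histogram`, truth).
#' @export
synth_photon_decay <- function(tau_ns = 2.5, n_photons = 1e5, window_ns = 12.5,
                               n_bins = 256L, seed = 1L, region_id = 1L) {
  if (tau_ns <= 0 || n_photons < 1 || window_ns <= tau_ns / 10)
    stop("synth_photon_decay: invalid parameters")
  .with_seed(seed, {
    # inverse-CDF sampling of the truncated exponential
    u <- stats::runif(n_photons)
    arr <- -tau_ns * log(1 - u * (1 - exp(-window_ns / tau_ns)))
    edges <- seq(0, window_ns, length.out = n_bins + 1L)
    counts <- tabulate(pmin(findInterval(arr, edges, rightmost.closed = TRUE), n_bins),
                       nbins = n_bins)
    list(hist = decay_histogram(edges, counts, region_id = region_id),
         truth = list(tau_ns = tau_ns, n_photons = n_photons,
                      window_ns = window_ns, n_bins = n_bins, seed = seed,
                      mean_arrival_ns = mean(arr)))
  })
}

# dense polygonal approximation of an ellipse, 0-based pixel coords
.ellipse_poly <- function(cx, cy, a, b, n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + a * cos(th), y = cy + b * sin(th))
}

#' Synthetic nucleus with controlled envelope invaginations
#'
#' The analytic shape is an ellipse with radial slit invaginations: at each
#' entry angle the outline runs inward by `depth_um` (slit width
#' `width_um`) and back out. Ground truth records both EOP conventions:
#' `eop` counts both slit walls (open-outline convention, 2x depth) and
#' `eop_skeleton` counts each invagination once (single polyline, as a
#' rasterised zero-width slit is measured).
#'
#' @param a_um,b_um ellipse semi-axes, um. @param invaginations data.frame
#'   with columns `angle` (rad), `depth_um`, `width_um` (may be zero rows).
#' @param pixel_size_um rasterisation scale. @param seed RNG seed (jitters
#'   nothing by default; kept for interface uniformity).
#' @return list(mask = `label_mask` (filled ellipse), skeleton = binary
#'   matrix of the envelope trace (ring + slit lines), outline = polygon
#'   matrix (um, two-wall convention), internal_segments = list of slit
#'   centreline polylines (um), truth).
#' @export
synth_nucleus <- function(a_um = 8, b_um = 5, invaginations = NULL,
                          pixel_size_um = 0.1, seed = 1L) {
  if (is.null(invaginations))
    invaginations <- data.frame(angle = numeric(), depth_um = numeric(),
                                width_um = numeric())
  if (nrow(invaginations) > 0) {
    if (any(invaginations$depth_um >= min(a_um, b_um)))
      stop("synth_nucleus: invagination depth must be < semi-axis")
    ang <- sort(invaginations$angle %% (2 * pi))
    if (nrow(invaginations) > 1L && min(diff(c(ang, ang[1L] + 2 * pi))) < 0.3)
      stop("synth_nucleus: overlapping invaginations")
  }
  margin <- 2
  cx <- a_um + margin; cy <- b_um + margin
  n_vert <- 1440L
  poly <- .ellipse_poly(cx, cy, a_um, b_um, n_vert)
  th_all <- seq(0, 2 * pi, length.out = n_vert + 1L)[-(n_vert + 1L)]

  segments <- list()
  if (nrow(invaginations) > 0) {
    ord <- order(invaginations$angle %% (2 * pi), decreasing = TRUE)
    inv <- invaginations[ord, , drop = FALSE]
    for (i in seq_len(nrow(inv))) {
      th0 <- inv$angle[i] %% (2 * pi)
      d <- inv$depth_um[i]; wdt <- inv$width_um[i]
      # entry point on the ellipse and inward (towards centre) direction
      p_entry <- c(cx + a_um * cos(th0), cy + b_um * sin(th0))
      dirin <- c(cx, cy) - p_entry; dirin <- dirin / sqrt(sum(dirin^2))
      perp <- c(-dirin[2L], dirin[1L])
      k <- which.min(abs(((th_all - th0 + pi) %% (2 * pi)) - pi))
      pA <- p_entry + perp * wdt / 2
      pB <- p_entry - perp * wdt / 2
      wall <- rbind(pA, pA + dirin * d, pB + dirin * d, pB)
      tail_rows <- if (k < nrow(poly))
        poly[seq(k + 1L, nrow(poly)), , drop = FALSE] else poly[0L, , drop = FALSE]
      poly <- rbind(poly[seq_len(k - 1L), , drop = FALSE], wall, tail_rows)
      segments[[length(segments) + 1L]] <-
        rbind(p_entry, p_entry + dirin * d)
    }
  }
  ell_perim <- polygon_perimeter(.ellipse_poly(cx, cy, a_um, b_um, n_vert))
  hull <- convex_hull_polygon(poly)
  hull_perim <- polygon_perimeter(hull)
  outline_perim <- polygon_perimeter(poly)
  seg_len <- sum(vapply(segments, function(s) polygon_perimeter(s, closed = FALSE),
                        numeric(1L)))
  truth <- list(eop = outline_perim / hull_perim,
                eop_skeleton = (ell_perim + seg_len) / hull_perim,
                a_um = a_um, b_um = b_um, pixel_size_um = pixel_size_um,
                invaginations = invaginations, seed = seed)

  # raster mask: filled ellipse (hull support); skeleton: ring + slit lines
  hpx <- ceiling((2 * (b_um + margin)) / pixel_size_um)
  wpx <- ceiling((2 * (a_um + margin)) / pixel_size_um)
  xs <- (seq_len(wpx) - 1) * pixel_size_um
  ys <- (seq_len(hpx) - 1) * pixel_size_um
  mask <- outer(ys, xs, function(y, x)
    ((x - cx) / a_um)^2 + ((y - cy) / b_um)^2 <= 1)
  bres <- function(x0, y0, x1, y1) {   # 8-connected integer line walk
    dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
    sx <- sign(x1 - x0); sy <- sign(y1 - y0)
    err <- dx + dy
    out <- matrix(0L, dx - dy + 1L, 2L); n <- 0L
    repeat {
      n <- n + 1L; out[n, ] <- c(x0, y0)
      if (x0 == x1 && y0 == y1) break
      e2 <- 2L * err
      if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
      if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
    }
    out[seq_len(n), , drop = FALSE]
  }
  rasterize <- function(pts) {        # polyline -> thin 8-connected pixel set
    # resample at ~1.4 px arclength spacing first: rounding a denser
    # sampling would produce a 2-px-thick digital curve
    seg <- sqrt(rowSums(diff(pts)^2))
    s <- c(0, cumsum(seg))
    n_out <- max(2L, ceiling(s[length(s)] / (1.4 * pixel_size_um)) + 1L)
    si <- seq(0, s[length(s)], length.out = n_out)
    pts <- cbind(stats::approx(s, pts[, 1L], si)$y, stats::approx(s, pts[, 2L], si)$y)
    v <- cbind(round(pts[, 1L] / pixel_size_um), round(pts[, 2L] / pixel_size_um))
    v <- v[c(TRUE, rowSums(abs(diff(v))) > 0), , drop = FALSE]
    px <- do.call(rbind, lapply(seq_len(max(nrow(v) - 1L, 1L)), function(i) {
      if (nrow(v) == 1L) v else
        bres(v[i, 1L], v[i, 2L], v[i + 1L, 1L], v[i + 1L, 2L])
    }))
    cbind(clamp_idx(px[, 2L] + 1L, hpx), clamp_idx(px[, 1L] + 1L, wpx))
  }
  skel <- matrix(FALSE, hpx, wpx)
  ring <- .ellipse_poly(cx, cy, a_um, b_um, n_vert)
  skel[rasterize(rbind(ring, ring[1L, ]))] <- TRUE
  for (s in segments) skel[rasterize(s)] <- TRUE
  list(mask = label_mask(mask * 1L, pixel_size_um), skeleton = skel,
       outline = poly, internal_segments = segments, truth = truth)
}

#' Synthetic polarised-nucleus fixtures
#'
#' Each cell is an elliptical nucleus with a designated front direction
#' (random per cell unless `orient_random = FALSE`, in which case the front
#' is +x). A fraction `front_fraction` (in expectation) of the top-quantile
#' pixels is placed in the front half of the nucleus: k = ceil(0.2 n_mask)
#' pixels are chosen (Binomial(k, front_fraction) of them from the front
#' half) and given high intensity over a low base; iid noise on top. The
#' Golgi centroid is placed just outside the nucleus on the front side.
#'
#' @param front_fraction expected share of top-quantile signal in the front
#'   half, in `[0, 1]`.
#' @param n_cells number of cells. @param image_size image side, px.
#' @param quantile top-quantile convention used for k (default 0.80).
#' @param noise_sd intensity noise sd (gap between base 50 and hot 150).
#' @param orient_random random front angles (default) or +x for all cells.
#' @param seed RNG seed.
#' @return list(cells = list of list(signal, mask, golgi_centroid,
#'   front_angle), truth).
#' @export
synth_polarized_cell <- function(front_fraction = 0.5, n_cells = 50L,
                                 image_size = 64L, quantile = 0.80,
                                 noise_sd = 5, orient_random = TRUE, seed = 1L) {
  if (front_fraction < 0 || front_fraction > 1)
    stop("synth_polarized_cell: front_fraction must be in [0, 1]")
  h <- image_size; w <- image_size
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  a <- 0.42 * w; b <- 0.30 * h
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  mask <- outer(ys, xs, function(y, x) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)
  midx <- which(mask)
  rc <- arrayInd(midx, dim(mask))
  px <- rc[, 2L] - 1 - cx; py <- rc[, 1L] - 1 - cy
  n_mask <- length(midx)
  k <- ceiling((1 - quantile) * n_mask)
  .with_seed(seed, {
    cells <- vector("list", n_cells)
    for (ci in seq_len(n_cells)) {
      th <- if (orient_random) stats::runif(1, 0, 2 * pi) else 0
      axis_coord <- px * cos(th) + py * sin(th)   # front = direction th
      front <- axis_coord > 0
      # weighted sampling without replacement: at front_fraction = 0.5 this
      # is a uniform k-subset of the mask, exactly the iid-intensity null
      wgt <- ifelse(front, front_fraction, 1 - front_fraction)
      if (all(wgt == 0)) wgt[] <- 1
      hot <- sample(seq_len(n_mask), k, prob = wgt)
      base <- rep(50, n_mask); base[hot] <- 150
      sig <- matrix(0, h, w)
      sig[midx] <- pmax(base + stats::rnorm(n_mask, 0, noise_sd), 0)
      golgi <- c(cx + (a + 2) * cos(th), cy + (a + 2) * sin(th))  # along front
      cells[[ci]] <- list(signal = sig, mask = mask,
                          golgi_centroid = golgi, front_angle = th)
    }
    list(cells = cells,
         truth = list(front_fraction = front_fraction, n_cells = n_cells,
                      quantile = quantile, k_top = k, n_mask = n_mask,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Synthetic multichannel cell image (nucleus / YAP-like / vinculin / actin)
#'
#' Channels: 1 nucleus stain, 2 YAP-like signal with distinct nuclear and
#' cytoplasmic levels, 3 vinculin with `n_fa_blobs` Gaussian focal-adhesion
#' blobs in the cytoplasm, 4 actin texture (parallel stripes or isotropic
#' noise).
#'
#' @param nuc_intensity,cyto_intensity YAP-like channel levels.
#' @param n_fa_blobs focal-adhesion blob count. @param actin_pattern
#'   `"stripes"` or `"isotropic"`. @param noise_sd additive noise sd.
#' @param image_size image side, px. @param pixel_size_um um/px.
#' @param stripe_angle stripe direction, rad. @param seed RNG seed.
#' @return list(stack (multichannel), nucleus_mask, cell_mask, truth).
#' @export
synth_cell_image <- function(nuc_intensity = 100, cyto_intensity = 50,
                             n_fa_blobs = 20L, actin_pattern = c("stripes", "isotropic"),
                             noise_sd = 0, image_size = 96L, pixel_size_um = 0.2,
                             stripe_angle = 0, seed = 1L) {
  actin_pattern <- match.arg(actin_pattern)
  if (nuc_intensity < 0 || cyto_intensity < 0)
    stop("synth_cell_image: intensities must be >= 0")
  h <- image_size; w <- image_size
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  r_cell <- 0.45 * w; r_nuc <- 0.18 * w
  cell <- outer(ys, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <= r_cell^2)
  nuc <- outer(ys, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <= r_nuc^2)
  .with_seed(seed, {
    noisy <- function(img) pmax(img + if (noise_sd > 0)
      matrix(stats::rnorm(h * w, 0, noise_sd), h, w) else 0, 0)
    ch_nuc <- noisy(200 * nuc)
    ch_yap <- noisy(nuc_intensity * nuc + cyto_intensity * (cell & !nuc))
    # vinculin blobs on a ring in the cytoplasm, mutually separated
    blob_sigma <- 1.2
    r_ring <- (r_nuc + r_cell) / 2
    if (n_fa_blobs > 0) {
      spacing_ok <- (2 * pi * r_ring) / n_fa_blobs > 3 * (2 * blob_sigma)
      if (!spacing_ok) stop("synth_cell_image: blob packing infeasible")
      th <- (seq_len(n_fa_blobs) - 1) * 2 * pi / n_fa_blobs
      bx <- cx + r_ring * cos(th); by <- cy + r_ring * sin(th)
      ch_vin <- matrix(0, h, w)
      for (i in seq_len(n_fa_blobs))
        ch_vin <- ch_vin + 200 * outer(exp(-(ys - by[i])^2 / (2 * blob_sigma^2)),
                                       exp(-(xs - bx[i])^2 / (2 * blob_sigma^2)))
      ch_vin <- noisy(ch_vin * cell)
    } else ch_vin <- noisy(matrix(0, h, w))
    ch_act <- if (actin_pattern == "stripes") {
      ph <- outer(ys, xs, function(y, x)
        (x * cos(stripe_angle) + y * sin(stripe_angle)))
      noisy((100 + 100 * sin(2 * pi * ph / 6)) * cell)
    } else {
      noisy(matrix(stats::runif(h * w, 0, 200), h, w) * cell)
    }
    arr <- array(0, dim = c(4L, h, w))
    arr[1L, , ] <- ch_nuc; arr[2L, , ] <- ch_yap
    arr[3L, , ] <- ch_vin; arr[4L, , ] <- ch_act
    list(stack = image_stack(arr, role = "multichannel",
                             pixel_size_um = pixel_size_um,
                             channel_names = c("nucleus", "yap", "vinculin", "actin")),
         nucleus_mask = label_mask(nuc * 1L, pixel_size_um),
         cell_mask = label_mask(cell * 1L, pixel_size_um),
         truth = list(nc_ratio = nuc_intensity / cyto_intensity,
                      n_fa_blobs = n_fa_blobs, actin_pattern = actin_pattern,
                      nuc_intensity = nuc_intensity,
                      cyto_intensity = cyto_intensity,
                      stripe_angle = stripe_angle, noise_sd = noise_sd,
                      seed = seed))
  })
}

#' Simulate persistent-random-walk cell trajectories
#'
#' Constant step length `speed * dt`; the heading angle accumulates
#' Gaussian increments with variance `2 * rot_diffusion * dt`. Defaults
#' mirror the motility acquisition protocol: one sample every 10 min for
#' 18 h (109 samples per cell).
#'
#' @param speed_um_min cell speed, um/min. @param rot_diffusion rotational
#'   diffusion coefficient, rad^2/min. @param n_cells cells to simulate.
#' @param dt_min sampling interval, min. @param duration_h total duration, h.
#' @param field_um cells start uniformly in a square field of this side
#'   (keeps re-tracking from a centroid table well-posed).
#' @param seed RNG seed.
#' @return list(trajectories = data.frame(cell_id, t_min, x_um, y_um), truth).
#' @export
simulate_cell_trajectories <- function(speed_um_min = 0.5, rot_diffusion = 0.05,
                                       n_cells = 30L, dt_min = 10, duration_h = 18,
                                       field_um = 1000, seed = 1L) {
  if (speed_um_min < 0 || rot_diffusion < 0 || duration_h * 60 / dt_min < 1)
    stop("simulate_cell_trajectories: invalid parameters")
  n_steps <- floor(duration_h * 60 / dt_min)     # 108 at defaults -> 109 samples
  .with_seed(seed, {
    step <- speed_um_min * dt_min
    out <- vector("list", n_cells)
    for (ci in seq_len(n_cells)) {
      x0 <- stats::runif(1, 0, field_um); y0 <- stats::runif(1, 0, field_um)
      th0 <- stats::runif(1, 0, 2 * pi)
      dth <- stats::rnorm(n_steps, 0, sqrt(2 * rot_diffusion * dt_min))
      th <- th0 + cumsum(dth) - dth           # heading during each step
      x <- x0 + c(0, cumsum(step * cos(th)))
      y <- y0 + c(0, cumsum(step * sin(th)))
      out[[ci]] <- data.frame(cell_id = ci, t_min = (0:n_steps) * dt_min,
                              x_um = x, y_um = y)
    }
    list(trajectories = do.call(rbind, out),
         truth = list(speed_um_min = speed_um_min, rot_diffusion = rot_diffusion,
                      n_cells = n_cells, dt_min = dt_min, duration_h = duration_h,
                      n_samples = n_steps + 1L, seed = seed))
  })
}
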