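# Nuclear-envelope morphometry and polarity.
#
# Excess of perimeter (EOP): total envelope trace length (outer outline
# plus internal invagination folds, from Lamin A/C-type staining) divided
# by the perimeter of the convex envelope. A smooth convex nucleus scores
# exactly 1; wrinkling and invaginations push it above 1.
#
# Polarity: per-cell top-quantile signal pixels mapped into a common
# normalised nucleus frame with the cell front (Golgi side) at +x, then
# averaged into an occupancy map; front-vs-rear and condition-vs-condition
# distribution tests run on the pooled normalised axis coordinates.

#' Excess of perimeter from polygon geometry
#'
#' @param outline closed simple polygon, n x 2 matrix (um), >= 3 vertices.
#' @param internal_segments list of open polylines (um) for internal NE
#'   invagination folds; each polyline's length is counted once.
#' @return object of class `nucleus_geometry`: list(outline,
#'   internal_segments, convex_envelope, area_um2, eop, excess).
#' @export
compute_eop <- function(outline, internal_segments = list()) {
  outline <- as.matrix(outline)
  if (nrow(outline) < 3L) stop("compute_eop: outline needs >= 3 vertices")
  # shoelace area (sign-free)
  x <- outline[, 1L]; y <- outline[, 2L]
  xs <- c(x, x[1L]); ys <- c(y, y[1L])
  area <- abs(sum(xs[-1L] * ys[-length(ys)] - xs[-length(xs)] * ys[-1L])) / 2
  if (area <= 0) stop("compute_eop: degenerate outline (zero area)")
  hull <- convex_hull_polygon(outline)
  internal <- sum(vapply(internal_segments,
                         function(s) polygon_perimeter(as.matrix(s), closed = FALSE),
                         numeric(1L)))
  eop <- (polygon_perimeter(outline) + internal) / polygon_perimeter(hull)
  structure(list(outline = outline, internal_segments = internal_segments,
                 convex_envelope = hull, area_um2 = area,
                 eop = eop, excess = eop - 1),
            class = "nucleus_geometry")
}

# calibrated chain-code length of a thin digital curve (Kulpa weights
# 0.948 / 1.340): raw 1 / sqrt(2) step counting overestimates digitised
# curve length by ~5% averaged over orientations; the calibrated weights
# bring smooth curves well under 1%.
.chain_length <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  idx <- which(skel)
  if (length(idx) < 2L) return(0)
  rc <- arrayInd(idx, dim(skel))
  occ <- matrix(FALSE, nr, nc); occ[idx] <- TRUE
  has <- function(r, c) r >= 1L & r <= nr & c >= 1L & c <= nc &
    occ[cbind(clamp_idx(r, nr), clamp_idx(c, nc))]
  r <- rc[, 1L]; c <- rc[, 2L]
  # forward neighbours only, so each adjacency is counted once
  n_e <- sum(has(r, c + 1L)) + sum(has(r + 1L, c))
  # a diagonal adjacency is a shortcut (not a curve step) whenever either
  # corner pixel between the two endpoints is itself on the curve
  dg1 <- has(r + 1L, c + 1L) & !(has(r, c + 1L) | has(r + 1L, c))
  dg2 <- has(r + 1L, c - 1L) & !(has(r, c - 1L) | has(r + 1L, c))
  n_o <- sum(dg1) + sum(dg2)
  0.948 * n_e + 1.340 * n_o
}

#' Excess of perimeter from an NE-skeleton image
#'
#' Measures the total skeleton length (outer ring plus interior
#' invagination branches) by corner-corrected 8-connected chain-code
#' summation, and divides by the convex-hull perimeter of the nucleus
#' mask. Each invagination branch is a single polyline, so its fold is
#' counted once. If the skeleton has no pixels near the mask boundary, a
#' warning is issued and the ring is approximated by the mask boundary.
#'
#' @param skeleton logical/0-1 matrix of the NE trace.
#' @param mask `label_mask` (or 0/1 matrix) of the nucleus.
#' @param pixel_size_um um per pixel (taken from the mask if a
#'   `label_mask` is supplied).
#' @return `nucleus_geometry`-like list with eop, excess,
#'   skeleton_length_um, hull_perimeter_um, area_um2.
#' @export
compute_eop_skeleton <- function(skeleton, mask, pixel_size_um = NULL) {
  if (inherits(mask, "label_mask")) {
    if (is.null(pixel_size_um)) pixel_size_um <- mask$pixel_size_um
    mask <- mask$labels > 0L
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 1.0
  skeleton <- skeleton > 0
  if (!any(mask)) stop("compute_eop_skeleton: empty nucleus mask")
  # boundary pixels of the mask (8-connected outer edge)
  er <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  inner <- mask &
    mask[clamp_idx(seq_len(nr) - 1L, nr), ] & mask[clamp_idx(seq_len(nr) + 1L, nr), ] &
    mask[, clamp_idx(seq_len(nc) - 1L, nc)] & mask[, clamp_idx(seq_len(nc) + 1L, nc)]
  boundary <- mask & !inner
  if (!any(skeleton & boundary) && !any(skeleton & mask & !inner)) {
    near <- skeleton & (boundary |
      boundary[clamp_idx(seq_len(nr) - 1L, nr), ] | boundary[clamp_idx(seq_len(nr) + 1L, nr), ] |
      boundary[, clamp_idx(seq_len(nc) - 1L, nc)] | boundary[, clamp_idx(seq_len(nc) + 1L, nc)])
    if (!any(near)) {
      warning("compute_eop_skeleton: skeleton lacks a closed ring; ",
              "approximating ring by the mask boundary")
      skeleton <- skeleton | boundary
    }
  }
  skel_len <- .chain_length(skeleton) * pixel_size_um
  rc <- arrayInd(which(boundary), dim(mask))
  pts <- cbind(x = (rc[, 2L] - 1) * pixel_size_um, y = (rc[, 1L] - 1) * pixel_size_um)
  hull <- convex_hull_polygon(pts)
  hull_perim <- polygon_perimeter(hull)
  eop <- skel_len / hull_perim
  list(eop = eop, excess = eop - 1, skeleton_length_um = skel_len,
       hull_perimeter_um = hull_perim,
       area_um2 = sum(mask) * pixel_size_um^2, convex_envelope = hull)
}

#' Rotation placing the cell front along +x
#'
#' The front direction is the vector from the nucleus centroid to the
#' Golgi centroid; on line patterns an explicit pattern axis may be
#' supplied instead, with the Golgi choosing the sign. Returns the angle
#' `theta` such that rotating coordinates by `-theta` maps the front to
#' +x.
#'
#' @param mask nucleus mask (`label_mask` or logical matrix).
#' @param golgi_centroid c(x, y), 0-based px.
#' @param pattern_axis optional axis angle in radians; sign resolved by
#'   the Golgi side.
#' @return list(theta, centroid = c(x, y)).
#' @export
orient_front <- function(mask, golgi_centroid = NULL, pattern_axis = NULL) {
  if (inherits(mask, "label_mask")) mask <- mask$labels > 0L
  idx <- which(mask)
  if (length(idx) == 0L) stop("orient_front: empty mask")
  rc <- arrayInd(idx, dim(mask))
  ctr <- c(mean(rc[, 2L] - 1), mean(rc[, 1L] - 1))     # (x, y)
  if (is.null(golgi_centroid) && is.null(pattern_axis))
    stop("orient_front: need golgi_centroid or pattern_axis")
  if (!is.null(pattern_axis)) {
    theta <- pattern_axis
    if (!is.null(golgi_centroid)) {
      v <- golgi_centroid - ctr
      if (cos(theta) * v[1L] + sin(theta) * v[2L] < 0) theta <- theta + pi
    }
  } else {
    v <- golgi_centroid - ctr
    if (sqrt(sum(v^2)) < 1e-9)
      stop("orient_front: Golgi centroid coincides with nucleus centroid; ",
           "supply an explicit pattern_axis")
    theta <- atan2(v[2L], v[1L])
  }
  list(theta = theta, centroid = ctr)
}

# normalised coordinates of selected pixels in the common nucleus frame:
# centroid at origin, front along +x, per-axis half-extent scaling so the
# rotated nucleus spans [-1, 1]^2
.normalise_cell <- function(mask, theta, sel_idx) {
  idx <- which(mask)
  rc <- arrayInd(idx, dim(mask))
  ctr <- c(mean(rc[, 2L] - 1), mean(rc[, 1L] - 1))
  rot <- function(ii) {
    rc2 <- arrayInd(ii, dim(mask))
    dx <- (rc2[, 2L] - 1) - ctr[1L]; dy <- (rc2[, 1L] - 1) - ctr[2L]
    cbind(dx * cos(theta) + dy * sin(theta),
          -dx * sin(theta) + dy * cos(theta))
  }
  all_rot <- rot(idx)
  hx <- max(abs(all_rot[, 1L])); hy <- max(abs(all_rot[, 2L]))
  if (hx <= 0 || hy <= 0) stop("degenerate mask extent")
  sr <- rot(sel_idx)
  cbind(x = sr[, 1L] / hx, y = sr[, 2L] / hy)
}

#' Front-rear polarity occupancy map
#'
#' Per cell: restrict the signal to the nucleus mask, select the top
#' `1 - quantile` fraction of in-mask pixels (exactly
#' `ceiling((1 - quantile) * n)` pixels, ties broken by intensity then
#' raster order), map them into the common frame (front = +x, per-axis
#' half-extent scaling) and binarise onto the grid. The map is the mean
#' occupancy across cells; the normalised x-coordinates of the selected
#' pixels are retained per cell for the distribution tests. Cells with
#' masks under 20 px are skipped with a message.
#'
#' @param cells list of per-cell lists with elements `signal` (matrix),
#'   `mask` (logical matrix or `label_mask`) and either `theta` (front
#'   angle, rad) or `golgi_centroid`.
#' @param quantile per-cell intensity quantile (default 0.80 = top 20%).
#' @param grid_shape occupancy grid c(rows, cols) over [-1,1]^2.
#' @return object of class `polarity_map`: list(grid, per_cell_axis_samples,
#'   n_cells, quantile).
#' @export
polarity_map <- function(cells, quantile = 0.80, grid_shape = c(32L, 32L)) {
  stopifnot(length(cells) >= 1L, quantile > 0, quantile < 1)
  gr <- matrix(0, grid_shape[1L], grid_shape[2L])
  samples <- list(); pops <- list()
  used <- 0L
  for (cell in cells) {
    mask <- cell$mask
    if (inherits(mask, "label_mask")) mask <- mask$labels > 0L
    n <- sum(mask)
    if (n < 20L) { message("polarity_map: cell skipped (mask < 20 px)"); next }
    theta <- if (!is.null(cell$theta)) cell$theta
             else orient_front(mask, cell$golgi_centroid)$theta
    idx <- which(mask)
    inten <- cell$signal[idx]
    k <- ceiling((1 - quantile) * n)
    ord <- order(-inten, idx)          # intensity desc, then raster order
    sel <- idx[ord[seq_len(k)]]
    nc <- .normalise_cell(mask, theta, sel)
    pop <- .normalise_cell(mask, theta, idx)[, 1L]   # all mask pixels
    # binarised per-cell occupancy on the common grid
    bx <- pmin(pmax(floor((nc[, 1L] + 1) / 2 * grid_shape[2L]) + 1L, 1L), grid_shape[2L])
    by <- pmin(pmax(floor((nc[, 2L] + 1) / 2 * grid_shape[1L]) + 1L, 1L), grid_shape[1L])
    occ <- matrix(0, grid_shape[1L], grid_shape[2L])
    occ[cbind(by, bx)] <- 1
    gr <- gr + occ
    samples[[length(samples) + 1L]] <- nc[, 1L]
    pops[[length(pops) + 1L]] <- pop
    used <- used + 1L
  }
  if (used == 0L) stop("polarity_map: no usable cells")
  structure(list(grid = gr / used, per_cell_axis_samples = samples,
                 per_cell_axis_population = pops,
                 n_cells = used, quantile = quantile),
            class = "polarity_map")
}

# survival function of sup_{t in [0,1]} |W(t)|, W standard Brownian motion
.surv_sup_absBM <- function(a) {
  if (a <= 0) return(1)
  k <- 0:200
  1 - (4 / pi) * sum((-1)^k / (2 * k + 1) * exp(-(2 * k + 1)^2 * pi^2 / (8 * a^2)))
}

#' Front-versus-rear distribution test
#'
#' Two-sided Kolmogorov-Smirnov statistic comparing the pooled
#' normalised axis samples with their mirror image (x -> -x):
#' `D = sup_x |F_n(x) + F_n(-x^-) - 1|`, the classical empirical symmetry
#' statistic. Because the mirror sample is a deterministic transform of
#' the data (not an independent sample), the null distribution of
#' `sqrt(n) D` is the supremum of |Brownian motion| on [0,1] -- not the
#' two-sample Kolmogorov distribution, which would reject twice too
#' often. The p-value uses that reflected-BM asymptotic.
#'
#' Because the mirror sample is a deterministic transform of the data,
#' the two-sample Kolmogorov null distribution does not apply. Two null
#' models are provided:
#'
#' * `"resample"` (default for a `polarity_map`): conditional Monte
#'   Carlo against the null implied by the top-quantile selection rule --
#'   under spatially unstructured intensities the selected pixels are a
#'   uniform k-subset of each nucleus mask, so null copies of D are
#'   generated by redrawing uniform subsets from the per-cell pixel
#'   populations retained in the map. Exact up to resampling error, and
#'   automatically accounts for the finite sampling fraction and the
#'   pixel-lattice discreteness of the axis coordinates.
#' * `"asymptotic"` (default for a plain numeric sample): the limit of
#'   `sqrt(n / q) D` under a symmetric continuous null is the supremum of
#'   |Brownian motion| on `[0, 1]` (the mirror empirical process is a
#'   reflected Brownian motion, not a bridge), where `q` is the
#'   finite-population factor (the map's `quantile`, or 1 for iid input).
#'
#' @param map `polarity_map` (or a numeric vector of axis samples).
#' @param null `"resample"` or `"asymptotic"`; see above.
#' @param n_boot resampling replicates (resample null).
#' @param boot_seed internal RNG seed for the resampling null; by default
#'   derived deterministically from the data, so identical inputs give
#'   identical p-values while distinct datasets get independent null
#'   draws.
#' @return list(statistic, p_value, n, method).
#' @export
front_rear_test <- function(map, null = NULL, n_boot = 99L, boot_seed = NULL) {
  is_map <- inherits(map, "polarity_map")
  if (is.null(null)) null <- if (is_map) "resample" else "asymptotic"
  null <- match.arg(null, c("resample", "asymptotic"))
  x <- if (is_map) unlist(map$per_cell_axis_samples) else map
  n <- length(x)
  if (n < 10L) stop("front_rear_test: need >= 10 pooled axis samples")
  D <- .mirror_ks_stat(x)
  if (null == "resample") {
    if (!is_map)
      stop("front_rear_test: resample null needs a polarity_map")
    ks <- vapply(map$per_cell_axis_samples, length, integer(1L))
    pops <- map$per_cell_axis_population
    if (is.null(boot_seed))    # data-derived: deterministic per dataset
      boot_seed <- as.integer(round(
        (sum(abs(x)) * 1e7 + sum(x * seq_along(x)) * 1e3) %% 2147483647))
    Dr <- .with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(r) {
        xr <- unlist(lapply(seq_along(pops), function(i)
          pops[[i]][sample.int(length(pops[[i]]), ks[i])]))
        .mirror_ks_stat(xr)
      }, numeric(1L))
    })
    # mid-p: D sits on a 1/n lattice, so ties with null draws are common;
    # counting them half removes the discreteness conservatism
    p <- (1 + sum(Dr > D) + 0.5 * sum(Dr == D)) / (n_boot + 1)
    method <- sprintf("two-sided KS, sample vs mirror (uniform-subset null, %d resamples)",
                      n_boot)
  } else {
    q <- if (is_map) map$quantile else 1
    p <- .surv_sup_absBM(sqrt(n / q) * D)
    method <- "two-sided KS, sample vs mirror (reflected-BM null)"
  }
  list(statistic = D, p_value = min(max(p, 0), 1), n = n, method = method)
}

# D = sup |F_n - G_n| over the pooled sample, G_n the mirror ECDF;
# ties are handled by evaluating at tie-group boundaries only
.mirror_ks_stat <- function(x) {
  n <- length(x)
  w <- c(x, -x)
  o <- order(w)
  e <- c(rep(1 / n, n), rep(-1 / n, n))[o]
  cum <- cumsum(e)
  group_end <- c(diff(w[o]) != 0, TRUE)
  max(abs(cum[group_end]))
}

# asymptotic CDF of the Cramer-von Mises criterion (limiting distribution),
# Anderson-Darling (1952) Bessel-K series as used for two-sample CvM
.cvm_limit_cdf <- function(x) {
  if (x <= 0) return(0)
  if (x > 20) return(1)
  k <- 0:10
  term <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(0.5) * factorial(k)) *
    exp(-(4 * k + 1)^2 / (16 * x)) * besselK((4 * k + 1)^2 / (16 * x), 0.25)
  min(1, max(0, sum(term) / (pi * sqrt(x))))
}

#' Two-sample Cramer-von Mises test
#'
#' Compares the pooled axis samples of two conditions. Statistic per
#' Anderson (1962): `T = U / (n m N) - (4 m n - 1) / (6 N)` with
#' `U = n sum_i (r_i - i)^2 + m sum_j (s_j - j)^2` over the pooled ranks;
#' the p-value uses the asymptotic limiting distribution of the
#' criterion.
#'
#' @param map_a,map_b `polarity_map` objects or numeric sample vectors.
#' @return list(statistic, p_value, n, m, method).
#' @export
condition_test <- function(map_a, map_b) {
  x <- if (inherits(map_a, "polarity_map")) unlist(map_a$per_cell_axis_samples) else map_a
  y <- if (inherits(map_b, "polarity_map")) unlist(map_b$per_cell_axis_samples) else map_b
  n <- as.numeric(length(x)); m <- as.numeric(length(y))  # avoid int overflow
  if (n < 10 || m < 10) stop("condition_test: need >= 10 samples per condition")
  N <- n + m
  rk <- rank(c(x, y), ties.method = "average")
  r <- sort(rk[seq_len(n)]); s <- sort(rk[n + seq_len(m)])
  U <- n * sum((r - seq_len(n))^2) + m * sum((s - seq_len(m))^2)
  T <- U / (n * m * N) - (4 * m * n - 1) / (6 * N)
  p <- 1 - .cvm_limit_cdf(T)
  list(statistic = T, p_value = min(max(p, 0), 1), n = n, m = m,
       method = "two-sample Cramer-von Mises (asymptotic)")
}
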