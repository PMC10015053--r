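# Low-level image primitives shared by the assay modules.
#
# Conventions (repo-wide): images are numeric matrices indexed [row, col];
# pixel coordinates are 0-based with x = col - 1, y = row - 1 and pixel
# centres at integer positions. Connectivity is 8-connected everywhere.

#' @keywords internal
clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

#' Separable Gaussian smoothing with replicate padding
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `sigma <= 0` returns
#'   `img` unchanged.
#' @return smoothed matrix of the same shape.
#' @keywords internal
smooth_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {          # rows
    out <- out + k[j] * img[clamp_idx(seq_len(nr) + (j - r - 1L), nr), , drop = FALSE]
  }
  out2 <- matrix(0, nr, nc)
  for (j in seq_along(k)) {          # cols
    out2 <- out2 + k[j] * out[, clamp_idx(seq_len(nc) + (j - r - 1L), nc), drop = FALSE]
  }
  out2
}

#' Otsu threshold
#'
#' Maximises between-class variance on a 256-bin histogram of the input
#' values. Returns a threshold on the original intensity scale; pixels
#' strictly above it are foreground.
#'
#' @param v numeric vector of intensities.
#' @keywords internal
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("otsu_threshold: no finite values")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)             # flat input: everything one class
  nb <- 256L
  h <- tabulate(pmin(as.integer((v - lo) / (hi - lo) * nb) + 1L, nb), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(nb) - 0.5) / nb
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  denom <- omega * (1 - omega)
  sb <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  kstar <- which.max(sb)
  lo + (kstar / nb) * (hi - lo)
}

# 8-neighbourhood row/col offsets
.nbr8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Connected-component labelling (8-connected)
#'
#' Iterative minimum-label propagation; components receive labels
#' 1..n in order of their smallest column-major pixel index.
#'
#' @param bin logical matrix (TRUE = foreground).
#' @return integer matrix, 0 = background.
#' @keywords internal
label_components <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  lab[bin] <- seq_len(sum(bin))
  idlab <- matrix(0L, nr, nc)
  idlab[bin] <- which(bin)           # propagate minimal pixel index instead
  lab <- idlab
  repeat {
    new <- lab
    for (k in seq_len(nrow(.nbr8))) {
      dr <- .nbr8[k, 1L]; dc <- .nbr8[k, 2L]
      rs <- clamp_idx(seq_len(nr) + dr, nr)
      cs <- clamp_idx(seq_len(nc) + dc, nc)
      sh <- lab[rs, cs, drop = FALSE]
      upd <- bin & sh > 0L & (sh < new | new == 0L)
      new[upd] <- sh[upd]
    }
    new[!bin] <- 0L
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0L]))
  out <- matrix(0L, nr, nc)
  out[lab > 0L] <- match(lab[lab > 0L], ids)
  out
}

#' Region properties of a label matrix
#'
#' @param lab integer label matrix.
#' @param img optional intensity matrix for weighted centroids / mass.
#' @return data.frame with label, area (px), centroid x/y (0-based px,
#'   intensity-weighted when `img` given) and mass (summed intensity).
#' @keywords internal
region_props <- function(lab, img = NULL) {
  fg <- which(lab > 0L)
  if (length(fg) == 0L)
    return(data.frame(label = integer(), area = integer(),
                      x = numeric(), y = numeric(), mass = numeric()))
  l <- lab[fg]
  rc <- arrayInd(fg, dim(lab))
  y <- rc[, 1L] - 1; x <- rc[, 2L] - 1
  w <- if (is.null(img)) rep(1, length(fg)) else img[fg]
  area <- as.vector(tapply(rep(1L, length(fg)), l, sum))
  mass <- as.vector(tapply(w, l, sum))
  cx <- as.vector(tapply(w * x, l, sum)) / mass
  cy <- as.vector(tapply(w * y, l, sum)) / mass
  data.frame(label = sort(unique(l)), area = area, x = cx, y = cy, mass = mass)
}

#' Strict 8-neighbourhood local maxima above a threshold
#'
#' Plateaus are collapsed to the centroid pixel of each plateau
#' component so one marker is returned per maximum.
#'
#' @return data.frame with 0-based x, y and the peak value.
#' @keywords internal
local_maxima <- function(img, threshold = -Inf, mask = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  ge <- matrix(TRUE, nr, nc)
  for (k in seq_len(nrow(.nbr8))) {
    dr <- .nbr8[k, 1L]; dc <- .nbr8[k, 2L]
    rs <- clamp_idx(seq_len(nr) + dr, nr)
    cs <- clamp_idx(seq_len(nc) + dc, nc)
    sh <- img[rs, cs, drop = FALSE]
    # replicate padding compares border pixels with themselves: harmless
    ge <- ge & (img >= sh)
  }
  cand <- ge & img > threshold
  if (!is.null(mask)) cand <- cand & mask
  if (!any(cand)) return(data.frame(x = numeric(), y = numeric(), value = numeric()))
  lab <- label_components(cand)
  pr <- region_props(lab)
  data.frame(x = round(pr$x), y = round(pr$y),
             value = img[cbind(round(pr$y) + 1, round(pr$x) + 1)])
}

#' Central-difference gradients
#' @return list(gx, gy) matrices (d/dx along columns, d/dy along rows).
#' @keywords internal
image_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- (img[, clamp_idx(seq_len(nc) + 1L, nc), drop = FALSE] -
         img[, clamp_idx(seq_len(nc) - 1L, nc), drop = FALSE]) / 2
  gy <- (img[clamp_idx(seq_len(nr) + 1L, nr), , drop = FALSE] -
         img[clamp_idx(seq_len(nr) - 1L, nr), , drop = FALSE]) / 2
  list(gx = gx, gy = gy)
}

#' Perimeter of a polygon given as an n x 2 matrix of vertices
#' @param closed close the ring (default TRUE).
#' @keywords internal
polygon_perimeter <- function(p, closed = TRUE) {
  if (closed) p <- rbind(p, p[1L, , drop = FALSE])
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

#' Convex hull of points as a closed polygon matrix
#' @keywords internal
convex_hull_polygon <- function(pts) {
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  pts[h, , drop = FALSE]
}
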