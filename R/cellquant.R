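# Scalar per-cell quantifications: YAP-style nuclear/cytoplasmic ratio,
# heterochromatin dots per nuclear area, focal-adhesion counts, actin
# structure-tensor coherency, and the spreading ratio.

# background estimate: median intensity outside the cell mask (robust
# default; the original acquisition backgrounds are unspecified)
.background_level <- function(img, cell_mask, background) {
  if (is.numeric(background)) return(background)
  out <- img[!cell_mask]
  if (length(out) == 0L) return(0)
  stats::median(out)
}

#' Nuclear / cytoplasmic intensity ratio
#'
#' Mean background-subtracted intensity inside the nucleus divided by the
#' mean over the cytoplasm (cell minus nucleus).
#'
#' @param signal intensity matrix. @param nucleus_mask,cell_mask logical
#'   matrices or `label_mask`s. @param background `"outside-median"`
#'   (default) or a numeric level.
#' @return the ratio (scalar).
#' @export
nc_ratio <- function(signal, nucleus_mask, cell_mask, background = "outside-median") {
  if (inherits(nucleus_mask, "label_mask")) nucleus_mask <- nucleus_mask$labels > 0L
  if (inherits(cell_mask, "label_mask")) cell_mask <- cell_mask$labels > 0L
  cyto <- cell_mask & !nucleus_mask
  if (!any(cyto)) stop("nc_ratio: empty cytoplasm region")
  if (!any(nucleus_mask)) stop("nc_ratio: empty nucleus mask")
  bg <- .background_level(signal, cell_mask, background)
  num <- mean(signal[nucleus_mask]) - bg
  den <- mean(signal[cyto]) - bg
  if (den <= 0)
    stop("nc_ratio: cytoplasm mean <= 0 after background subtraction, ",
         "ratio undefined")
  num / den
}

#' Fluorescent dot density within a nucleus
#'
#' Dots are local intensity maxima above a threshold; above-threshold
#' pixels are split between dots by nearest-marker assignment (a
#' marker-based watershed simplification adequate for separated foci).
#' Density is the summed (background-subtracted) dot intensity divided by
#' the nuclear area in um^2; the dot count is also reported.
#'
#' @param signal intensity matrix. @param nucleus_mask logical matrix or
#'   `label_mask`. @param pixel_size_um um per pixel (from the mask when a
#'   `label_mask`). @param threshold_mode `"otsu"` or `"absolute"`;
#' @param threshold absolute threshold value.
#' @param smooth_sigma pre-smoothing for maxima detection (px).
#' @return list(n_dots, total_dot_intensity, density_per_um2, area_um2).
#' @export
dot_density <- function(signal, nucleus_mask, pixel_size_um = NULL,
                        threshold_mode = c("otsu", "absolute"), threshold = NULL,
                        smooth_sigma = 1) {
  threshold_mode <- match.arg(threshold_mode)
  if (inherits(nucleus_mask, "label_mask")) {
    if (is.null(pixel_size_um)) pixel_size_um <- nucleus_mask$pixel_size_um
    nucleus_mask <- nucleus_mask$labels > 0L
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 1.0
  area <- sum(nucleus_mask) * pixel_size_um^2
  if (area <= 0) stop("dot_density: zero-area nucleus")
  vals <- signal[nucleus_mask]
  thr <- if (threshold_mode == "otsu") otsu_threshold(vals) else {
    if (is.null(threshold)) stop("dot_density: absolute mode needs threshold")
    threshold
  }
  fg <- nucleus_mask & signal > thr
  if (!any(fg))
    return(list(n_dots = 0L, total_dot_intensity = 0, density_per_um2 = 0,
                area_um2 = area))
  sm <- smooth_gaussian(signal, smooth_sigma)
  mx <- local_maxima(sm, threshold = thr, mask = fg)
  n_dots <- nrow(mx)
  total <- sum(signal[fg] - thr)
  list(n_dots = n_dots, total_dot_intensity = total,
       density_per_um2 = total / area, area_um2 = area)
}

#' Count focal adhesions
#'
#' Connected components (8-connected) of above-threshold vinculin signal
#' inside the cell mask, kept when their area is >= `min_area_um2`
#' (inclusive).
#'
#' @param vinculin intensity matrix. @param cell_mask logical matrix or
#'   `label_mask`. @param min_area_um2 minimum component area (default
#'   0.25 um^2). @param pixel_size_um um per pixel.
#' @param threshold_mode `"otsu"` (within the cell mask) or `"absolute"`.
#' @param threshold absolute threshold value.
#' @return integer count.
#' @export
count_focal_adhesions <- function(vinculin, cell_mask, min_area_um2 = 0.25,
                                  pixel_size_um = NULL,
                                  threshold_mode = c("otsu", "absolute"),
                                  threshold = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (inherits(cell_mask, "label_mask")) {
    if (is.null(pixel_size_um)) pixel_size_um <- cell_mask$pixel_size_um
    cell_mask <- cell_mask$labels > 0L
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 1.0
  if (!any(cell_mask)) stop("count_focal_adhesions: empty cell mask")
  vals <- vinculin[cell_mask]
  if (max(vals) <= min(vals)) return(0L)
  thr <- if (threshold_mode == "otsu") otsu_threshold(vals) else {
    if (is.null(threshold)) stop("count_focal_adhesions: absolute mode needs threshold")
    threshold
  }
  bin <- cell_mask & vinculin > thr
  if (!any(bin)) return(0L)
  lab <- label_components(bin)
  areas <- tabulate(lab[lab > 0L]) * pixel_size_um^2
  sum(areas >= min_area_um2)
}

#' Actin coherency from the image structure tensor
#'
#' Per pixel the structure tensor is the Gaussian-smoothed outer product
#' of the intensity gradient (scale `tensor_sigma`); coherency is the
#' eigenvalue anisotropy `(l1 - l2) / (l1 + l2)` in [0, 1], averaged over
#' mask pixels with non-zero tensor trace. 1 = perfectly aligned
#' filaments, 0 = isotropic texture.
#'
#' @param actin intensity matrix. @param cell_mask logical matrix or
#'   `label_mask`. @param tensor_sigma smoothing scale in px (default 2).
#' @return mean coherency (scalar in [0, 1]).
#' @export
actin_coherency <- function(actin, cell_mask, tensor_sigma = 2) {
  if (inherits(cell_mask, "label_mask")) cell_mask <- cell_mask$labels > 0L
  if (sum(cell_mask) < (2 * ceiling(3 * tensor_sigma) + 1)^2)
    stop("actin_coherency: mask smaller than the tensor support")
  g <- image_gradients(actin)
  jxx <- smooth_gaussian(g$gx * g$gx, tensor_sigma)
  jyy <- smooth_gaussian(g$gy * g$gy, tensor_sigma)
  jxy <- smooth_gaussian(g$gx * g$gy, tensor_sigma)
  tr <- jxx + jyy
  # (l1 - l2) = sqrt((jxx - jyy)^2 + 4 jxy^2) for a symmetric 2x2 tensor
  dif <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  ok <- cell_mask & tr > 0
  if (!any(ok)) stop("actin_coherency: flat image, coherency undefined")
  mean(dif[ok] / tr[ok])
}

#' Cell spreading ratio
#'
#' Area at t1 over area at t0 (e.g. 30 min after attachment over the
#' moment of attachment).
#'
#' @param mask_t0,mask_t1 logical matrices or `label_mask`s.
#' @return the ratio (scalar).
#' @export
spreading_ratio <- function(mask_t0, mask_t1) {
  if (inherits(mask_t0, "label_mask")) mask_t0 <- mask_t0$labels > 0L
  if (inherits(mask_t1, "label_mask")) mask_t1 <- mask_t1$labels > 0L
  a0 <- sum(mask_t0)
  if (a0 == 0) stop("spreading_ratio: empty t0 mask")
  sum(mask_t1) / a0
}
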