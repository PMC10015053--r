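# Spectral (ratiometric) FRET readout of the nuclear-envelope tension
# sensor. The sensor carries a cpCerulean donor (~480 nm) and cpVenus
# acceptor (~530 nm); emission is sampled every 10 nm from 460 to 600 nm.
# The inverted FRET index is the donor/acceptor peak ratio: the higher
# the index, the less energy transfer, i.e. the more extended the sensor
# and the higher the envelope tension.

#' Emission spectrum of a labelled region
#'
#' Per-channel mean over the region's pixels, minus the per-channel mean
#' over a designated cell-free background region, clamped at zero. With
#' no background label the subtraction is skipped (message logged).
#'
#' @param stack spectral `image_stack`.
#' @param mask `label_mask` sharing the stack's spatial shape.
#' @param label region label. @param background_label background region
#'   label, or `NA` to skip subtraction.
#' @return object of class `emission_spectrum`:
#'   data.frame(wavelength_nm, intensity) with attr `region`.
#' @export
extract_spectrum <- function(stack, mask, label, background_label = NA) {
  stopifnot(inherits(stack, "image_stack"), stack$role == "spectral",
            inherits(mask, "label_mask"))
  pix <- which(mask$labels == label)
  if (length(pix) == 0L) stop("extract_spectrum: empty region for label ", label)
  nc <- n_planes(stack)
  vals <- numeric(nc); bg <- numeric(nc)
  bgpix <- if (!is.na(background_label)) which(mask$labels == background_label) else integer()
  if (!is.na(background_label) && length(bgpix) == 0L) {
    message("extract_spectrum: background label ", background_label,
            " empty; skipping subtraction")
  }
  for (ci in seq_len(nc)) {
    plane <- stack_plane(stack, ci)
    vals[ci] <- mean(plane[pix])
    if (length(bgpix)) bg[ci] <- mean(plane[bgpix])
  }
  structure(data.frame(wavelength_nm = stack$channel_wavelengths_nm,
                       intensity = pmax(vals - bg, 0)),
            region = label, class = c("emission_spectrum", "data.frame"))
}

#' Inverted FRET index (donor/acceptor peak ratio)
#'
#' The peak is the maximum sampled channel within a window around each
#' band centre (no curve fitting -- the acquisition grid is 10 nm).
#' Higher index = higher envelope tension.
#'
#' @param spectrum `emission_spectrum` (or data.frame with
#'   wavelength_nm/intensity columns).
#' @param donor_window,acceptor_window wavelength windows, nm.
#' @return list(value, donor_peak_nm, acceptor_peak_nm, region).
#' @export
inverted_fret_index <- function(spectrum, donor_window = c(470, 490),
                                acceptor_window = c(520, 540)) {
  wl <- spectrum$wavelength_nm; it <- spectrum$intensity
  din <- wl >= donor_window[1L] & wl <= donor_window[2L]
  ain <- wl >= acceptor_window[1L] & wl <= acceptor_window[2L]
  if (!any(din) || !any(ain))
    stop("inverted_fret_index: window contains no sampled wavelength")
  dpk <- max(it[din]); apk <- max(it[ain])
  if (apk <= 0) stop("inverted_fret_index: acceptor peak is zero, index undefined")
  list(value = dpk / apk,
       donor_peak_nm = wl[din][which.max(it[din])],
       acceptor_peak_nm = wl[ain][which.max(it[ain])],
       region = attr(spectrum, "region"))
}

#' Per-cell inverted FRET index table
#'
#' One index per labelled nuclear-envelope region. Per-region failures
#' (e.g. zero acceptor peak) become missing rows and are logged; the
#' batch never aborts. Mean spectra are ratioed by default
#' (spectrum-then-ratio); `per_pixel = TRUE` instead ratios per pixel and
#' averages the pixel indices over the region.
#'
#' @param stack spectral `image_stack`. @param ne_mask `label_mask` of NE
#'   regions. @param background_label cell-free region label or `NA`.
#' @param donor_window,acceptor_window peak search windows, nm.
#' @param per_pixel ratio per pixel then average (default FALSE).
#' @return data.frame(cell, index, donor_peak_nm, acceptor_peak_nm) with
#'   attr `meta` holding median/quartile summary statistics.
#' @export
fret_per_cell <- function(stack, ne_mask, background_label = NA,
                          donor_window = c(470, 490),
                          acceptor_window = c(520, 540), per_pixel = FALSE) {
  stopifnot(inherits(stack, "image_stack"), stack$role == "spectral")
  labs <- setdiff(sort(unique(as.vector(ne_mask$labels))), 0L)
  if (!is.na(background_label)) labs <- setdiff(labs, background_label)
  if (length(labs) == 0L) stop("fret_per_cell: no labelled NE regions")
  wl <- stack$channel_wavelengths_nm
  nc <- length(wl)
  labvec <- as.vector(ne_mask$labels)
  sel <- labvec %in% labs
  grp <- factor(labvec[sel], levels = labs)
  # per-region per-channel means in one pass per channel
  m <- matrix(0, length(labs), nc)          # regions x channels
  bg <- numeric(nc)
  bgpix <- if (!is.na(background_label)) which(labvec == background_label) else integer()
  cnt <- as.vector(table(grp))
  for (ci in seq_len(nc)) {
    plane <- as.vector(stack_plane(stack, ci))
    m[, ci] <- rowsum(plane[sel], grp)[, 1L] / cnt
    if (length(bgpix)) bg[ci] <- mean(plane[bgpix])
  }
  din <- wl >= donor_window[1L] & wl <= donor_window[2L]
  ain <- wl >= acceptor_window[1L] & wl <= acceptor_window[2L]
  if (!any(din) || !any(ain)) stop("fret_per_cell: empty peak window")
  idx <- rep(NA_real_, length(labs))
  dnm <- rep(NA_real_, length(labs)); anm <- rep(NA_real_, length(labs))
  if (per_pixel) {
    arr <- stack$pixels
    for (k in seq_along(labs)) {
      pix <- which(ne_mask$labels == labs[k])
      spc <- matrix(0, length(pix), nc)
      for (ci in seq_len(nc))
        spc[, ci] <- pmax(stack_plane(stack, ci)[pix] - bg[ci], 0)
      dpk <- apply(spc[, din, drop = FALSE], 1L, max)
      apk <- apply(spc[, ain, drop = FALSE], 1L, max)
      ok <- apk > 0
      if (!any(ok)) { message("fret_per_cell: region ", labs[k], " undefined"); next }
      idx[k] <- mean(dpk[ok] / apk[ok])
      dnm[k] <- wl[din][which.max(colMeans(spc[, din, drop = FALSE]))]
      anm[k] <- wl[ain][which.max(colMeans(spc[, ain, drop = FALSE]))]
    }
  } else {
    spec <- sweep(m, 2L, bg)
    spec[spec < 0] <- 0
    dpk <- apply(spec[, din, drop = FALSE], 1L, max)
    apk <- apply(spec[, ain, drop = FALSE], 1L, max)
    bad <- apk <= 0
    if (any(bad))
      message("fret_per_cell: ", sum(bad), " region(s) with zero acceptor peak dropped")
    idx[!bad] <- dpk[!bad] / apk[!bad]
    dnm <- wl[din][apply(spec[, din, drop = FALSE], 1L, which.max)]
    anm <- wl[ain][apply(spec[, ain, drop = FALSE], 1L, which.max)]
  }
  out <- data.frame(cell = labs, index = idx, donor_peak_nm = dnm,
                    acceptor_peak_nm = anm)
  ok <- is.finite(out$index)
  attr(out, "meta") <- list(n = sum(ok),
                            median = stats::median(out$index[ok]),
                            q1 = unname(stats::quantile(out$index[ok], 0.25)),
                            q3 = unname(stats::quantile(out$index[ok], 0.75)))
  out
}
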