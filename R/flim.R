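# FLIM chromatin-compaction readout. Histone H2B carries a GFP donor and
# mCherry acceptor; when chromatin compacts, nucleosome proximity enables
# FRET and shortens the donor lifetime. The readout is therefore a single
# "overall lifetime" per region: higher lifetime = lower compaction.
# Lifetimes are estimated by maximum likelihood for a mono-exponential
# decay truncated to the acquisition window.

#' Decay histogram container
#'
#' @param bin_edges_ns uniform bin edges (length n_bins + 1), first edge 0.
#' @param counts non-negative integer photon counts per bin.
#' @param region_id identifier carried through to results.
#' @return object of class `decay_histogram`.
#' @export
decay_histogram <- function(bin_edges_ns, counts, region_id = 1L) {
  stopifnot(length(bin_edges_ns) == length(counts) + 1L)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("decay_histogram: counts must be non-negative integers")
  widths <- diff(bin_edges_ns)
  if (max(abs(widths - widths[1L])) > 1e-9 * widths[1L])
    stop("decay_histogram: bins must be uniform")
  structure(list(bin_edges_ns = bin_edges_ns, counts = as.numeric(counts),
                 window_ns = bin_edges_ns[length(bin_edges_ns)],
                 region_id = region_id),
            class = "decay_histogram")
}

# mean of an exponential(tau) truncated to [0, T]
.trunc_exp_mean <- function(tau, T) {
  r <- T / tau
  # stable for large r (plain exp underflows harmlessly) and small r
  tau - T * exp(-r) / (1 - exp(-r))
}

#' Fit a mono-exponential lifetime from a decay histogram
#'
#' Maximum-likelihood estimate for an exponential truncated to the
#' acquisition window `[0, T]`: the MLE solves
#' `mean(arrivals) = tau - T exp(-T/tau) / (1 - exp(-T/tau))`,
#' with arrivals represented by bin midpoints. The right-hand side is
#' strictly increasing in tau and approaches T/2, so a sample mean at or
#' above T/2 is non-identifiable. Solved monotonically (uniroot) to
#' relative tolerance 1e-6.
#'
#' @param hist `decay_histogram`.
#' @param photon_floor minimum total photons required (default 100).
#' @return list(tau_ns, n_photons, loglik, mean_arrival_ns, region_id).
#' @export
fit_lifetime <- function(hist, photon_floor = 100) {
  stopifnot(inherits(hist, "decay_histogram"))
  n <- sum(hist$counts)
  if (n < photon_floor)
    stop("fit_lifetime: insufficient signal (", n, " photons < floor ",
         photon_floor, ")")
  T <- hist$window_ns
  mids <- (hist$bin_edges_ns[-1L] + hist$bin_edges_ns[-length(hist$bin_edges_ns)]) / 2
  mbar <- sum(hist$counts * mids) / n
  if (mbar >= T / 2)
    stop("fit_lifetime: sample mean >= T/2, no decay within window ",
         "(non-identifiable)")
  if (sum(hist$counts > 0) == 1L)
    stop("fit_lifetime: all photons in one bin, degenerate fit")
  f <- function(tau) .trunc_exp_mean(tau, T) - mbar
  lo <- max(mbar / 2, T * 1e-6)
  while (f(lo) > 0) lo <- lo / 2
  hi <- T
  while (f(hi) < 0) hi <- hi * 2
  tau <- stats::uniroot(f, c(lo, hi), tol = 1e-6 * mbar)$root
  ll <- -n * log(tau * (1 - exp(-T / tau))) - n * mbar / tau
  list(tau_ns = tau, n_photons = n, loglik = ll, mean_arrival_ns = mbar,
       region_id = hist$region_id)
}

#' Per-region lifetimes from pooled photon data
#'
#' Photons are pooled within each labelled region before fitting
#' ("overall lifetime" readout; pool-then-fit is stable at low counts).
#' Input is either a decay table with per-region histograms
#' (`region_id, bin_start_ns, bin_end_ns, counts`) or per-pixel photon
#' arrivals (`x, y, arrival_ns`, 0-based pixel coords) plus a
#' `label_mask`. Regions below the photon floor become missing rows and
#' are logged; the batch never aborts.
#'
#' @param decays decay table or photon table (see above).
#' @param mask `label_mask`, required for photon-table input.
#' @param window_ns acquisition window for photon-table input.
#' @param n_bins histogram bins for photon-table input.
#' @param photon_floor minimum pooled photons per region.
#' @return data.frame(region_id, tau_ns, n_photons) with attr `meta`
#'   (group median/quartiles of tau).
#' @export
lifetime_per_region <- function(decays, mask = NULL, window_ns = NULL,
                                n_bins = 256L, photon_floor = 100) {
  hists <- list()
  if (all(c("region_id", "bin_start_ns", "bin_end_ns", "counts") %in% names(decays))) {
    for (rid in sort(unique(decays$region_id))) {
      d <- decays[decays$region_id == rid, ]
      d <- d[order(d$bin_start_ns), ]
      hists[[as.character(rid)]] <-
        decay_histogram(c(d$bin_start_ns, d$bin_end_ns[nrow(d)]), d$counts,
                        region_id = rid)
    }
  } else if (all(c("x", "y", "arrival_ns") %in% names(decays))) {
    if (is.null(mask)) stop("lifetime_per_region: photon input needs a mask")
    if (is.null(window_ns)) window_ns <- max(decays$arrival_ns)
    lab <- mask$labels[cbind(decays$y + 1L, decays$x + 1L)]
    for (rid in setdiff(sort(unique(lab)), 0L)) {
      arr <- decays$arrival_ns[lab == rid]
      edges <- seq(0, window_ns, length.out = n_bins + 1L)
      counts <- tabulate(pmin(findInterval(arr, edges, rightmost.closed = TRUE),
                              n_bins), nbins = n_bins)
      hists[[as.character(rid)]] <- decay_histogram(edges, counts, region_id = rid)
    }
  } else stop("lifetime_per_region: unrecognised input columns")
  res <- lapply(hists, function(h) {
    tryCatch(fit_lifetime(h, photon_floor = photon_floor),
             error = function(e) {
               message("lifetime_per_region: region ", h$region_id, " skipped: ",
                       conditionMessage(e))
               NULL
             })
  })
  out <- data.frame(
    region_id = vapply(hists, function(h) h$region_id, numeric(1L)),
    tau_ns = vapply(res, function(r) if (is.null(r)) NA_real_ else r$tau_ns, numeric(1L)),
    n_photons = vapply(hists, function(h) sum(h$counts), numeric(1L)))
  rownames(out) <- NULL
  ok <- is.finite(out$tau_ns)
  attr(out, "meta") <- list(n = sum(ok),
                            median = stats::median(out$tau_ns[ok]),
                            q1 = unname(stats::quantile(out$tau_ns[ok], 0.25)),
                            q3 = unname(stats::quantile(out$tau_ns[ok], 0.75)))
  out
}
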