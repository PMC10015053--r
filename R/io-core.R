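# Core containers and file plumbing: ImageStack / LabelMask constructors,
# TIFF-backed stack reading with sidecar metadata, key-value configuration,
# and JSON/CSV result records.

#' ImageStack: a time-, wavelength- or channel-indexed greyscale stack
#'
#' @param pixels numeric array `c(n_planes, h, w)` (a matrix is promoted to
#'   one plane); all values must be finite and >= 0.
#' @param role one of `"time"`, `"spectral"`, `"multichannel"`.
#' @param pixel_size_um micrometres per pixel; defaults to 1 with a warning
#'   when missing.
#' @param frame_interval_s frame spacing in seconds (time role only).
#' @param channel_wavelengths_nm strictly increasing emission centres
#'   (spectral role only), one per plane.
#' @param channel_names optional names (multichannel role).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(pixels, role = c("time", "spectral", "multichannel"),
                        pixel_size_um = NULL, frame_interval_s = NULL,
                        channel_wavelengths_nm = NULL, channel_names = NULL) {
  role <- match.arg(role)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(1L, dim(pixels)))
  if (length(dim(pixels)) != 3L)
    stop("image_stack: pixels must be a matrix or 3D array (plane, y, x)")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("image_stack: intensities must be finite and >= 0")
  if (is.null(pixel_size_um)) {
    warning("image_stack: missing pixel size, falling back to 1.0 um/px")
    pixel_size_um <- 1.0
  }
  stopifnot(pixel_size_um > 0)
  if (role == "spectral") {
    if (is.null(channel_wavelengths_nm))
      stop("image_stack: spectral role requires channel_wavelengths_nm")
    if (!is.null(frame_interval_s))
      stop("image_stack: spectral stacks cannot carry frame_interval_s")
    if (length(channel_wavelengths_nm) != dim(pixels)[1L])
      stop("image_stack: wavelength count (", length(channel_wavelengths_nm),
           ") != plane count (", dim(pixels)[1L], ")")
    if (any(diff(channel_wavelengths_nm) <= 0))
      stop("image_stack: wavelengths must be strictly increasing")
  } else if (role == "time") {
    if (!is.null(channel_wavelengths_nm))
      stop("image_stack: time stacks cannot carry wavelengths")
    if (is.null(frame_interval_s)) frame_interval_s <- 1.0
    stopifnot(frame_interval_s > 0)
  }
  structure(list(pixels = pixels, role = role,
                 axis_order = c(switch(role, time = "time", "channel"), "y", "x"),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = if (role == "time") frame_interval_s,
                 channel_wavelengths_nm = channel_wavelengths_nm,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack role=%s planes=%d %dx%d px @%.3g um/px>\n",
              x$role, d[1L], d[2L], d[3L], x$pixel_size_um))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

#' Number of planes in a stack
#' @param x an `image_stack`.
#' @export
n_planes <- function(x) dim(x$pixels)[1L]

#' Extract plane i as a matrix
#' @param x an `image_stack`; @param i plane index.
#' @export
stack_plane <- function(x, i) matrix(x$pixels[i, , ], dim(x$pixels)[2L], dim(x$pixels)[3L])

#' LabelMask: labelled segmentation mask
#'
#' @param labels 2D integer matrix, 0 = background, k > 0 = object k.
#' @param pixel_size_um micrometres per pixel.
#' @export
label_mask <- function(labels, pixel_size_um = 1.0) {
  stopifnot(is.matrix(labels))
  if (any(labels < 0) || any(labels != round(labels)))
    stop("label_mask: labels must be non-negative integers")
  structure(list(labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
                 pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' Read an ImageStack from a multi-page TIFF
#'
#' Metadata (pixel size, frame interval, wavelengths) is taken from a
#' sidecar key-value config file `<path>.meta` when present, or from the
#' `meta` argument; explicit arguments win on conflict.
#'
#' @param path TIFF path.
#' @param role `"time"`, `"spectral"` or `"multichannel"`.
#' @param meta optional named list overriding sidecar values
#'   (`pixel_size_um`, `frame_interval_s`, `channel_wavelengths_nm`).
#' @return `image_stack`.
#' @export
read_stack <- function(path, role = c("time", "spectral", "multichannel"),
                       meta = list()) {
  role <- match.arg(role)
  px <- read_tiff(path)
  side <- list()
  sc <- paste0(path, ".meta")
  if (file.exists(sc)) side <- read_config(sc)
  g <- function(key) if (!is.null(meta[[key]])) meta[[key]] else side[[key]]
  wl <- g("channel_wavelengths_nm")
  if (!is.null(wl)) wl <- as.numeric(wl)
  image_stack(px, role = role,
              pixel_size_um = if (!is.null(g("pixel_size_um"))) as.numeric(g("pixel_size_um")),
              frame_interval_s = if (role == "time" && !is.null(g("frame_interval_s")))
                as.numeric(g("frame_interval_s")),
              channel_wavelengths_nm = if (role == "spectral") wl)
}

#' Read a labelled mask TIFF
#' @param path TIFF path; @param pixel_size_um micrometres per pixel.
#' @export
read_mask <- function(path, pixel_size_um = 1.0) {
  px <- read_tiff(path)
  label_mask(matrix(px[1L, , ], dim(px)[2L], dim(px)[3L]), pixel_size_um)
}

# ---- configuration ---------------------------------------------------------

#' Read a plain-text key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; values holding commas are
#' split into vectors. Keys are returned as a named list of character
#' vectors (callers coerce).
#'
#' @param path config path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("read_config: malformed line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!nzchar(key)) stop("read_config: empty key in line: ", ln)
    out[[key]] <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
  }
  out
}

# registry of assay parameters: every key has a documented default
.assay_defaults <- list(
  seed = 1L,
  pixel_size_um = 1.0,
  frame_interval_s = 0.01,
  frame_interval_min = 10,
  # microrheology / tracking
  msd.max_lag_fraction = 0.25,
  msd.max_disp_um = NA_real_,          # NA = auto (5 x median frame step)
  msd.min_mass = 0,
  msd.threshold_mode = "otsu",
  # fret
  fret.donor_window_nm = c(470, 490),
  fret.acceptor_window_nm = c(520, 540),
  fret.background_label = NA_integer_,
  fret.per_pixel = FALSE,
  # flim
  flim.photon_floor = 100L,
  # morphometry / polarity
  eop.mode = "polygon",
  polarity.quantile = 0.80,
  polarity.grid = c(32L, 32L),
  # cell_quant
  ncratio.background = "outside-median",
  dots.min_distance_px = 2L,
  fa.min_area_um2 = 0.25,
  fa.threshold_mode = "otsu",
  coherency.tensor_sigma = 2,
  # motility
  motility.max_disp_um = 50,
  motility.min_track_len = 12L
)

#' Assemble an assay configuration
#'
#' Starts from documented defaults, overlays a config file, then explicit
#' overrides. Unknown keys are rejected.
#'
#' @param path optional key-value config file.
#' @param overrides named list of parameter overrides.
#' @return named list with class `assay_config`.
#' @export
assay_config <- function(path = NULL, overrides = list()) {
  cfg <- .assay_defaults
  apply_kv <- function(cfg, kv, coerce) {
    for (k in names(kv)) {
      if (!k %in% names(.assay_defaults))
        stop("assay_config: unknown parameter '", k, "'")
      v <- kv[[k]]
      tmpl <- .assay_defaults[[k]]
      if (coerce && is.character(v) && !is.character(tmpl)) {
        v <- if (is.logical(tmpl)) as.logical(v)
             else if (is.integer(tmpl)) as.integer(v)
             else as.numeric(v)
      }
      cfg[[k]] <- v
    }
    cfg
  }
  if (!is.null(path)) cfg <- apply_kv(cfg, read_config(path), coerce = TRUE)
  cfg <- apply_kv(cfg, overrides, coerce = FALSE)
  class(cfg) <- "assay_config"
  cfg
}

# ---- result records --------------------------------------------------------

#' Write a result record to JSON and CSV
#'
#' The record is a data.frame (the tabular part) with optional scalar
#' metadata attached as attribute `meta`. `<path>.csv` holds the table,
#' `<path>.json` the table plus metadata. All numeric content must be
#' finite. Reading back with [read_results()] returns an equal record.
#'
#' @param record data.frame, possibly with `attr(record, "meta")`.
#' @param path output path prefix (no extension).
#' @export
write_results <- function(record, path) {
  stopifnot(is.data.frame(record))
  num <- vapply(record, is.numeric, logical(1L))
  if (any(vapply(record[num], function(col) any(!is.finite(col)), logical(1L))))
    stop("write_results: record contains non-finite values")
  meta <- attr(record, "meta")
  if (!is.null(meta)) {
    mn <- unlist(meta[vapply(meta, is.numeric, logical(1L))], use.names = FALSE)
    if (length(mn) && any(!is.finite(mn)))
      stop("write_results: metadata contains non-finite values")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(record, paste0(path, ".csv"), row.names = FALSE)
  payload <- list(meta = meta, columns = as.list(record))
  jsonlite::write_json(payload, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a result record written by [write_results()]
#' @param path path prefix used at write time.
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cols <- payload$columns
  df <- if (length(cols) == 0L) data.frame() else as.data.frame(cols)
  if (!is.null(payload$meta) && length(payload$meta)) attr(df, "meta") <- payload$meta
  df
}
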