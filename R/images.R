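#' Multi-channel image container
#'
#' A named list of 2D intensity matrices sharing one pixel grid and physical
#' pixel scale. This is the unit of the foci pipeline: typically a Hoechst
#' channel for segmentation, an EGFP channel for expression gating and focus
#' detection, and one or two marker channels (e.g. 53BP1, gamma-H2AX).
#'
#' @param channels named list of numeric matrices, all with identical
#'   dimensions.
#' @param pixel_scale physical pixel size in micrometres per pixel.
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_scale) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("all channels must have identical dimensions")
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L || pixel_scale <= 0)
    stop("pixel_scale must be a positive scalar (um/px)")
  structure(list(channels = channels, pixel_scale = pixel_scale,
                 dim = dims[[1L]]),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  cat(sprintf("<multichannel_image> %d x %d px, %.4g um/px, channels: %s\n",
              x$dim[1L], x$dim[2L], x$pixel_scale,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract one channel from a multi-channel image
#'
#' @param img a [multichannel_image()].
#' @param name channel name.
#' @return The channel's intensity matrix.
#' @export
get_channel <- function(img, name) {
  stopifnot(inherits(img, "multichannel_image"))
  if (!name %in% names(img$channels))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(img$channels), collapse = ", ")))
  img$channels[[name]]
}

#' Time-lapse container
#'
#' A single-channel movie stored as a row x col x frame array with the
#' acquisition frame interval.
#'
#' @param frames numeric array `c(rows, cols, n_frames)`.
#' @param frame_interval seconds between frames.
#' @param pixel_scale micrometres per pixel.
#' @return An object of class `time_lapse`.
#' @export
time_lapse <- function(frames, frame_interval, pixel_scale) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            frame_interval > 0, pixel_scale > 0)
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_scale = pixel_scale, n_frames = dim(frames)[3L]),
            class = "time_lapse")
}

#' @export
print.time_lapse <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<time_lapse> %d x %d px, %d frames @ %.3g s, %.4g um/px\n",
              d[1L], d[2L], d[3L], x$frame_interval, x$pixel_scale))
  invisible(x)
}

#' Frame acquisition times
#'
#' Frame `i` is acquired at `(i - 1) * frame_interval` seconds.
#'
#' @param movie a [time_lapse()].
#' @return Numeric vector of times in seconds, one per frame.
#' @export
frame_times <- function(movie) {
  stopifnot(inherits(movie, "time_lapse"))
  (seq_len(movie$n_frames) - 1) * movie$frame_interval
}

#' Label map container
#'
#' Integer grid of nucleus instance labels: 0 is background, labels run
#' 1..n_labels with no gaps and each label is a single 4-connected component.
#'
#' @param labels integer matrix.
#' @param pixel_scale micrometres per pixel.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, pixel_scale) {
  storage.mode(labels) <- "integer"
  n <- if (length(labels)) max(labels) else 0L
  structure(list(labels = labels, n_labels = as.integer(n),
                 pixel_scale = pixel_scale),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d nuclei\n",
              nrow(x$labels), ncol(x$labels), x$n_labels))
  invisible(x)
}

#' Per-nucleus measurements from a label map
#'
#' @param lm a [label_map()].
#' @return data.frame with one row per nucleus: `nucleus_id`, centroid
#'   (`row`, `col`), `area_px` and `area_um2`.
#' @export
label_map_stats <- function(lm) {
  stopifnot(inherits(lm, "label_map"))
  if (lm$n_labels == 0L)
    return(data.frame(nucleus_id = integer(0), row = numeric(0),
                      col = numeric(0), area_px = integer(0),
                      area_um2 = numeric(0)))
  idx <- which(lm$labels > 0L)
  lab <- lm$labels[idx]
  nr <- nrow(lm$labels)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  area <- tabulate(lab, nbins = lm$n_labels)
  data.frame(
    nucleus_id = seq_len(lm$n_labels),
    row = as.numeric(tapply(r, lab, mean)),
    col = as.numeric(tapply(cc, lab, mean)),
    area_px = area,
    area_um2 = area * lm$pixel_scale^2
  )
}

# ---- TIFF I/O --------------------------------------------------------------
# Stills are written as multi-page TIFF (one page per channel) and movies as
# multi-page TIFF (one page per frame), each with a JSON sidecar recording
# channel names / frame interval and the pixel scale. 32-bit float pages keep
# synthetic intensities exact enough for round-tripping.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-channel image to TIFF
#'
#' Pages hold channels in order; a JSON sidecar (`<path>.json`) records channel
#' names and pixel scale.
#'
#' @param img a [multichannel_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(img, path) {
  stopifnot(inherits(img, "multichannel_image"))
  mx <- max(1, vapply(img$channels, max, numeric(1)))
  pages <- lapply(img$channels, function(ch) ch / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(kind = "multichannel", channel_names = names(img$channels),
         pixel_scale = img$pixel_scale, intensity_scale = mx),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel TIFF written by [write_multichannel_tiff()]
#'
#' Plain multi-page TIFFs from other sources are accepted when `channel_names`
#' and `pixel_scale` are supplied explicitly.
#'
#' @param path TIFF path.
#' @param channel_names optional channel names (defaults to the sidecar).
#' @param pixel_scale optional um/px (defaults to the sidecar).
#' @return A [multichannel_image()].
#' @export
read_multichannel_tiff <- function(path, channel_names = NULL,
                                   pixel_scale = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, collapse_gray)
  scale <- 1
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (is.null(channel_names)) channel_names <- meta$channel_names
    if (is.null(pixel_scale)) pixel_scale <- meta$pixel_scale
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(pages))
  if (is.null(pixel_scale))
    stop("pixel_scale not found in sidecar; supply it explicitly")
  if (length(channel_names) != length(pages))
    stop("channel_names length does not match page count")
  pages <- lapply(pages, function(p) p * scale)
  multichannel_image(setNames(pages, channel_names), pixel_scale)
}

#' Write a time-lapse to multi-page TIFF
#'
#' @param movie a [time_lapse()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_time_lapse_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "time_lapse"))
  mx <- max(1, max(movie$frames))
  pages <- lapply(seq_len(movie$n_frames),
                  function(i) movie$frames[, , i] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(kind = "time_lapse", frame_interval = movie$frame_interval,
         pixel_scale = movie$pixel_scale, intensity_scale = mx),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a time-lapse TIFF written by [write_time_lapse_tiff()]
#'
#' @param path TIFF path.
#' @param frame_interval optional seconds per frame (defaults to the sidecar).
#' @param pixel_scale optional um/px (defaults to the sidecar).
#' @return A [time_lapse()].
#' @export
read_time_lapse_tiff <- function(path, frame_interval = NULL,
                                 pixel_scale = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, collapse_gray)
  scale <- 1
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval
    if (is.null(pixel_scale)) pixel_scale <- meta$pixel_scale
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(frame_interval) || is.null(pixel_scale))
    stop("frame_interval/pixel_scale not found in sidecar; supply explicitly")
  arr <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * scale
  time_lapse(arr, frame_interval, pixel_scale)
}

#' Write a label map to TIFF (plus per-nucleus CSV)
#'
#' Labels are stored as 16-bit grey values (label/65535); the sidecar records
#' `n_labels` and pixel scale so [read_label_map_tiff()] restores integers
#' exactly.
#'
#' @param lm a [label_map()].
#' @param path output TIFF path.
#' @param csv_path optional path for the per-nucleus statistics CSV.
#' @return `path`, invisibly.
#' @export
write_label_map_tiff <- function(lm, path, csv_path = NULL) {
  stopifnot(inherits(lm, "label_map"))
  if (lm$n_labels > 65535L) stop("too many labels for 16-bit storage")
  tiff::writeTIFF(lm$labels / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(kind = "label_map", n_labels = lm$n_labels,
         pixel_scale = lm$pixel_scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    write.csv(label_map_stats(lm), csv_path, row.names = FALSE)
  invisible(path)
}

#' Read a label map written by [write_label_map_tiff()]
#'
#' @param path TIFF path.
#' @param pixel_scale optional um/px override.
#' @return A [label_map()].
#' @export
read_label_map_tiff <- function(path, pixel_scale = NULL) {
  m <- collapse_gray(tiff::readTIFF(path, as.is = FALSE))
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (is.null(pixel_scale)) pixel_scale <- meta$pixel_scale
  }
  if (is.null(pixel_scale))
    stop("pixel_scale not found in sidecar; supply it explicitly")
  label_map(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)),
            pixel_scale)
}

# tiff::readTIFF may return H x W x channels for non-grayscale data; keep the
# first plane (our writers always emit single-plane grayscale).
collapse_gray <- function(x) {
  if (length(dim(x)) == 3L) x[, , 1L] else x
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream index.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}
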