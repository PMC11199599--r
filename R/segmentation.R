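#' Huang's fuzzy-thresholding of an intensity histogram
#'
#' Returns the threshold minimizing Huang's measure of fuzziness. For each
#' candidate threshold `t`, pixels are split at `t` (foreground = levels
#' strictly above `t`, the dark-background convention); each side's fuzzy
#' membership is `u(g) = 1 / (1 + |g - mu_side| / C)` with `C` the occupied
#' intensity range, and the fuzziness is the count-weighted Shannon entropy
#' `sum_g h(g) [-u log u - (1-u) log(1-u)]`. The candidate minimizing this sum
#' is returned; when several candidates tie exactly (e.g. a two-spike
#' histogram, where the measure is flat anywhere between the spikes), the
#' midpoint of the tied run is chosen.
#'
#' @param counts non-negative histogram counts per intensity level.
#' @param levels intensity value of each bin (default `0:(length(counts)-1)`).
#' @return The threshold as an intensity level; foreground is `> threshold`.
#' @export
huang_threshold <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(levels), all(counts >= 0),
            !is.unsorted(levels))
  occ <- which(counts > 0)
  if (length(occ) == 0L || length(unique(levels[occ])) < 2L)
    stop("degenerate histogram: need at least 2 occupied intensity levels")
  first <- occ[1L]; last <- occ[length(occ)]
  C <- levels[last] - levels[first]
  W <- cumsum(counts * levels)
  N <- cumsum(counts)
  Wt <- W[length(W)]; Nt <- N[length(N)]
  cand <- first:(last - 1L)
  S <- vapply(cand, function(k) {
    mu0 <- W[k] / N[k]
    mu1 <- (Wt - W[k]) / (Nt - N[k])
    lo <- seq_len(k); hi <- seq.int(k + 1L, length(counts))
    u <- c(1 / (1 + abs(levels[lo] - mu0) / C),
           1 / (1 + abs(levels[hi] - mu1) / C))
    sum(counts[c(lo, hi)] * fuzzy_entropy(u))
  }, numeric(1))
  tied <- which(S - min(S) <= 1e-10 * max(1, abs(min(S))))
  levels[cand[tied[ceiling(length(tied) / 2)]]]
}

# -u log u - (1 - u) log(1 - u), with 0 log 0 = 0. u in (0, 1].
fuzzy_entropy <- function(u) {
  h <- -u * log(u)
  q <- 1 - u
  pos <- q > 0
  h[pos] <- h[pos] - q[pos] * log(q[pos])
  h
}

#' Huang threshold of an intensity image
#'
#' Bins the image into `n_bins` equal-width bins spanning its range (as an
#' 8-bit acquisition would be histogrammed when `n_bins = 256`) and applies
#' [huang_threshold()]. The returned value is on the image's intensity scale,
#' so the foreground mask `img > threshold` is invariant under positive
#' rescaling of the image.
#'
#' @param img numeric matrix.
#' @param n_bins number of histogram bins (default 256).
#' @return Threshold intensity; foreground is `img > threshold`.
#' @export
huang_threshold_image <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (rng[2L] <= rng[1L])
    stop("degenerate histogram: image has a single intensity level")
  width <- (rng[2L] - rng[1L]) / n_bins
  bin <- pmin(n_bins, floor((img - rng[1L]) / width) + 1L)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- rng[1L] + (seq_len(n_bins) - 0.5) * width
  huang_threshold(counts, mids)
}

#' Segmentation parameters
#'
#' @param min_nucleus_area smallest retained component, px^2 (default 750,
#'   half the area of the smallest default simulated nucleus).
#' @param exclude_border drop nuclei touching the image edge (default `TRUE`;
#'   partial nuclei bias per-cell focus counts).
#' @param watershed_h h-depth for watershed seed suppression on the distance
#'   transform, in distance units (default 2 px).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(min_nucleus_area = 750, exclude_border = TRUE,
                                watershed_h = 2) {
  stopifnot(min_nucleus_area >= 0, watershed_h >= 0)
  structure(list(min_nucleus_area = min_nucleus_area,
                 exclude_border = isTRUE(exclude_border),
                 watershed_h = watershed_h),
            class = "segmentation_params")
}

#' Segment nuclei from a Hoechst channel
#'
#' Foreground by [huang_threshold_image()] (dark background: pixels above the
#' threshold), instance splitting by watershed on the Euclidean distance
#' transform with h-depth seed suppression, followed by enforcement of
#' 4-connected single-component labels, removal of components below
#' `min_nucleus_area`, and (optionally) of border-touching nuclei. Labels are
#' renumbered 1..n in raster order. A blank or constant image yields an empty
#' label map.
#'
#' @param hoechst numeric intensity matrix.
#' @param params a [segmentation_params()].
#' @param pixel_scale micrometres per pixel recorded in the output.
#' @return A [label_map()].
#' @export
segment_nuclei <- function(hoechst, params = segmentation_params(),
                           pixel_scale = 1) {
  stopifnot(is.matrix(hoechst))
  empty <- label_map(matrix(0L, nrow(hoechst), ncol(hoechst)), pixel_scale)
  thr <- tryCatch(huang_threshold_image(hoechst), error = function(e) NULL)
  if (is.null(thr)) return(empty)
  fg <- hoechst > thr
  if (!any(fg)) return(empty)

  dm <- EBImage::distmap(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = params$watershed_h,
                                              ext = 1))
  labels <- split_4connected(ws)
  labels <- drop_small_and_border(labels, params)
  label_map(labels, pixel_scale)
}

# Re-label so every label is one 4-connected component (watershed basins can
# in principle be split by the h-merging); bwlabel is 4-connected.
split_4connected <- function(ws) {
  out <- matrix(0L, nrow(ws), ncol(ws))
  nxt <- 0L
  for (l in seq_len(max(0, max(ws)))) {
    m <- ws == l
    if (!any(m)) next
    cc <- EBImage::imageData(EBImage::bwlabel(m))
    for (k in seq_len(max(cc))) {
      nxt <- nxt + 1L
      out[cc == k] <- nxt
    }
  }
  out
}

drop_small_and_border <- function(labels, params) {
  n <- max(0L, max(labels))
  if (n == 0L) return(labels)
  keep <- rep(TRUE, n)
  area <- tabulate(labels[labels > 0L], nbins = n)
  keep[area < params$min_nucleus_area] <- FALSE
  if (params$exclude_border) {
    border <- unique(c(labels[1L, ], labels[nrow(labels), ],
                       labels[, 1L], labels[, ncol(labels)]))
    keep[border[border > 0L]] <- FALSE
  }
  # renumber survivors in raster order of first pixel
  out <- matrix(0L, nrow(labels), ncol(labels))
  survivors <- which(keep)
  if (length(survivors)) {
    firsts <- vapply(survivors, function(l) which(labels == l)[1L], integer(1))
    survivors <- survivors[order(firsts)]
    for (i in seq_along(survivors)) out[labels == survivors[i]] <- i
  }
  out
}
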