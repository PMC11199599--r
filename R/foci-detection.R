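#' Detection parameters for focus finding
#'
#' @param blur_sigma Gaussian pre-blur sigma in px (default 0.8, a mild blur
#'   that suppresses single-pixel noise without moving 6-px foci).
#' @param prominence explicit prominence for the maxima search, or `NULL` to
#'   estimate it as `prominence_k` times the MAD-based noise SD of the
#'   background (pixels outside all nuclei). When the background is noiseless
#'   (MAD 0), 5% of the channel's dynamic range is used instead.
#' @param prominence_k multiplier on the robust noise SD (default 5).
#' @param size_min,size_max focus area bounds in px^2 (defaults 2 and 50;
#'   50 px^2 is roughly an 8-px-diameter spot, comfortably above a 6-px
#'   focus).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(blur_sigma = 0.8, prominence = NULL,
                             prominence_k = 5, size_min = 2, size_max = 50) {
  stopifnot(blur_sigma >= 0, is.null(prominence) || prominence > 0,
            prominence_k > 0, size_min >= 0, size_min <= size_max)
  structure(list(blur_sigma = blur_sigma, prominence = prominence,
                 prominence_k = prominence_k, size_min = size_min,
                 size_max = size_max), class = "detection_params")
}

#' Gaussian pre-blur
#'
#' Separable Gaussian convolution with symmetric (reflective) boundary
#' handling; kernel truncated at 4 sigma and normalized to unit mass, so a
#' constant image is returned unchanged. `sigma = 0` is the identity.
#'
#' @param channel numeric matrix.
#' @param sigma blur sigma in pixels (>= 0).
#' @return The blurred matrix.
#' @export
preblur <- function(channel, sigma = 0.8) {
  stopifnot(is.matrix(channel), sigma >= 0)
  if (sigma == 0) return(channel)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  out <- convolve_dim1(channel, k, r)
  t(convolve_dim1(t(out), k, r))
}

# 1D convolution along rows with symmetric reflection padding.
convolve_dim1 <- function(m, k, r) {
  n <- nrow(m)
  pad <- c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1L, 1L))
  P <- m[pad, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * P[j:(j + n - 1L), , drop = FALSE]
  out
}

#' Prominence-based local-maxima detection
#'
#' Finds intensity maxima the way interactive spot counters do: a candidate
#' peak is a constant-value plateau with no higher 8-neighbour inside the
#' mask, and it is reported only if it cannot be reached from any
#' higher-ranked peak without descending more than `prominence` below its own
#' value. Peaks are ranked by value (ties broken toward the smaller linear
#' pixel index, so of two equal peaks joined by a shallow saddle exactly one
#' is reported). The highest peak of each connected mask region is always
#' reported unless the region is constant — a uniform image therefore yields
#' no maxima. Plateau peaks are reported at the plateau centroid.
#'
#' Implemented as a single union-find sweep over pixels in decreasing
#' intensity order (the persistence formulation of the flood-fill rule).
#'
#' @param img numeric matrix.
#' @param mask logical matrix restricting the search (default: whole image).
#' @param prominence minimum intensity drop separating a reported maximum
#'   from any higher-ranked maximum (> 0).
#' @return data.frame with one row per accepted maximum: centroid `row`,
#'   `col` (1-based, pixel-center), peak `value`, measured `prominence`
#'   (peak minus its merge saddle; peak minus the region minimum for the
#'   highest peak), `plateau_px`, and `anchor` (linear index of a pixel on
#'   the peak plateau). Rows are ordered by decreasing value.
#' @export
find_maxima <- function(img, mask = NULL, prominence) {
  stopifnot(is.matrix(img), is.numeric(prominence),
            length(prominence) == 1L, prominence > 0)
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  stopifnot(is.logical(mask), identical(dim(mask), dim(img)))
  empty <- data.frame(row = numeric(0), col = numeric(0), value = numeric(0),
                      prominence = numeric(0), plateau_px = integer(0),
                      anchor = integer(0))
  midx <- which(mask)
  if (!length(midx)) return(empty)
  ord <- midx[order(-img[midx], midx)]

  parent <- integer(nr * nc)          # 0 = unprocessed
  cid_at <- integer(nr * nc)          # component id stored at the root pixel
  ncomp <- 0L
  cval <- cmin <- csr <- csc <- numeric(0)
  cidx <- integer(0); cnp <- integer(0); calive <- logical(0)
  acc <- list()

  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }

  for (p in ord) {
    v <- img[p]
    r <- (p - 1L) %% nr + 1L
    cl <- (p - 1L) %/% nr + 1L
    up <- r > 1L; dn <- r < nr; lf <- cl > 1L; rt <- cl < nc
    nbrs <- c(if (up) p - 1L, if (dn) p + 1L,
              if (lf) c(p - nr, if (up) p - nr - 1L, if (dn) p - nr + 1L),
              if (rt) c(p + nr, if (up) p + nr - 1L, if (dn) p + nr + 1L))
    nbrs <- nbrs[parent[nbrs] != 0L]
    if (!length(nbrs)) {
      ncomp <- ncomp + 1L
      parent[p] <- p; cid_at[p] <- ncomp
      cval[ncomp] <- v; cmin[ncomp] <- v
      csr[ncomp] <- r; csc[ncomp] <- cl
      cidx[ncomp] <- p; cnp[ncomp] <- 1L; calive[ncomp] <- TRUE
      next
    }
    roots <- unique(vapply(nbrs, find_root, integer(1)))
    if (length(roots) == 1L) {
      ci <- cid_at[roots]
      parent[p] <- roots
      if (cval[ci] == v) {
        csr[ci] <- csr[ci] + r; csc[ci] <- csc[ci] + cl
        cnp[ci] <- cnp[ci] + 1L
        if (p < cidx[ci]) cidx[ci] <- p
      }
      if (v < cmin[ci]) cmin[ci] <- v
    } else {
      cs <- cid_at[roots]
      o <- order(-cval[cs], cidx[cs])
      win_root <- roots[o[1L]]; wc <- cs[o[1L]]
      for (j in o[-1L]) {
        lc <- cs[j]
        if (cval[lc] == v && cval[wc] == v) {
          # two same-level plateaus joined by p: one plateau
          csr[wc] <- csr[wc] + csr[lc]; csc[wc] <- csc[wc] + csc[lc]
          cnp[wc] <- cnp[wc] + cnp[lc]
          if (cidx[lc] < cidx[wc]) cidx[wc] <- cidx[lc]
        } else {
          pers <- cval[lc] - v
          if (pers > prominence)
            acc[[length(acc) + 1L]] <- c(csr[lc] / cnp[lc], csc[lc] / cnp[lc],
                                         cval[lc], pers, cnp[lc], cidx[lc])
        }
        if (cmin[lc] < cmin[wc]) cmin[wc] <- cmin[lc]
        calive[lc] <- FALSE
        parent[roots[j]] <- win_root
      }
      parent[p] <- win_root
      if (cval[wc] == v) {
        csr[wc] <- csr[wc] + r; csc[wc] <- csc[wc] + cl
        cnp[wc] <- cnp[wc] + 1L
        if (p < cidx[wc]) cidx[wc] <- p
      }
      if (v < cmin[wc]) cmin[wc] <- v
    }
  }
  for (ci in which(calive)) {
    if (cval[ci] > cmin[ci])
      acc[[length(acc) + 1L]] <- c(csr[ci] / cnp[ci], csc[ci] / cnp[ci],
                                   cval[ci], cval[ci] - cmin[ci], cnp[ci],
                                   cidx[ci])
  }
  if (!length(acc)) return(empty)
  m <- do.call(rbind, acc)
  out <- data.frame(row = m[, 1L], col = m[, 2L], value = m[, 3L],
                    prominence = m[, 4L], plateau_px = as.integer(m[, 5L]),
                    anchor = as.integer(m[, 6L]))
  out[order(-out$value, out$anchor), , drop = FALSE]
}

# Area and mean intensity of the region 8-connected to `anchor` with
# intensity >= level, inside the mask.
focus_region_stats <- function(img, mask, anchor, level) {
  nr <- nrow(img)
  keep <- mask & img >= level
  if (!keep[anchor]) return(c(area = 1, mean = img[anchor]))
  visited <- logical(length(img))
  queue <- integer(sum(keep))
  queue[1L] <- anchor; visited[anchor] <- TRUE
  head <- 1L; tailq <- 1L
  total <- 0
  while (head <= tailq) {
    p <- queue[head]; head <- head + 1L
    total <- total + img[p]
    r <- (p - 1L) %% nr + 1L
    cl <- (p - 1L) %/% nr + 1L
    up <- r > 1L; dn <- r < nr; lf <- cl > 1L; rt <- cl < ncol(img)
    nbrs <- c(if (up) p - 1L, if (dn) p + 1L,
              if (lf) c(p - nr, if (up) p - nr - 1L, if (dn) p - nr + 1L),
              if (rt) c(p + nr, if (up) p + nr - 1L, if (dn) p + nr + 1L))
    for (q in nbrs) {
      if (keep[q] && !visited[q]) {
        visited[q] <- TRUE
        tailq <- tailq + 1L
        queue[tailq] <- q
      }
    }
  }
  c(area = tailq, mean = total / tailq)
}

#' Detect foci in one channel, per nucleus
#'
#' Applies the mild Gaussian pre-blur, chooses the prominence (explicit, or
#' `prominence_k` x the MAD noise SD of the background), and runs
#' [find_maxima()] inside each nucleus of the label map. Each focus's area is
#' the set of pixels 8-connected to its peak with intensity above
#' (peak - p/2), clipped to the nucleus, where p is the focus's effective
#' prominence: its measured prominence capped at (peak - median cell
#' intensity) -- the cell median serving as the local background, so an
#' isolated 6-px-FWHM spot gets its FWHM disk (~28 px^2) -- and floored at
#' the detection prominence.
#'
#' @param channel numeric intensity matrix.
#' @param lm a [label_map()].
#' @param params a [detection_params()].
#' @param channel_name recorded in the output.
#' @return data.frame of focus records: `nucleus_id`, `channel`, centroid
#'   `row`/`col`, peak `value`, `prominence` (measured), `area` (px^2) and
#'   `mean_intensity`.
#' @export
detect_foci <- function(channel, lm, params = detection_params(),
                        channel_name = "channel") {
  stopifnot(is.matrix(channel), inherits(lm, "label_map"),
            identical(dim(channel), dim(lm$labels)),
            inherits(params, "detection_params"))
  blurred <- preblur(channel, params$blur_sigma)
  prom <- params$prominence
  if (is.null(prom)) {
    # noise SD from the raw background: the blur shrinks noise but not focus
    # prominence, so k x raw-noise SD keeps a wide margin over noise maxima
    bg <- channel[lm$labels == 0L]
    sdn <- if (length(bg)) mad(bg) else 0
    prom <- params$prominence_k * sdn
    if (prom <= 0) prom <- 0.05 * diff(range(blurred))
    if (prom <= 0) return(empty_foci(channel_name))
  }
  out <- empty_foci(channel_name)
  for (id in seq_len(lm$n_labels)) {
    sel <- which(lm$labels == id)
    if (!length(sel)) next
    nr <- nrow(channel)
    rs <- range((sel - 1L) %% nr + 1L)
    cls <- range((sel - 1L) %/% nr + 1L)
    sub <- blurred[rs[1L]:rs[2L], cls[1L]:cls[2L], drop = FALSE]
    smask <- lm$labels[rs[1L]:rs[2L], cls[1L]:cls[2L], drop = FALSE] == id
    mx <- find_maxima(sub, smask, prom)
    if (!nrow(mx)) next
    med <- stats::median(sub[smask])
    stats <- t(vapply(seq_len(nrow(mx)), function(i) {
      p_eff <- max(prom, min(mx$prominence[i], mx$value[i] - med))
      focus_region_stats(sub, smask, mx$anchor[i], mx$value[i] - p_eff / 2)
    }, numeric(2)))
    out <- rbind(out, data.frame(
      nucleus_id = id, channel = channel_name,
      row = mx$row + rs[1L] - 1, col = mx$col + cls[1L] - 1,
      value = mx$value, prominence = mx$prominence,
      area = stats[, 1L], mean_intensity = stats[, 2L]))
  }
  rownames(out) <- NULL
  out
}

empty_foci <- function(channel_name = character(0)) {
  data.frame(nucleus_id = integer(0),
             channel = character(0), row = numeric(0), col = numeric(0),
             value = numeric(0), prominence = numeric(0), area = numeric(0),
             mean_intensity = numeric(0))
}

#' Filter foci by area
#'
#' Retains foci with `size_min <= area <= size_max`; input order is
#' preserved.
#'
#' @param foci data.frame from [detect_foci()].
#' @param params a [detection_params()].
#' @return The filtered data.frame.
#' @export
filter_foci <- function(foci, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  foci[foci$area >= params$size_min & foci$area <= params$size_max, ,
       drop = FALSE]
}

#' Gate analysis to EGFP-expressing cells
#'
#' A nucleus passes if its mean EGFP intensity exceeds the Huang threshold of
#' the whole EGFP channel (fluorescence above background as set by the auto
#' threshold). If the channel is constant (no expression anywhere), no cell
#' passes and a warning is emitted.
#'
#' @param lm a [label_map()].
#' @param egfp EGFP channel matrix.
#' @return Integer vector of passing nucleus ids (possibly empty).
#' @export
gate_expressing_cells <- function(lm, egfp) {
  stopifnot(inherits(lm, "label_map"), identical(dim(egfp), dim(lm$labels)))
  if (lm$n_labels == 0L) return(integer(0))
  thr <- tryCatch(huang_threshold_image(egfp), error = function(e) {
    warning("no expressing cells: ", conditionMessage(e))
    NULL
  })
  if (is.null(thr)) return(integer(0))
  inside <- lm$labels > 0L
  means <- tapply(egfp[inside], lm$labels[inside], mean)
  ids <- as.integer(names(means))
  sort(ids[means > thr])
}

#' Per-cell focus counts over gated cells
#'
#' Counts foci per gated nucleus (cells with no foci count 0) and the
#' population mean = total foci / number of gated cells. With no gated cells
#' the table is empty and the mean is reported as missing (`NA`), not 0.
#'
#' @param foci data.frame of focus records.
#' @param gated_ids integer vector of nucleus ids included in the analysis.
#' @return `list(per_cell = data.frame(nucleus_id, n_foci), mean_foci,
#'   n_cells)`.
#' @export
count_foci <- function(foci, gated_ids) {
  gated_ids <- sort(unique(as.integer(gated_ids)))
  if (!length(gated_ids))
    return(list(per_cell = data.frame(nucleus_id = integer(0),
                                      n_foci = integer(0)),
                mean_foci = NA_real_, n_cells = 0L))
  n <- vapply(gated_ids, function(id) sum(foci$nucleus_id == id), integer(1))
  list(per_cell = data.frame(nucleus_id = gated_ids, n_foci = n),
       mean_foci = sum(n) / length(gated_ids),
       n_cells = length(gated_ids))
}
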