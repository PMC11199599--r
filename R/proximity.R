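#' Distance-bin thresholds for proximity classification
#'
#' Defaults encode the published bins: overlapping for distances up to 5 px
#' (0.36 um), proximal for 5-15 px (0.36-1.07 um), distant beyond 15 px
#' (1.07 um). The default pixel scale derives from the bins' own 15 px ~
#' 1.07 um correspondence (~0.0713 um/px); measured distances are real-valued,
#' so the integer bins are read as half-open intervals
#' `d <= 5 < d <= 15 < d`.
#'
#' @param overlap_max upper bound of the overlapping bin, px.
#' @param proximal_max upper bound of the proximal bin, px.
#' @param pixel_scale micrometres per pixel used for reporting.
#' @return An object of class `proximity_thresholds`.
#' @export
proximity_thresholds <- function(overlap_max = 5, proximal_max = 15,
                                 pixel_scale = 1.07 / 15) {
  stopifnot(overlap_max > 0, proximal_max > overlap_max, pixel_scale > 0)
  structure(list(overlap_max = overlap_max, proximal_max = proximal_max,
                 pixel_scale = pixel_scale), class = "proximity_thresholds")
}

#' Convert a pixel distance to micrometres
#'
#' @param d distance(s) in pixels.
#' @param pixel_scale micrometres per pixel.
#' @return Distance(s) in micrometres (report to 2 decimals in summaries).
#' @export
pixels_to_um <- function(d, pixel_scale) {
  stopifnot(pixel_scale > 0)
  d * pixel_scale
}

#' Classify a nearest-neighbour distance into proximity bins
#'
#' `overlapping` iff `d <= overlap_max`; `proximal` iff
#' `overlap_max < d <= proximal_max`; `distant` iff `d > proximal_max`. The
#' three classes partition `[0, Inf)`.
#'
#' @param d non-negative distance(s) in pixels.
#' @param thresholds a [proximity_thresholds()].
#' @return Character vector of class labels.
#' @export
classify_proximity <- function(d, thresholds = proximity_thresholds()) {
  stopifnot(inherits(thresholds, "proximity_thresholds"))
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  out <- ifelse(d <= thresholds$overlap_max, "overlapping",
                ifelse(d <= thresholds$proximal_max, "proximal", "distant"))
  out[is.na(d)] <- NA_character_
  out
}

#' Cross-channel nearest-neighbour distances, per nucleus
#'
#' For every focus in the source set, the Euclidean centroid distance to its
#' nearest neighbour among the comparator set's foci *in the same nucleus*
#' (the comparison is directional: source -> comparator). Ties go to the
#' comparator focus appearing first in `foci_b`. Source foci in cells with no
#' comparator foci are labelled `unmatched`.
#'
#' @param foci_a source foci (data.frame with `nucleus_id`, `row`, `col`).
#' @param foci_b comparator foci (same columns).
#' @param thresholds a [proximity_thresholds()].
#' @param comparator_channel name recorded in the output (default: from
#'   `foci_b$channel` if present).
#' @return data.frame of proximity records, one per source focus:
#'   `nucleus_id`, source `row`/`col`, `comparator_channel`,
#'   `nn_distance` (px), `nn_distance_um`, `nn_index` (row index into
#'   `foci_b`), `class_label` in
#'   {overlapping, proximal, distant, unmatched}.
#' @export
nearest_neighbour_distances <- function(foci_a, foci_b,
                                        thresholds = proximity_thresholds(),
                                        comparator_channel = NULL) {
  stopifnot(inherits(thresholds, "proximity_thresholds"))
  if (is.null(comparator_channel))
    comparator_channel <- if (nrow(foci_b) && "channel" %in% names(foci_b))
      as.character(foci_b$channel[1L]) else "comparator"
  n <- nrow(foci_a)
  out <- data.frame(
    nucleus_id = if (n) foci_a$nucleus_id else integer(0),
    row = if (n) foci_a$row else numeric(0),
    col = if (n) foci_a$col else numeric(0),
    comparator_channel = rep(comparator_channel, n),
    nn_distance = rep(NA_real_, n), nn_distance_um = rep(NA_real_, n),
    nn_index = rep(NA_integer_, n),
    class_label = rep("unmatched", n),
    stringsAsFactors = FALSE)
  if (!n) return(out)
  for (i in seq_len(n)) {
    j <- which(foci_b$nucleus_id == foci_a$nucleus_id[i])
    if (!length(j)) next
    dd <- sqrt((foci_b$row[j] - foci_a$row[i])^2 +
               (foci_b$col[j] - foci_a$col[i])^2)
    best <- which.min(dd)   # ties: first (lowest comparator index)
    out$nn_distance[i] <- dd[best]
    out$nn_index[i] <- j[best]
    out$nn_distance_um[i] <- pixels_to_um(dd[best], thresholds$pixel_scale)
    out$class_label[i] <- classify_proximity(dd[best], thresholds)
  }
  out
}

proximity_classes <- c("overlapping", "proximal", "distant")

#' Summarize proximity records per cell and per population
#'
#' Counts and fractions of each class among matched foci per cell, and the
#' population view: mean per-cell count per class and the overall class
#' fractions pooled over matched foci. Unmatched foci are excluded from
#' fractions but reported in their own column.
#'
#' @param records data.frame from [nearest_neighbour_distances()].
#' @param gated_ids optional nucleus ids to include (default: all cells
#'   present in `records`).
#' @return `list(per_cell, population, n_cells)`; `per_cell` has one row per
#'   cell with counts `n_overlapping`/`n_proximal`/`n_distant`/`n_unmatched`
#'   and the matched-focus fractions; `population` has one row per class with
#'   `mean_count_per_cell` and `fraction`.
#' @export
summarize_proximity <- function(records, gated_ids = NULL) {
  if (is.null(gated_ids)) gated_ids <- sort(unique(records$nucleus_id))
  gated_ids <- sort(unique(as.integer(gated_ids)))
  recs <- records[records$nucleus_id %in% gated_ids, , drop = FALSE]
  per_cell <- do.call(rbind, lapply(gated_ids, function(id) {
    r <- recs[recs$nucleus_id == id, , drop = FALSE]
    cnt <- vapply(proximity_classes,
                  function(cl) sum(r$class_label == cl), integer(1))
    matched <- sum(cnt)
    frac <- if (matched > 0) cnt / matched else rep(NA_real_, 3L)
    data.frame(nucleus_id = id,
               n_overlapping = cnt[1L], n_proximal = cnt[2L],
               n_distant = cnt[3L],
               n_unmatched = sum(r$class_label == "unmatched"),
               frac_overlapping = frac[1L], frac_proximal = frac[2L],
               frac_distant = frac[3L])
  }))
  if (is.null(per_cell))
    per_cell <- data.frame(nucleus_id = integer(0), n_overlapping = integer(0),
                           n_proximal = integer(0), n_distant = integer(0),
                           n_unmatched = integer(0),
                           frac_overlapping = numeric(0),
                           frac_proximal = numeric(0),
                           frac_distant = numeric(0))
  total_matched <- sum(per_cell$n_overlapping) + sum(per_cell$n_proximal) +
    sum(per_cell$n_distant)
  population <- data.frame(
    class = proximity_classes,
    mean_count_per_cell = if (nrow(per_cell))
      c(mean(per_cell$n_overlapping), mean(per_cell$n_proximal),
        mean(per_cell$n_distant)) else rep(NA_real_, 3L),
    fraction = if (total_matched > 0)
      c(sum(per_cell$n_overlapping), sum(per_cell$n_proximal),
        sum(per_cell$n_distant)) / total_matched else rep(NA_real_, 3L))
  rownames(per_cell) <- rownames(population) <- NULL
  list(per_cell = per_cell, population = population,
       n_cells = length(gated_ids))
}
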