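#' Build a run configuration
#'
#' Assembles and validates the configuration for [run_foci_pipeline()] /
#' [run_stripe_pipeline()]. `config` may be a list or a path to a YAML file;
#' defaults are filled in for absent blocks. Tiled acquisitions are handled by
#' listing each tile as one image: tiles are processed independently and
#' per-cell records pooled.
#'
#' @param config list or YAML path.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    channels = list(hoechst = "hoechst", egfp = "egfp",
                    markers = character(0)),
    segmentation = list(), detection = list(), thresholds = list(),
    direction = "egfp_to_marker",
    baseline_frames = 1:5, damage_frame = 5L, window = 10L,
    out_dir = NULL, seed = 1L, qc_overlay = FALSE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config$segmentation_params <- do.call(segmentation_params,
                                        config$segmentation)
  config$detection_params <- do.call(detection_params, config$detection)
  config$proximity_thresholds <- do.call(proximity_thresholds,
                                         config$thresholds)
  if (!config$direction %in% c("egfp_to_marker", "marker_to_egfp"))
    stop("direction must be 'egfp_to_marker' or 'marker_to_egfp'")
  class(config) <- c("run_config", "list")
  config
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "images")]), f)
  unname(tools::md5sum(f))
}

write_manifest <- function(config, out_dir, extra = list()) {
  manifest <- c(list(
    package = "dsbfoci",
    version = as.character(utils::packageVersion("dsbfoci")),
    config_hash = config_hash(config),
    seed = config$seed), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

load_images <- function(config) {
  if (!is.null(config$images)) return(config$images)
  paths <- config$input_paths
  if (is.null(paths) && !is.null(config$input_dir))
    paths <- list.files(config$input_dir, pattern = "\\.tiff?$",
                        full.names = TRUE)
  if (is.null(paths)) return(list())
  lapply(paths, read_multichannel_tiff)
}

#' Run the foci-proximity pipeline
#'
#' For every image: segment nuclei from the Hoechst channel, gate analysis to
#' EGFP-expressing cells, detect and size-filter foci in the EGFP and marker
#' channels, compute directional nearest-neighbour records (EGFP -> marker by
#' default), classify them into the distance bins and summarize per cell; then
#' pool per-cell records across images. With `out_dir` set, writes per-image
#' label-map TIFF + nuclei CSV, foci and proximity CSVs, summary CSVs, an
#' optional QC overlay PNG, and a machine-readable run manifest.
#'
#' @param config a [run_config()] (or list/YAML path coerced to one). Images
#'   come from `config$images` (list of [multichannel_image()]),
#'   `config$input_paths`, or `config$input_dir`.
#' @return Invisibly, `list(images = per-image results, pooled = pooled
#'   summaries, n_images)`. Per-image results carry the label map, gated ids,
#'   foci, proximity records and summaries.
#' @export
run_foci_pipeline <- function(config) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  images <- load_images(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!length(images)) {
    warning("empty image set: nothing to analyse")
    if (!is.null(out_dir)) write_manifest(config, out_dir,
                                          list(n_images = 0L))
    return(invisible(list(images = list(), pooled = NULL, n_images = 0L)))
  }
  ch <- config$channels
  results <- vector("list", length(images))
  pooled_records <- list()
  pooled_counts <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    hoechst <- get_channel(img, ch$hoechst)
    egfp <- get_channel(img, ch$egfp)
    lm <- segment_nuclei(hoechst, config$segmentation_params,
                         pixel_scale = img$pixel_scale)
    gated <- gate_expressing_cells(lm, egfp)
    foci_egfp <- filter_foci(detect_foci(egfp, lm, config$detection_params,
                                         channel_name = ch$egfp),
                             config$detection_params)
    counts <- count_foci(foci_egfp, gated)
    prox <- list()
    for (mk in ch$markers) {
      foci_mk <- filter_foci(detect_foci(get_channel(img, mk), lm,
                                         config$detection_params,
                                         channel_name = mk),
                             config$detection_params)
      recs <- if (config$direction == "egfp_to_marker")
        nearest_neighbour_distances(foci_egfp, foci_mk,
                                    config$proximity_thresholds,
                                    comparator_channel = mk)
      else
        nearest_neighbour_distances(foci_mk, foci_egfp,
                                    config$proximity_thresholds,
                                    comparator_channel = ch$egfp)
      prox[[mk]] <- list(records = recs,
                         summary = summarize_proximity(recs, gated))
      if (nrow(recs)) {
        recs$image <- i
        pooled_records[[length(pooled_records) + 1L]] <-
          recs[recs$nucleus_id %in% gated, , drop = FALSE]
      }
    }
    if (nrow(counts$per_cell)) {
      pc <- counts$per_cell; pc$image <- i
      pooled_counts[[length(pooled_counts) + 1L]] <- pc
    }
    results[[i]] <- list(label_map = lm, gated_ids = gated,
                         foci_egfp = foci_egfp, proximity = prox,
                         counts = counts)
    if (!is.null(out_dir)) {
      tag <- sprintf("image%03d", i)
      write_label_map_tiff(lm, file.path(out_dir, paste0(tag, "_labels.tif")),
                           file.path(out_dir, paste0(tag, "_nuclei.csv")))
      write.csv(foci_egfp, file.path(out_dir, paste0(tag, "_foci_egfp.csv")),
                row.names = FALSE)
      for (mk in ch$markers) {
        write.csv(prox[[mk]]$records,
                  file.path(out_dir, sprintf("%s_proximity_%s.csv", tag, mk)),
                  row.names = FALSE)
        write.csv(prox[[mk]]$summary$per_cell,
                  file.path(out_dir, sprintf("%s_summary_%s.csv", tag, mk)),
                  row.names = FALSE)
      }
      if (isTRUE(config$qc_overlay))
        qc_overlay_png(img, lm,
                       if (length(ch$markers))
                         prox[[ch$markers[1L]]]$records else NULL,
                       file.path(out_dir, paste0(tag, "_qc.png")),
                       hoechst_name = ch$hoechst)
    }
  }
  pooled <- NULL
  if (length(pooled_records)) {
    all_recs <- do.call(rbind, pooled_records)
    all_recs$cell_uid <- paste(all_recs$image, all_recs$nucleus_id, sep = ":")
    key <- unique(all_recs$cell_uid)
    remap <- setNames(seq_along(key), key)
    tmp <- all_recs
    tmp$nucleus_id <- remap[tmp$cell_uid]
    pooled <- summarize_proximity(tmp)
  }
  pooled_mean <- if (length(pooled_counts)) {
    pc <- do.call(rbind, pooled_counts)
    list(mean_foci = mean(pc$n_foci), n_cells = nrow(pc))
  } else NULL
  if (!is.null(out_dir)) {
    if (!is.null(pooled))
      write.csv(pooled$population, file.path(out_dir, "pooled_population.csv"),
                row.names = FALSE)
    write_manifest(config, out_dir, list(
      n_images = length(images),
      n_cells = vapply(results, function(x) x$label_map$n_labels, integer(1)),
      n_gated = vapply(results, function(x) length(x$gated_ids), integer(1)),
      n_foci = vapply(results, function(x) nrow(x$foci_egfp), integer(1))))
  }
  invisible(list(images = results, pooled = pooled,
                 pooled_counts = pooled_mean, n_images = length(images)))
}

#' Run the stripe-recruitment pipeline
#'
#' Extracts damage/control traces from each movie, double-normalizes against
#' the pre-damage baseline, aggregates the per-cell ratio curves (mean +/-
#' SEM), classifies active recruitment and fits the exponential model. With
#' `out_dir` set, writes per-cell trace CSVs, the aggregate curve CSV, the
#' fit/classification JSON and a run manifest.
#'
#' @param config a [run_config()]-style list. Movies come from
#'   `config$movies` (list of [time_lapse()]) or `config$input_paths`;
#'   matching ROIs from `config$rois` (list of [roi_pair()]) or are
#'   auto-placed from `config$label_maps` + `config$damage_rects`
#'   (see [auto_control_roi()]).
#' @return Invisibly, `list(traces, aggregate, classification, fit, n_cells)`.
#' @export
run_stripe_pipeline <- function(config) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  movies <- config$movies
  if (is.null(movies) && !is.null(config$input_paths))
    movies <- lapply(config$input_paths, read_time_lapse_tiff)
  if (is.null(movies)) movies <- list()
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!length(movies)) {
    warning("empty movie set: nothing to analyse")
    if (!is.null(out_dir)) write_manifest(config, out_dir,
                                          list(n_cells = 0L))
    return(invisible(list(traces = list(), aggregate = NULL,
                          classification = NULL, fit = NULL, n_cells = 0L)))
  }
  rois <- config$rois
  if (is.null(rois)) {
    stopifnot(!is.null(config$label_maps), !is.null(config$damage_rects))
    rois <- lapply(seq_along(movies), function(i) {
      lmm <- config$label_maps[[i]]
      mask <- if (inherits(lmm, "label_map")) lmm$labels > 0L else lmm > 0L
      auto_control_roi(mask, config$damage_rects[[i]])
    })
  }
  stopifnot(length(rois) == length(movies))
  traces <- lapply(seq_along(movies), function(i)
    normalize_trace(extract_traces(movies[[i]], rois[[i]]),
                    config$baseline_frames))
  agg <- aggregate_curves(traces)
  cls <- classify_recruitment(agg, config$window)
  fit <- fit_kinetics(agg, damage_frame = config$damage_frame)
  if (!is.null(out_dir)) {
    for (i in seq_along(traces))
      write.csv(as.data.frame(traces[[i]]),
                file.path(out_dir, sprintf("cell%03d_trace.csv", i)),
                row.names = FALSE)
    write.csv(agg, file.path(out_dir, "aggregate.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(classification = as.character(cls),
           plateau = attr(cls, "plateau"), plateau_sem = attr(cls, "sem"),
           A_hat = fit$A_hat, tau_hat = fit$tau_hat, rss = fit$rss,
           converged = fit$converged, n_cells = attr(agg, "n_cells")),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(config, out_dir, list(n_cells = attr(agg, "n_cells")))
  }
  invisible(list(traces = traces, aggregate = agg,
                 classification = cls, fit = fit,
                 n_cells = attr(agg, "n_cells")))
}

#' Write a QC overlay PNG
#'
#' Hoechst channel as grayscale background, nucleus outlines, and (when
#' proximity records are given) source foci colored by proximity class.
#'
#' @param img a [multichannel_image()].
#' @param lm a [label_map()].
#' @param records optional proximity records.
#' @param path output PNG path.
#' @param hoechst_name name of the background channel.
#' @return `path`, invisibly.
#' @export
qc_overlay_png <- function(img, lm, records, path,
                           hoechst_name = "hoechst") {
  ho <- get_channel(img, hoechst_name)
  grDevices::png(path, width = ncol(ho) * 2, height = nrow(ho) * 2)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::image(t(ho[nrow(ho):1, ]), col = grDevices::gray.colors(64),
                  axes = FALSE, useRaster = TRUE)
  if (lm$n_labels > 0L)
    graphics::contour(t(lm$labels[nrow(ho):1, ] > 0) * 1, levels = 0.5,
                      add = TRUE, drawlabels = FALSE, col = "cyan")
  if (!is.null(records) && nrow(records)) {
    cols <- c(overlapping = "red", proximal = "orange", distant = "yellow",
              unmatched = "gray")
    x <- (records$col - 1) / (ncol(ho) - 1)
    y <- 1 - (records$row - 1) / (nrow(ho) - 1)
    graphics::points(x, y, col = cols[records$class_label], pch = 3, cex = 1.2)
  }
  invisible(path)
}
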