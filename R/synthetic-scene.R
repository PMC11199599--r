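#' Noise model for synthetic rendering
#'
#' Photon (Poisson) noise followed by additive Gaussian read noise and a
#' constant camera offset, applied in that order. `poisson_scale` is the
#' number of photons per intensity unit; 0 disables photon noise. Defaults
#' emulate a moderately bright confocal acquisition; the model is deliberately
#' simple and documented rather than calibrated to any instrument.
#'
#' @param poisson_scale photons per intensity unit (>= 0; 0 = off).
#' @param read_noise_sd Gaussian read-noise SD in intensity units (>= 0).
#' @param offset constant added after noise (>= 0).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(poisson_scale = 1, read_noise_sd = 1, offset = 0) {
  stopifnot(poisson_scale >= 0, read_noise_sd >= 0, offset >= 0)
  structure(list(poisson_scale = poisson_scale, read_noise_sd = read_noise_sd,
                 offset = offset), class = "noise_spec")
}

#' Convert a full-width-at-half-maximum to a Gaussian sigma
#'
#' Foci are rendered as isotropic Gaussians; a measured focus diameter of
#' 6 px (FWHM) corresponds to sigma = 6 / (2 sqrt(2 ln 2)) ~ 2.55 px.
#'
#' @param fwhm full width at half maximum, pixels.
#' @return sigma in pixels.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Synthetic scene specification
#'
#' Describes one multi-channel field of view: elliptical Hoechst-stained
#' nuclei (optionally touching), an EGFP channel in which a configurable
#' fraction of cells express nuclear EGFP, and downstream focus channels
#' added via [place_focus_pairs()]. Defaults emulate the acquisition the
#' pipelines target: ~110 nm pixels and nuclei a few micrometres across.
#'
#' @param image_shape integer `c(rows, cols)` in pixels.
#' @param pixel_scale micrometres per pixel (> 0).
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param nucleus_radius_range `c(min, max)` semi-axis range in pixels.
#' @param allow_touching if `FALSE`, nucleus masks must be disjoint.
#' @param background_level constant background intensity in every channel.
#' @param hoechst_level peak nuclear intensity in the Hoechst channel.
#' @param egfp_level nuclear EGFP fill intensity in expressing cells.
#' @param expressing_fraction fraction of nuclei expressing EGFP (0..1).
#' @param noise a [noise_spec()].
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(256L, 256L),
                       pixel_scale = 0.11,
                       n_nuclei = 5L,
                       nucleus_radius_range = c(22, 32),
                       allow_touching = FALSE,
                       background_level = 5,
                       hoechst_level = 60,
                       egfp_level = 40,
                       expressing_fraction = 1,
                       noise = noise_spec(),
                       seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1),
            pixel_scale > 0, n_nuclei >= 0,
            length(nucleus_radius_range) == 2L,
            all(nucleus_radius_range > 0),
            nucleus_radius_range[1L] <= nucleus_radius_range[2L],
            background_level >= 0, hoechst_level > 0, egfp_level >= 0,
            expressing_fraction >= 0, expressing_fraction <= 1,
            inherits(noise, "noise_spec"))
  structure(list(image_shape = as.integer(image_shape),
                 pixel_scale = pixel_scale, n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = nucleus_radius_range,
                 allow_touching = isTRUE(allow_touching),
                 background_level = background_level,
                 hoechst_level = hoechst_level, egfp_level = egfp_level,
                 expressing_fraction = expressing_fraction,
                 noise = noise, seed = as.integer(seed)),
            class = "scene_spec")
}

# Normalized elliptical radius of every pixel for one nucleus: 0 at the
# center, 1 on the boundary. Returns a matrix over the full grid.
ellipse_rho <- function(shape, row0, col0, a, b, theta) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L]) - row0
  cc <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE) - col0
  u <- r * cos(theta) + cc * sin(theta)
  v <- -r * sin(theta) + cc * cos(theta)
  sqrt((u / a)^2 + (v / b)^2)
}

# Smooth nuclear fill: flat top, linear falloff over the outer 5% of the
# elliptical radius (a sharp but not binary edge, so the truth mask rho <= 1
# matches the thresholdable extent). Foci placed at rho <= 0.75 sit on a
# locally flat fill.
nucleus_fill <- function(rho) {
  f <- pmin(1, pmax(0, (1 - rho) / 0.05))
  f[rho <= 0.95] <- 1
  f[rho > 1] <- 0
  f
}

#' Generate a ground-truthed scene of elliptical nuclei
#'
#' Places `n_nuclei` random ellipses fully inside the field (rejecting
#' placements that overlap existing nuclei when `allow_touching = FALSE`),
#' renders the Hoechst and EGFP channels with the scene's noise model, and
#' returns both the image and a `synthetic_truth` record carrying the exact
#' label map, nucleus parameters and (initially empty) focus table. Identical
#' spec and seed give bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @return `list(image = multichannel_image, truth = synthetic_truth)`.
#' @export
generate_nuclei_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  shape <- spec$image_shape
  truth <- withr::with_seed(spec$seed, {
    nuclei <- data.frame(nucleus_id = integer(0), row = numeric(0),
                         col = numeric(0), a = numeric(0), b = numeric(0),
                         theta = numeric(0), expressing = logical(0))
    labels <- matrix(0L, shape[1L], shape[2L])
    rng <- spec$nucleus_radius_range
    max_attempts <- 300L
    n_expr <- round(spec$expressing_fraction * spec$n_nuclei)
    for (i in seq_len(spec$n_nuclei)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        a <- runif(1, rng[1L], rng[2L])
        b <- runif(1, rng[1L], rng[2L])
        theta <- runif(1, 0, pi)
        rad <- max(a, b)
        if (2 * rad + 4 > min(shape)) break
        row0 <- runif(1, rad + 2, shape[1L] - rad - 2)
        col0 <- runif(1, rad + 2, shape[2L] - rad - 2)
        rho <- ellipse_rho(shape, row0, col0, a, b, theta)
        inside <- rho <= 1
        ok <- spec$allow_touching || !any(labels[inside] > 0L)
        if (ok) {
          labels[inside] <- i
          nuclei <- rbind(nuclei, data.frame(
            nucleus_id = i, row = row0, col = col0, a = a, b = b,
            theta = theta, expressing = i <= n_expr))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(paste0(
          "failed to place nucleus %d of %d without overlap ",
          "(allow_touching = FALSE): reduce n_nuclei or nucleus_radius_range"),
          i, spec$n_nuclei))
    }
    structure(list(
      nucleus_masks = labels, nuclei = nuclei,
      foci = empty_focus_truth(), pair_distances = empty_pair_truth(),
      kinetics = NULL, seed = spec$seed, image_shape = shape,
      pixel_scale = spec$pixel_scale,
      background_level = spec$background_level,
      hoechst_level = spec$hoechst_level, egfp_level = spec$egfp_level,
      noise = spec$noise), class = "synthetic_truth")
  })
  list(image = render_channels(truth), truth = truth)
}

empty_focus_truth <- function() {
  data.frame(focus_id = integer(0), nucleus_id = integer(0),
             channel = character(0), row = numeric(0), col = numeric(0),
             psf_sigma = numeric(0), amplitude = numeric(0),
             pair_id = integer(0))
}

empty_pair_truth <- function() {
  data.frame(pair_id = integer(0), nucleus_id = integer(0),
             channel_a = character(0), channel_b = character(0),
             row_a = numeric(0), col_a = numeric(0), row_b = numeric(0),
             col_b = numeric(0), distance_px = numeric(0))
}

#' Place cross-channel focus pairs at controlled separations
#'
#' For every requested distance `d`, adds one focus to `channel_a` and one to
#' `channel_b` inside the same nucleus with centroid separation exactly `d`
#' pixels (to floating precision). Pairs are the ground truth for the
#' proximity classifier: the true class of each pair follows from `d` and the
#' distance bins.
#'
#' Anchors are kept at normalized elliptical radius <= `margin` so foci sit on
#' the flat part of the nuclear fill, and foci sharing a channel and a nucleus
#' are at least `min_separation` px apart so spots stay individually
#' resolvable (choosing `min_separation` > 2 max(distances) guarantees each
#' focus's within-cell nearest neighbour is its own partner).
#'
#' @param truth a `synthetic_truth` from [generate_nuclei_scene()].
#' @param channel_a,channel_b channel names receiving the two foci.
#' @param distances_px numeric vector of requested separations (>= 0).
#' @param amplitude spot peak amplitude above the local background.
#' @param psf_sigma Gaussian sigma of the rendered spot, px
#'   (default: 6 px FWHM).
#' @param angle orientation of each pair in radians, or `NULL` for random.
#' @param min_separation minimum anchor-to-anchor spacing per channel, px.
#' @param margin maximum normalized elliptical radius for focus positions.
#' @param snap if `TRUE`, anchors are rounded to integer pixel positions
#'   (with `angle = 0` and integer distances, both foci then fall exactly on
#'   pixel centers, making end-to-end distance recovery exact).
#' @return The updated `synthetic_truth`.
#' @export
place_focus_pairs <- function(truth, channel_a, channel_b, distances_px,
                              amplitude = 50, psf_sigma = fwhm_to_sigma(6),
                              angle = NULL, min_separation = 16,
                              margin = 0.75, snap = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"),
            all(distances_px >= 0), psf_sigma > 0, amplitude >= 0)
  if (nrow(truth$nuclei) == 0L)
    stop("cannot place focus pairs: the scene has no nuclei")
  stream <- nrow(truth$foci) + nrow(truth$pair_distances) + 1L
  withr::with_seed(derive_seed(truth$seed, stream), {
    for (d in distances_px) {
      res <- try_place_pair(truth, channel_a, channel_b, d, amplitude,
                            psf_sigma, angle, min_separation, margin, snap)
      if (is.null(res))
        stop(sprintf(paste0(
          "failed to place a focus pair at distance %.3g px: no nucleus can ",
          "hold both foci at margin %.2g with min_separation %.3g px"),
          d, margin, min_separation))
      truth <- res
    }
  })
  truth
}

try_place_pair <- function(truth, channel_a, channel_b, d, amplitude,
                           psf_sigma, angle, min_separation, margin, snap) {
  nuc <- truth$nuclei
  for (k in sample.int(nrow(nuc))) {
    n <- nuc[k, ]
    for (att in seq_len(200L)) {
      # random point in the margin-scaled ellipse
      psi <- runif(1, 0, 2 * pi)
      rho <- margin * sqrt(runif(1))
      du <- rho * n$a * cos(psi)
      dv <- rho * n$b * sin(psi)
      p1r <- n$row + du * cos(n$theta) - dv * sin(n$theta)
      p1c <- n$col + du * sin(n$theta) + dv * cos(n$theta)
      if (snap) { p1r <- round(p1r); p1c <- round(p1c) }
      phi <- if (is.null(angle)) runif(1, 0, 2 * pi) else angle
      p2r <- p1r + d * cos(phi)
      p2c <- p1c + d * sin(phi)
      if (!point_in_nucleus(truth, n, p2r, p2c, margin)) next
      if (!point_in_nucleus(truth, n, p1r, p1c, margin)) next
      if (!clear_of_channel(truth, channel_a, n$nucleus_id, p1r, p1c,
                            min_separation)) next
      if (!clear_of_channel(truth, channel_b, n$nucleus_id, p2r, p2c,
                            min_separation)) next
      pid <- nrow(truth$pair_distances) + 1L
      fid <- nrow(truth$foci)
      truth$foci <- rbind(truth$foci, data.frame(
        focus_id = fid + 1:2, nucleus_id = n$nucleus_id,
        channel = c(channel_a, channel_b), row = c(p1r, p2r),
        col = c(p1c, p2c), psf_sigma = psf_sigma, amplitude = amplitude,
        pair_id = pid))
      truth$pair_distances <- rbind(truth$pair_distances, data.frame(
        pair_id = pid, nucleus_id = n$nucleus_id, channel_a = channel_a,
        channel_b = channel_b, row_a = p1r, col_a = p1c, row_b = p2r,
        col_b = p2c, distance_px = d))
      return(truth)
    }
  }
  NULL
}

point_in_nucleus <- function(truth, n, r, cc, margin) {
  if (r < 1 || cc < 1 || r > truth$image_shape[1L] ||
      cc > truth$image_shape[2L]) return(FALSE)
  u <- (r - n$row) * cos(n$theta) + (cc - n$col) * sin(n$theta)
  v <- -(r - n$row) * sin(n$theta) + (cc - n$col) * cos(n$theta)
  sqrt((u / n$a)^2 + (v / n$b)^2) <= margin
}

clear_of_channel <- function(truth, channel, nucleus_id, r, cc,
                             min_separation) {
  f <- truth$foci[truth$foci$channel == channel &
                    truth$foci$nucleus_id == nucleus_id, , drop = FALSE]
  if (nrow(f) == 0L) return(TRUE)
  all(sqrt((f$row - r)^2 + (f$col - cc)^2) >= min_separation)
}

#' Render all channels of a synthetic truth record
#'
#' Builds the noiseless channels (constant background, nuclear Hoechst fill,
#' nuclear EGFP fill in expressing cells, and every focus as an isotropic
#' Gaussian spot), then applies Poisson noise followed by Gaussian read noise
#' and the camera offset. Pixels are clamped at zero. Rendering is
#' deterministic given `seed`.
#'
#' @param truth a `synthetic_truth`.
#' @param noise a [noise_spec()]; defaults to the truth's own.
#' @param seed integer seed for the noise draws; defaults to the truth's seed.
#' @return A [multichannel_image()].
#' @export
render_channels <- function(truth, noise = truth$noise, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(noise, "noise_spec"))
  base <- render_base_channels(truth)
  withr::with_seed(derive_seed(seed, 7L), {
    out <- lapply(base, apply_noise, noise = noise)
  })
  multichannel_image(out, truth$pixel_scale)
}

# Noiseless channel stack from a truth record.
render_base_channels <- function(truth) {
  shape <- truth$image_shape
  names_all <- unique(c("hoechst", "egfp",
                        unique(as.character(truth$foci$channel))))
  chans <- lapply(names_all, function(nm)
    matrix(truth$background_level, shape[1L], shape[2L]))
  names(chans) <- names_all
  for (k in seq_len(nrow(truth$nuclei))) {
    n <- truth$nuclei[k, ]
    fill <- nucleus_fill(ellipse_rho(shape, n$row, n$col, n$a, n$b, n$theta))
    chans$hoechst <- chans$hoechst + truth$hoechst_level * fill
    if (isTRUE(n$expressing) && truth$egfp_level > 0)
      chans$egfp <- chans$egfp + truth$egfp_level * fill
  }
  if (nrow(truth$foci) > 0L) {
    for (k in seq_len(nrow(truth$foci))) {
      f <- truth$foci[k, ]
      chans[[f$channel]] <- add_gaussian_spot(
        chans[[f$channel]], f$row, f$col, f$psf_sigma, f$amplitude)
    }
  }
  chans
}

# Add amplitude * exp(-r^2 / 2 sigma^2) in a +/- 5 sigma window.
add_gaussian_spot <- function(img, row0, col0, sigma, amplitude) {
  if (amplitude == 0) return(img)
  w <- ceiling(5 * sigma)
  r1 <- max(1L, floor(row0 - w)); r2 <- min(nrow(img), ceiling(row0 + w))
  c1 <- max(1L, floor(col0 - w)); c2 <- min(ncol(img), ceiling(col0 + w))
  if (r1 > r2 || c1 > c2) return(img)
  rr <- r1:r2; cc <- c1:c2
  g <- outer(exp(-(rr - row0)^2 / (2 * sigma^2)),
             exp(-(cc - col0)^2 / (2 * sigma^2)))
  img[rr, cc] <- img[rr, cc] + amplitude * g
  img
}

apply_noise <- function(img, noise) {
  out <- img
  if (noise$poisson_scale > 0) {
    n <- length(out)
    out <- matrix(rpois(n, pmax(0, out) * noise$poisson_scale) /
                    noise$poisson_scale, nrow(img), ncol(img))
  }
  if (noise$read_noise_sd > 0)
    out <- out + matrix(rnorm(length(out), 0, noise$read_noise_sd),
                        nrow(img), ncol(img))
  out <- out + noise$offset
  pmax(out, 0)
}

#' Recompute pair separations from truth positions
#'
#' Utility for verifying the generator's distance contract: the Euclidean
#' distance between each pair's two stored positions.
#'
#' @param truth a `synthetic_truth`.
#' @return Numeric vector, one distance per pair, in pixels.
#' @export
recompute_pair_distances <- function(truth) {
  pd <- truth$pair_distances
  sqrt((pd$row_a - pd$row_b)^2 + (pd$col_a - pd$col_b)^2)
}
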