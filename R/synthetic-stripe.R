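#' Recruitment kinetics specification for stripe movies
#'
#' Encodes the laser-microirradiation protocol the movies emulate: `n_frames`
#' frames at `frame_interval` seconds with damage initiated after
#' `damage_frame` (defaults 80, 15 s and 5), and a damage stripe of
#' `stripe_length` x `stripe_width` micrometres (defaults 6.5 x 1). Recruitment
#' in the stripe follows 1 + A (1 - exp(-(t - t_dmg)/tau)) for t >= t_dmg;
#' whole-frame photobleaching decays as exp(-bleach_rate t) and cancels in the
#' double-normalized ratio.
#'
#' @param amplitude plateau gain A of the recruitment factor (>= 0,
#'   dimensionless).
#' @param tau recruitment time constant, seconds (> 0).
#' @param bleach_rate whole-frame bleaching rate, per second (>= 0).
#' @param damage_frame last pre-damage frame index (damage starts after it).
#' @param n_frames total frames.
#' @param frame_interval seconds between frames.
#' @param stripe_length damage stripe length, micrometres.
#' @param stripe_width damage stripe width, micrometres.
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(amplitude = 1, tau = 120, bleach_rate = 0,
                          damage_frame = 5L, n_frames = 80L,
                          frame_interval = 15, stripe_length = 6.5,
                          stripe_width = 1.0) {
  stopifnot(amplitude >= 0, tau > 0, bleach_rate >= 0,
            damage_frame >= 1, damage_frame < n_frames,
            frame_interval > 0, stripe_length > 0, stripe_width > 0)
  structure(list(amplitude = amplitude, tau = tau, bleach_rate = bleach_rate,
                 damage_frame = as.integer(damage_frame),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 stripe_length = stripe_length, stripe_width = stripe_width),
            class = "kinetics_spec")
}

#' Default single-cell scene for stripe movies
#'
#' One large EGFP-expressing nucleus at 0.10 um/px, sized so the default
#' 6.5 x 1 um stripe and a same-size control region both fit inside it.
#' Arguments override [scene_spec()] defaults.
#'
#' @param ... overrides passed to [scene_spec()].
#' @return A [scene_spec()].
#' @export
stripe_scene_spec <- function(...) {
  args <- list(image_shape = c(120L, 120L), pixel_scale = 0.10,
               n_nuclei = 1L, nucleus_radius_range = c(42, 48),
               allow_touching = TRUE, background_level = 2,
               hoechst_level = 30, egfp_level = 50, expressing_fraction = 1,
               noise = noise_spec(0, 0, 0), seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_spec, args)
}

#' The noiseless recruitment factor
#'
#' `1 + A (1 - exp(-(t - t_dmg)/tau))` for `t >= t_dmg`, 1 before; this is the
#' closed form the double-normalized ratio of a noiseless movie equals at
#' every frame (bleaching cancels).
#'
#' @param t times in seconds.
#' @param amplitude plateau gain A.
#' @param tau time constant, seconds.
#' @param t_damage damage time, seconds.
#' @return Numeric vector of factors.
#' @export
recruitment_factor <- function(t, amplitude, tau, t_damage) {
  f <- rep(1, length(t))
  post <- t >= t_damage
  f[post] <- 1 + amplitude * (1 - exp(-(t[post] - t_damage) / tau))
  f
}

#' Generate a ground-truthed laser-stripe time-lapse
#'
#' Renders a single-cell movie following the striping protocol in the
#' kinetics spec: the EGFP channel of the scene is the base frame; every frame
#' is scaled by the bleaching factor `exp(-bleach_rate t)`; pixels inside the
#' damage stripe are additionally scaled by the recruitment factor. Noise is
#' then applied per frame. The stripe is an axis-aligned rectangle centered on
#' the first nucleus that can contain it; if none can, a geometry error is
#' raised.
#'
#' @param kinetics a [kinetics_spec()].
#' @param scene a [scene_spec()]; default [stripe_scene_spec()].
#' @param snr if finite, sets Gaussian read noise to
#'   (mean baseline stripe intensity)/snr; `Inf` (with the default noiseless
#'   scene spec) gives a noiseless movie.
#' @param noise optional [noise_spec()] overriding both `snr` and the scene's
#'   noise.
#' @param seed seed for the noise draws (default: the scene seed).
#' @return `list(movie = time_lapse, truth = synthetic_truth)`; the truth
#'   carries `kinetics`, the stripe rectangle (`stripe_roi`, as
#'   `c(r1, r2, c1, c2)`) and the nucleus label map.
#' @export
generate_stripe_movie <- function(kinetics = kinetics_spec(),
                                  scene = stripe_scene_spec(),
                                  snr = Inf, noise = NULL,
                                  seed = scene$seed) {
  stopifnot(inherits(kinetics, "kinetics_spec"), inherits(scene, "scene_spec"))
  gen <- generate_nuclei_scene(
    scene_spec_with_noise(scene, noise_spec(0, 0, 0)))
  truth <- gen$truth
  base <- render_base_channels(truth)$egfp

  len_px <- max(1L, round(kinetics$stripe_length / scene$pixel_scale))
  wid_px <- max(1L, round(kinetics$stripe_width / scene$pixel_scale))
  stripe <- place_stripe(truth, len_px, wid_px)
  if (is.null(stripe))
    stop(sprintf(paste0(
      "stripe of %d x %d px (%.3g x %.3g um at %.3g um/px) does not fit ",
      "inside any nucleus"), len_px, wid_px, kinetics$stripe_length,
      kinetics$stripe_width, scene$pixel_scale))

  nse <- resolve_movie_noise(noise, snr, base, stripe, scene)
  tt <- (seq_len(kinetics$n_frames) - 1) * kinetics$frame_interval
  t_dmg <- kinetics$damage_frame * kinetics$frame_interval
  fct <- recruitment_factor(tt, kinetics$amplitude, kinetics$tau, t_dmg)
  rows <- stripe[1L]:stripe[2L]
  cols <- stripe[3L]:stripe[4L]

  frames <- array(0, dim = c(dim(base), kinetics$n_frames))
  withr::with_seed(derive_seed(seed, 11L), {
    for (i in seq_len(kinetics$n_frames)) {
      fr <- base * exp(-kinetics$bleach_rate * tt[i])
      fr[rows, cols] <- fr[rows, cols] * fct[i]
      frames[, , i] <- apply_noise_local(fr, nse)
    }
  })

  truth$kinetics <- kinetics
  truth$stripe_roi <- stripe
  truth$stripe_nucleus <- attr(stripe, "nucleus_id")
  truth$noise <- nse
  list(movie = time_lapse(frames, kinetics$frame_interval,
                          scene$pixel_scale),
       truth = truth)
}

# apply_noise without seed management (the movie loop owns the RNG state)
apply_noise_local <- function(img, noise) {
  out <- img
  if (noise$poisson_scale > 0)
    out <- matrix(rpois(length(out), pmax(0, out) * noise$poisson_scale) /
                    noise$poisson_scale, nrow(img), ncol(img))
  if (noise$read_noise_sd > 0)
    out <- out + matrix(rnorm(length(out), 0, noise$read_noise_sd),
                        nrow(img), ncol(img))
  pmax(out + noise$offset, 0)
}

scene_spec_with_noise <- function(scene, noise) {
  scene$noise <- noise
  scene
}

resolve_movie_noise <- function(noise, snr, base, stripe, scene) {
  if (!is.null(noise)) return(noise)
  if (is.finite(snr)) {
    stopifnot(snr > 0)
    b0 <- mean(base[stripe[1L]:stripe[2L], stripe[3L]:stripe[4L]])
    return(noise_spec(poisson_scale = 0, read_noise_sd = b0 / snr,
                      offset = 0))
  }
  scene$noise
}

# Center an axis-aligned len x wid rectangle on each nucleus in turn; return
# the first placement fully inside that nucleus's mask.
place_stripe <- function(truth, len_px, wid_px) {
  for (k in seq_len(nrow(truth$nuclei))) {
    n <- truth$nuclei[k, ]
    r1 <- round(n$row - wid_px / 2); r2 <- r1 + wid_px - 1L
    c1 <- round(n$col - len_px / 2); c2 <- c1 + len_px - 1L
    if (r1 < 1 || c1 < 1 || r2 > truth$image_shape[1L] ||
        c2 > truth$image_shape[2L]) next
    sub <- truth$nucleus_masks[r1:r2, c1:c2]
    if (all(sub == n$nucleus_id)) {
      out <- as.integer(c(r1, r2, c1, c2))
      attr(out, "nucleus_id") <- n$nucleus_id
      return(out)
    }
  }
  NULL
}
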