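make_movie <- function(arr) time_lapse(arr, frame_interval = 15,
                                       pixel_scale = 0.1)

test_that("trace extraction is the per-frame ROI mean, with geometry checks", {
  arr <- array(7, dim = c(30, 30, 12))
  rp <- roi_pair(damage = c(10, 12, 5, 20), control = c(20, 22, 5, 20))
  tr <- extract_traces(make_movie(arr), rp)
  expect_true(all(tr$F_bleach == 7) && all(tr$F_control == 7))
  expect_equal(tr$t_s, (0:11) * 15)

  # single-pixel ROI equals that pixel's time series
  arr2 <- arr
  arr2[3, 4, ] <- seq_len(12)
  rp1 <- roi_pair(damage = c(3, 3, 4, 4), control = c(20, 20, 4, 4))
  expect_equal(extract_traces(make_movie(arr2), rp1)$F_bleach,
               as.numeric(1:12))

  # out-of-bounds ROI errors; overlapping ROIs are rejected at construction
  expect_error(extract_traces(make_movie(arr),
                              roi_pair(c(10, 40, 5, 20), c(1, 2, 1, 2))),
               "outside")
  expect_error(roi_pair(c(10, 12, 5, 20), c(12, 14, 5, 20)), "disjoint")
})

test_that("double normalization is exact, scale-invariant and bleach-cancelling", {
  # identical damage and control ROIs: R = 1 everywhere
  arr <- array(rep(seq(100, 45, length.out = 12), each = 900),
               dim = c(30, 30, 12))
  rp <- roi_pair(c(10, 12, 5, 20), c(20, 22, 5, 20))
  tr <- normalize_trace(extract_traces(make_movie(arr), rp))
  expect_true(all(abs(tr$R - 1) < 1e-12))

  # whole movie scaled by a constant: R unchanged
  sim <- generate_stripe_movie(kinetics_spec(amplitude = 0.8, tau = 120,
                                             bleach_rate = 0.001))
  rp2 <- auto_control_roi(sim$truth$nucleus_masks > 0, sim$truth$stripe_roi)
  r1 <- normalize_trace(extract_traces(sim$movie, rp2))$R
  movie_scaled <- time_lapse(sim$movie$frames * 3.14, 15, 0.1)
  r2 <- normalize_trace(extract_traces(movie_scaled, rp2))$R
  expect_equal(r2, r1, tolerance = 1e-12)

  # noiseless A = 0.8, tau = 120 s, bleach 0.001/s: R equals the closed form
  closed <- recruitment_factor((0:79) * 15, 0.8, 120, 75)
  expect_lt(max(abs(r1 - closed)), 1e-6)

  # baseline mean is 1 by construction
  expect_lt(abs(mean(r1[1:5]) - 1), 1e-9)

  # zero baseline triggers a normalization error
  dead <- array(0, dim = c(30, 30, 12))
  expect_error(normalize_trace(extract_traces(make_movie(dead), rp)),
               "baseline")
})

test_that("aggregation gives mean and SEM with closed-form checks", {
  tmpl <- data.frame(t_s = (0:9) * 15)
  mk <- function(r) {
    tr <- structure(cbind(tmpl, R = r),
                    class = c("recruitment_trace", "data.frame"))
    tr
  }
  # identical traces: SEM 0 everywhere
  agg0 <- aggregate_curves(list(mk(rep(2, 10)), mk(rep(2, 10)),
                                mk(rep(2, 10))))
  expect_true(all(agg0$sem_R == 0))
  # R = 1 and R = 3: mean 2, SEM 1 at every frame
  agg <- aggregate_curves(list(mk(rep(1, 10)), mk(rep(3, 10))))
  expect_true(all(agg$mean_R == 2))
  expect_true(all(abs(agg$sem_R - 1) < 1e-12))
  expect_identical(attr(agg, "n_cells"), 2L)
  # unequal lengths refuse to align
  short <- mk(rep(1, 10))[1:5, ]
  class(short) <- c("recruitment_trace", "data.frame")
  expect_error(aggregate_curves(list(mk(rep(1, 10)), short)), "unequal")
})

test_that("noisy simulated cells aggregate onto the closed-form curve", {
  kin <- kinetics_spec(amplitude = 1, tau = 120)
  traces <- lapply(1:20, function(s) {
    sim <- generate_stripe_movie(kin, stripe_scene_spec(seed = s), snr = 10,
                                 seed = s)
    rp <- auto_control_roi(sim$truth$nucleus_masks > 0, sim$truth$stripe_roi)
    normalize_trace(extract_traces(sim$movie, rp))
  })
  agg <- aggregate_curves(traces)
  closed <- recruitment_factor(agg$t_s, 1, 120, 75)
  covered <- abs(agg$mean_R - closed) <= 3 * pmax(agg$sem_R, 1e-12)
  expect_gte(mean(covered), 0.95)
})

test_that("recruitment classification follows the > 1 plateau criterion", {
  flat <- data.frame(t_s = (0:79) * 15, mean_R = rep(1, 80))
  expect_identical(as.character(classify_recruitment(flat)), "none")

  batch <- function(amplitude, seeds) {
    traces <- lapply(seeds, function(s) {
      sim <- generate_stripe_movie(kinetics_spec(amplitude = amplitude),
                                   stripe_scene_spec(seed = s), snr = 10,
                                   seed = s)
      rp <- auto_control_roi(sim$truth$nucleus_masks > 0,
                             sim$truth$stripe_roi)
      normalize_trace(extract_traces(sim$movie, rp))
    })
    aggregate_curves(traces)
  }
  expect_identical(as.character(classify_recruitment(batch(0, 1:8))), "none")
  expect_identical(as.character(classify_recruitment(batch(1, 1:8))),
                   "active")
})

test_that("kinetic fitting recovers parameters and handles flat curves", {
  # noiseless closed-form curve: A and tau within 1%
  t_s <- (0:79) * 15
  curve <- data.frame(t_s = t_s,
                      mean_R = recruitment_factor(t_s, 0.5, 90, 75))
  fit <- fit_kinetics(curve, damage_frame = 5)
  expect_lt(abs(fit$A_hat - 0.5) / 0.5, 0.01)
  expect_lt(abs(fit$tau_hat - 90) / 90, 0.01)

  # flat curve: A within 1e-6 of 0
  flat <- data.frame(t_s = t_s, mean_R = rep(1, 80))
  fit0 <- fit_kinetics(flat, damage_frame = 5)
  expect_lt(abs(fit0$A_hat), 1e-6)

  # too few post-damage frames
  expect_error(fit_kinetics(curve[1:8, ], damage_frame = 5), "insufficient")
})

test_that("tau is recovered from noisy single-cell curves (median error <= 15%)", {
  t_s <- (0:79) * 15
  truthR <- recruitment_factor(t_s, 0.8, 150, 75)
  errs <- withr::with_seed(77, vapply(1:50, function(i) {
    noisy <- truthR + rnorm(80, 0, 0.08)  # SNR ~10 on the recruitment signal
    fit <- fit_kinetics(data.frame(t_s = t_s, mean_R = noisy),
                        damage_frame = 5)
    abs(fit$tau_hat - 150) / 150
  }, numeric(1)))
  expect_lte(median(errs), 0.15)
})
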