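test_that("nuclei scene generation honours counts, determinism and placement limits", {
  # empty case
  sp0 <- scene_spec(n_nuclei = 0, background_level = 0,
                    noise = noise_spec(0, 0, 0), seed = 4)
  gen0 <- generate_nuclei_scene(sp0)
  expect_true(all(get_channel(gen0$image, "hoechst") == 0))
  expect_identical(sum(gen0$truth$nucleus_masks), 0L)

  # two touching nuclei allowed: exactly 2 labels in truth
  sp2 <- scene_spec(n_nuclei = 2, allow_touching = TRUE, seed = 11)
  gen2 <- generate_nuclei_scene(sp2)
  expect_setequal(setdiff(unique(as.vector(gen2$truth$nucleus_masks)), 0L),
                  1:2)

  # determinism: same spec + seed => bit-identical images and truth
  a <- generate_nuclei_scene(scene_spec(seed = 7))
  b <- generate_nuclei_scene(scene_spec(seed = 7))
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$nucleus_masks, b$truth$nucleus_masks)

  # impossible non-touching density errors out, naming the constraint
  expect_error(
    generate_nuclei_scene(scene_spec(image_shape = c(90, 90), n_nuclei = 8,
                                     nucleus_radius_range = c(20, 24),
                                     allow_touching = FALSE, seed = 1)),
    "allow_touching")

  # nuclei above background in the Hoechst channel
  ho <- get_channel(a$image, "hoechst")
  inside <- a$truth$nucleus_masks > 0
  expect_gt(mean(ho[inside]), mean(ho[!inside]) + 20)
})

test_that("focus pairs are placed at the requested separations", {
  gen <- generate_nuclei_scene(scene_spec(seed = 5))
  tr <- place_focus_pairs(gen$truth, "egfp", "marker1", c(3, 10, 20))
  expect_equal(recompute_pair_distances(tr), c(3, 10, 20), tolerance = 1e-12)
  expect_true(all(abs(recompute_pair_distances(tr) -
                        tr$pair_distances$distance_px) <= 1e-9))

  # coincident centroids at distance 0
  tr0 <- place_focus_pairs(gen$truth, "egfp", "marker1", 0)
  expect_equal(tr0$pair_distances$row_a, tr0$pair_distances$row_b)
  expect_equal(tr0$pair_distances$col_a, tr0$pair_distances$col_b)

  # both members of each pair sit inside the same nucleus
  lm <- gen$truth$nucleus_masks
  for (k in seq_len(nrow(tr$pair_distances))) {
    pd <- tr$pair_distances[k, ]
    expect_identical(lm[round(pd$row_a), round(pd$col_a)], pd$nucleus_id)
    expect_identical(lm[round(pd$row_b), round(pd$col_b)], pd$nucleus_id)
  }

  # random distances, fixed seed: recomputed distances equal requested
  d <- runif(6, 1, 22)
  trr <- place_focus_pairs(generate_nuclei_scene(scene_spec(seed = 9))$truth,
                           "egfp", "marker1", d)
  expect_true(max(abs(recompute_pair_distances(trr) - d)) <= 1e-9)

  # a distance no nucleus can hold errors out
  expect_error(place_focus_pairs(gen$truth, "egfp", "marker1", 500),
               "failed to place")
})

test_that("rendering puts spots where the truth says, with non-negative pixels", {
  gen <- generate_nuclei_scene(scene_spec(seed = 13))
  tr <- place_focus_pairs(gen$truth, "egfp", "marker1", 12)
  img <- render_channels(tr, noise = noise_spec(0, 0, 0))
  mk <- get_channel(img, "marker1")
  f <- tr$foci[tr$foci$channel == "marker1", ]
  peak <- which(mk == max(mk), arr.ind = TRUE)
  expect_lt(sqrt((peak[1, 1] - f$row)^2 + (peak[1, 2] - f$col)^2), 1)

  # amplitude 0 foci leave the channel equal to the background field
  tr0 <- tr
  tr0$foci$amplitude <- 0
  img0 <- render_channels(tr0, noise = noise_spec(0, 0, 0))
  expect_true(all(get_channel(img0, "marker1") ==
                    tr$background_level))

  # noisy rendering never goes negative
  imgn <- render_channels(tr, noise = noise_spec(0.5, 3, 0))
  expect_true(all(vapply(imgn$channels, function(ch) all(ch >= 0),
                         logical(1))))
})

test_that("Poisson rendering is unbiased at the focus peak (Monte Carlo)", {
  gen <- generate_nuclei_scene(scene_spec(seed = 21))
  tr <- place_focus_pairs(gen$truth, "egfp", "marker1", 10, amplitude = 200,
                          snap = TRUE, angle = 0)
  noiseless <- render_channels(tr, noise = noise_spec(0, 0, 0))
  f <- tr$foci[tr$foci$channel == "marker1", ]
  truev <- get_channel(noiseless, "marker1")[f$row, f$col]
  vals <- vapply(1:100, function(s) {
    get_channel(render_channels(tr, noise = noise_spec(1, 0, 0), seed = s),
                "marker1")[f$row, f$col]
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - truev), 3 * se)
})

test_that("stripe movies follow the protocol and the closed-form ratio", {
  kin <- kinetics_spec()  # protocol defaults: 80 frames, 15 s, damage after 5
  sim <- generate_stripe_movie(kin)
  expect_identical(sim$movie$n_frames, 80L)
  expect_equal(sim$movie$frame_interval, 15)
  expect_identical(sim$truth$kinetics$damage_frame, 5L)
  # stripe geometry: 6.5 x 1 um at 0.1 um/px -> 65 x 10 px
  roi <- sim$truth$stripe_roi
  expect_identical(roi[2] - roi[1] + 1L, 10L)
  expect_identical(roi[4] - roi[3] + 1L, 65L)

  # frames before damage carry no recruitment signal
  base <- sim$movie$frames[, , 1]
  for (i in 2:kin$damage_frame)
    expect_equal(sim$movie$frames[, , i], base, tolerance = 1e-12)

  # A = 0: damage ROI indistinguishable from control at all frames
  sim0 <- generate_stripe_movie(kinetics_spec(amplitude = 0))
  rp <- auto_control_roi(sim0$truth$nucleus_masks > 0, sim0$truth$stripe_roi)
  tr0 <- normalize_trace(extract_traces(sim0$movie, rp))
  expect_true(all(abs(tr0$R - 1) < 1e-9))

  # bleach_rate = 0, A = 1: plateau of the normalized ratio is 2
  siml <- generate_stripe_movie(kinetics_spec(amplitude = 1, tau = 60))
  rpl <- auto_control_roi(siml$truth$nucleus_masks > 0, siml$truth$stripe_roi)
  trl <- normalize_trace(extract_traces(siml$movie, rpl))
  expect_equal(tail(trl$R, 1), 2, tolerance = 1e-4)
})

test_that("the double-normalized ratio cancels bleaching exactly", {
  rates <- c(0, 1e-4, 5e-4, 1e-3, 5e-3)
  curves <- lapply(rates, function(b) {
    sim <- generate_stripe_movie(kinetics_spec(amplitude = 0.7, tau = 150,
                                               bleach_rate = b))
    rp <- auto_control_roi(sim$truth$nucleus_masks > 0, sim$truth$stripe_roi)
    normalize_trace(extract_traces(sim$movie, rp))$R
  })
  ref <- curves[[1]]
  for (k in 2:length(curves))
    expect_lt(max(abs(curves[[k]] - ref)), 1e-9)
  # and the common curve equals the closed form
  tt <- (0:79) * 15
  expect_lt(max(abs(ref - recruitment_factor(tt, 0.7, 150, 75))), 1e-9)
})
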