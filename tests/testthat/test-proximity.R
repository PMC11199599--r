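test_that("classification follows the distance bins and boundary convention", {
  thr <- proximity_thresholds()
  expect_identical(classify_proximity(c(4, 10, 20), thr),
                   c("overlapping", "proximal", "distant"))
  expect_identical(classify_proximity(0, thr), "overlapping")
  expect_identical(classify_proximity(5, thr), "overlapping")
  expect_identical(classify_proximity(15, thr), "proximal")
  expect_identical(classify_proximity(15.0001, thr), "distant")
  expect_error(classify_proximity(-1, thr), "non-negative")
})

test_that("the three classes partition [0, Inf)", {
  thr <- proximity_thresholds()
  d <- c(seq(0, 30, by = 0.25), 1e6)
  cls <- classify_proximity(d, thr)
  expect_true(all(cls %in% c("overlapping", "proximal", "distant")))
  expect_identical(length(cls), length(d))
})

test_that("pixel-to-micrometre conversion reproduces the bin bounds in micrometres", {
  scale <- 1.07 / 15
  expect_equal(pixels_to_um(15, scale), 1.07)
  expect_equal(round(pixels_to_um(5, scale), 2), 0.36)
  expect_identical(pixels_to_um(0, scale), 0)
})

test_that("classifying in px then converting agrees with converting then classifying", {
  thr_px <- proximity_thresholds()
  scale <- thr_px$pixel_scale
  thr_um <- proximity_thresholds(overlap_max = 5 * scale,
                                 proximal_max = 15 * scale,
                                 pixel_scale = 1)
  withr::with_seed(8, d <- runif(500, 0, 30))
  expect_identical(classify_proximity(d, thr_px),
                   classify_proximity(pixels_to_um(d, scale), thr_um))
})

test_that("nearest-neighbour records cover the trivial and unmatched cases", {
  a <- data.frame(nucleus_id = c(1L, 2L), channel = "egfp",
                  row = c(10, 40), col = c(10, 40))
  b <- data.frame(nucleus_id = 1L, channel = "m", row = 10, col = 13)
  recs <- nearest_neighbour_distances(a, b)
  expect_equal(recs$nn_distance[1], 3)
  expect_identical(recs$class_label[1], "overlapping")
  # cell 2 has no comparator foci
  expect_identical(recs$class_label[2], "unmatched")
  expect_true(is.na(recs$nn_distance[2]))
  # directional: B -> A is a different record set
  recs_rev <- nearest_neighbour_distances(b, a)
  expect_identical(nrow(recs_rev), 1L)
})

test_that("nearest-neighbour distances equal the O(n^2) oracle on random cells", {
  withr::with_seed(99, {
    for (rep in 1:150) {
      n_cells <- sample(1:4, 1)
      na <- sample(0:20, 1); nb <- sample(0:20, 1)
      a <- data.frame(nucleus_id = sample(n_cells, na, replace = TRUE),
                      row = runif(na, 0, 60), col = runif(na, 0, 60))
      b <- data.frame(nucleus_id = sample(n_cells, nb, replace = TRUE),
                      row = runif(nb, 0, 60), col = runif(nb, 0, 60))
      got <- nearest_neighbour_distances(a, b)
      want <- oracle_nn(a, b)
      expect_identical(got$nn_distance, want$distance)
      expect_identical(got$nn_index, want$index)
    }
  })
})

test_that("summaries give per-cell fractions and are invariant to label permutation", {
  recs <- data.frame(
    nucleus_id = c(1L, 1L, 1L, 2L, 2L),
    row = 0, col = 0, comparator_channel = "m",
    nn_distance = c(2, 10, 20, 3, NA),
    nn_distance_um = NA_real_, nn_index = NA_integer_,
    class_label = c("overlapping", "proximal", "distant", "overlapping",
                    "unmatched"))
  s <- summarize_proximity(recs)
  pc1 <- s$per_cell[s$per_cell$nucleus_id == 1L, ]
  expect_equal(unlist(pc1[, c("frac_overlapping", "frac_proximal",
                              "frac_distant")], use.names = FALSE),
               rep(1 / 3, 3))
  expect_identical(s$per_cell$n_unmatched, c(0L, 1L))
  expect_identical(s$n_cells, 2L)
  expect_equal(sum(s$population$fraction), 1)

  # permuting cell labels leaves the population summary unchanged
  recs2 <- recs
  recs2$nucleus_id <- c(2L, 2L, 2L, 1L, 1L)[match(recs$nucleus_id, c(1L, 2L))]
  recs2$nucleus_id <- ifelse(recs$nucleus_id == 1L, 2L, 1L)
  s2 <- summarize_proximity(recs2)
  expect_equal(s2$population, s$population)
})

test_that("pairs planted across the bins come back with their true classes", {
  gen <- generate_nuclei_scene(scene_spec(
    image_shape = c(420, 420), n_nuclei = 10,
    nucleus_radius_range = c(22, 26), noise = noise_spec(0, 0, 0), seed = 55))
  dists <- c(1, 3, 5, 6, 9, 14, 15, 16, 22)
  # min_separation > 2 max(dists): each focus's NN is its own partner
  tr <- place_focus_pairs(gen$truth, "egfp", "marker1", dists,
                          angle = 0, snap = TRUE, min_separation = 46)
  img <- render_channels(tr, noise = noise_spec(0, 0, 0))
  lm <- segment_nuclei(get_channel(img, "hoechst"), pixel_scale = 0.11)
  fe <- filter_foci(detect_foci(get_channel(img, "egfp"), lm,
                                channel_name = "egfp"))
  fm <- filter_foci(detect_foci(get_channel(img, "marker1"), lm,
                                channel_name = "marker1"))
  recs <- nearest_neighbour_distances(fe, fm)
  expect_identical(nrow(recs), length(dists))
  got <- sort(recs$nn_distance)
  expect_equal(got, sort(dists), tolerance = 1e-9)
  expect_identical(classify_proximity(got), classify_proximity(sort(dists)))
})
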