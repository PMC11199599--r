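# dsbfoci

Quantitative image analysis of DNA double-strand-break (DSB) repair for cell
biologists working with multi-channel confocal microscopy. The package
implements two pipelines end to end:

* **Foci proximity** — how close does a repair protein get to damage-marker
  foci? Nuclei are segmented from the Hoechst channel (Huang auto-threshold,
  watershed splitting of touching nuclei), analysis is gated to
  EGFP-expressing cells, foci are detected per nucleus as prominence-ranked
  local maxima after a mild 0.8 σ Gaussian blur, and each focus is classified
  by the distance *d* to its nearest neighbour in a comparator channel:

  | class | pixels | micrometres |
  |---|---|---|
  | overlapping | d ≤ 5 px | ≤ 0.36 µm |
  | proximal | 5 < d ≤ 15 px | 0.36–1.07 µm |
  | distant | d > 15 px | > 1.07 µm |

* **Stripe recruitment** — how fast does a protein accumulate at a laser
  microirradiation track? From an 80-frame, 15 s-interval time-lapse (damage
  after frame 5, 6.5 × 1 µm stripe), per-cell damage and control ROI traces
  are double-normalized,

      R(t) = [F(t)/F(-)]_bleach / [F(t)/F(-)]_control,

  so photobleaching and drift cancel; active recruitment means R > 1.
  Curves are aggregated as mean ± SEM across cells and an exponential model
  R(t) = 1 + A·(1 − exp(−(t − t_dmg)/τ)) is fitted for parameter-recovery
  checks.

A synthetic-imaging module generates ground-truthed scenes (elliptical
nuclei, Gaussian foci planted at exact cross-channel separations,
Poisson + Gaussian noise) and stripe movies, so the whole chain is testable
without microscope data. See the methods vignette
(`vignettes/dsbfoci-methods.Rmd`) for the model details and design choices.

## Worked example

Plant six cross-channel focus pairs at known separations in a noiseless
synthetic field, run the foci pipeline, and read back the classes:

```r
library(dsbfoci)

gen   <- generate_nuclei_scene(scene_spec(image_shape = c(420, 420),
          n_nuclei = 6, nucleus_radius_range = c(22, 26),
          noise = noise_spec(0, 0, 0), seed = 42))
truth <- place_focus_pairs(gen$truth, "egfp", "marker1",
          c(2, 4, 8, 12, 18, 24), angle = 0, snap = TRUE,
          min_separation = 50)
img   <- render_channels(truth, noise = noise_spec(0, 0, 0))

res <- run_foci_pipeline(list(images = list(img),
         channels = list(hoechst = "hoechst", egfp = "egfp",
                         markers = "marker1")))
res$images[[1]]$proximity$marker1$summary$population
#>         class mean_count_per_cell  fraction
#> 1 overlapping           0.3333333 0.3333333
#> 2    proximal           0.3333333 0.3333333
#> 3     distant           0.3333333 0.3333333
```

The six planted distances (2, 4, 8, 12, 18, 24 px) come back exactly and
fall two-each into the overlapping / proximal / distant bins — e.g. 4 px is
0.29 µm (overlapping), 12 px is 0.86 µm (proximal), 24 px is 1.71 µm
(distant) at the default 1.07/15 µm/px reporting scale.

Recruitment on ten simulated stripe movies (A = 1, τ = 120 s, SNR 10):

```r
kin  <- kinetics_spec(amplitude = 1, tau = 120)
sims <- lapply(1:10, function(s)
  generate_stripe_movie(kin, stripe_scene_spec(seed = s), snr = 10, seed = s))
res2 <- run_stripe_pipeline(list(
  movies = lapply(sims, `[[`, "movie"),
  rois   = lapply(sims, function(x)
    auto_control_roi(x$truth$nucleus_masks > 0, x$truth$stripe_roi))))
```

This prints (via the returned object): classification `active`, plateau
`2.001`, fitted `A_hat = 1.001`, `tau_hat = 119.9 s`, `n = 10` — the double
ratio plateaus at 1 + A = 2 and the fit recovers the simulated parameters.

Both pipelines can also be driven from the shell via
`inst/cli/dsbfoci.R` (`simulate`, `foci`, `stripe` verbs with `--config`,
`--out`, `--seed`).

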