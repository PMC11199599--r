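#' Damage/control ROI pair
#'
#' Axis-aligned rectangles given as `c(r1, r2, c1, c2)` (inclusive pixel
#' bounds). The control ROI must lie in the same cell but away from the
#' damage site; the two must be disjoint.
#'
#' @param damage damage-stripe rectangle.
#' @param control control rectangle (same cell, disjoint from `damage`).
#' @param nucleus_id owning nucleus (optional, for bookkeeping).
#' @return An object of class `roi_pair`.
#' @export
roi_pair <- function(damage, control, nucleus_id = NA_integer_) {
  damage <- as.integer(damage); control <- as.integer(control)
  stopifnot(length(damage) == 4L, length(control) == 4L,
            damage[1L] <= damage[2L], damage[3L] <= damage[4L],
            control[1L] <= control[2L], control[3L] <= control[4L])
  overlap <- damage[1L] <= control[2L] && control[1L] <= damage[2L] &&
    damage[3L] <= control[4L] && control[3L] <= damage[4L]
  if (overlap) stop("damage and control ROIs must be disjoint")
  structure(list(damage = damage, control = control,
                 nucleus_id = as.integer(nucleus_id)), class = "roi_pair")
}

#' Auto-place a control ROI inside the same nucleus
#'
#' The control region is the largest axis-aligned rectangle inscribed in the
#' nucleus mask after removing the damage ROI dilated by `clearance` px
#' (Chebyshev). Errors if no pixel remains.
#'
#' @param nucleus_mask logical matrix of the cell's mask.
#' @param damage damage rectangle `c(r1, r2, c1, c2)`.
#' @param clearance dilation of the damage ROI in px (default 5).
#' @param nucleus_id recorded in the result.
#' @return A [roi_pair()].
#' @export
auto_control_roi <- function(nucleus_mask, damage, clearance = 5L,
                             nucleus_id = NA_integer_) {
  stopifnot(is.matrix(nucleus_mask))
  m <- nucleus_mask
  r1 <- max(1L, damage[1L] - clearance); r2 <- min(nrow(m), damage[2L] + clearance)
  c1 <- max(1L, damage[3L] - clearance); c2 <- min(ncol(m), damage[4L] + clearance)
  m[r1:r2, c1:c2] <- FALSE
  rect <- largest_rectangle(m)
  if (is.null(rect))
    stop("no room for a control ROI in this nucleus after excluding the damage site")
  roi_pair(damage, rect, nucleus_id)
}

# Largest axis-aligned all-TRUE rectangle in a logical matrix
# (largest-rectangle-in-histogram scan over rows). Returns c(r1, r2, c1, c2).
largest_rectangle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  heights <- integer(nc)
  best <- 0L; best_rect <- NULL
  for (r in seq_len(nr)) {
    heights <- ifelse(m[r, ], heights + 1L, 0L)
    # histogram scan with a stack
    stack_c <- integer(nc + 1L); stack_h <- integer(nc + 1L); top <- 0L
    for (cc in seq_len(nc + 1L)) {
      h <- if (cc <= nc) heights[cc] else 0L
      start <- cc
      while (top > 0L && stack_h[top] > h) {
        area <- stack_h[top] * (cc - stack_c[top])
        if (area > best) {
          best <- area
          best_rect <- c(r - stack_h[top] + 1L, r, stack_c[top], cc - 1L)
        }
        start <- stack_c[top]
        top <- top - 1L
      }
      if (top == 0L || stack_h[top] < h) {
        top <- top + 1L
        stack_c[top] <- start; stack_h[top] <- h
      }
    }
  }
  best_rect
}

#' Extract raw damage/control traces from a time-lapse
#'
#' Per-frame mean intensity over each ROI's pixels; no interpolation or
#' registration. Frame times are `(frame - 1) * frame_interval` seconds.
#'
#' @param movie a [time_lapse()].
#' @param rois a [roi_pair()].
#' @return An object of class `recruitment_trace`: data.frame columns
#'   `frame`, `t_s`, `F_bleach`, `F_control` (the normalized ratio is added
#'   by [normalize_trace()]).
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "time_lapse"), inherits(rois, "roi_pair"))
  d <- dim(movie$frames)
  for (rect in list(rois$damage, rois$control))
    if (rect[1L] < 1L || rect[3L] < 1L || rect[2L] > d[1L] || rect[4L] > d[2L])
      stop("ROI extends outside the frame bounds")
  f_b <- apply(movie$frames[rois$damage[1L]:rois$damage[2L],
                            rois$damage[3L]:rois$damage[4L], , drop = FALSE],
               3L, mean)
  f_c <- apply(movie$frames[rois$control[1L]:rois$control[2L],
                            rois$control[3L]:rois$control[4L], , drop = FALSE],
               3L, mean)
  tr <- data.frame(frame = seq_len(d[3L]), t_s = frame_times(movie),
                   F_bleach = f_b, F_control = f_c)
  structure(tr, class = c("recruitment_trace", "data.frame"),
            frame_interval = movie$frame_interval,
            nucleus_id = rois$nucleus_id)
}

#' Double-normalize a recruitment trace
#'
#' Adds `R(t) = (F_bleach(t)/F_bleach(-)) / (F_control(t)/F_control(-))`,
#' where each `F(-)` is the mean of that ROI's trace over the pre-damage
#' baseline frames. Active recruitment drives `R > 1`; whole-cell bleaching
#' and global intensity changes cancel in the double ratio.
#'
#' @param trace a `recruitment_trace` from [extract_traces()].
#' @param baseline_frames pre-damage frame indices (default `1:5`; damage is
#'   initiated after frame 5 in the standard protocol).
#' @return The trace with columns `R` and attributes `baseline_frames`,
#'   `F_minus_bleach`, `F_minus_control`.
#' @export
normalize_trace <- function(trace, baseline_frames = 1:5) {
  stopifnot(inherits(trace, "recruitment_trace"),
            all(baseline_frames >= 1), all(baseline_frames <= nrow(trace)))
  f_mb <- mean(trace$F_bleach[baseline_frames])
  f_mc <- mean(trace$F_control[baseline_frames])
  if (!is.finite(f_mb) || !is.finite(f_mc) || f_mb <= 0 || f_mc <= 0)
    stop("non-positive baseline mean: empty ROI or saturated detector?")
  trace$R <- (trace$F_bleach / f_mb) / (trace$F_control / f_mc)
  attr(trace, "baseline_frames") <- baseline_frames
  attr(trace, "F_minus_bleach") <- f_mb
  attr(trace, "F_minus_control") <- f_mc
  trace
}

#' Aggregate normalized curves across cells
#'
#' Pointwise mean and SEM (sample SD / sqrt(n)) of the per-cell ratios,
#' frame-aligned by index (a common protocol is assumed; unequal lengths are
#' an error). With a single cell the SEM is reported as missing.
#'
#' @param traces list of normalized `recruitment_trace`s, or a numeric matrix
#'   with one column per cell (rows = frames).
#' @param t_s optional frame times (taken from the first trace otherwise).
#' @return data.frame `t_s`, `mean_R`, `sem_R`, with attribute `n_cells`.
#' @export
aggregate_curves <- function(traces, t_s = NULL) {
  if (is.list(traces) && !is.data.frame(traces)) {
    lens <- vapply(traces, nrow, integer(1))
    if (length(unique(lens)) != 1L)
      stop("traces have unequal lengths; cannot align frames by index")
    if (!all(vapply(traces, function(x) "R" %in% names(x), logical(1))))
      stop("traces must be normalized first (missing R column)")
    R <- vapply(traces, function(x) x$R, numeric(lens[1L]))
    if (is.null(t_s)) t_s <- traces[[1L]]$t_s
  } else {
    R <- as.matrix(traces)
    if (is.null(t_s)) t_s <- seq_len(nrow(R)) - 1
  }
  n <- ncol(R)
  mean_r <- rowMeans(R)
  sem <- if (n > 1L) apply(R, 1L, sd) / sqrt(n) else rep(NA_real_, nrow(R))
  out <- data.frame(t_s = t_s, mean_R = mean_r, sem_R = sem)
  attr(out, "n_cells") <- n
  out
}

#' Classify a mean curve as active recruitment or none
#'
#' Active iff the mean ratio over the last `window` frames exceeds
#' `1 + 2 * SEM` of that window mean (active recruitment means a sustained
#' ratio > 1; the 2-SEM guard keeps noise-level excursions from being called
#' active). The SEM is taken from the aggregate's between-cell SEMs (their
#' mean over the window) when present, because per-cell baseline
#' normalization leaves each cell's curve with a small persistent offset that
#' frame-to-frame scatter alone would miss; with no between-cell SEM (single
#' cell), the within-window scatter SEM is used. A curve identically 1 is
#' `none`.
#'
#' @param curve data.frame from [aggregate_curves()] (or any with `mean_R`).
#' @param window number of trailing frames to average (default 10).
#' @return `"active"` or `"none"`, with attributes `plateau` and `sem`.
#' @export
classify_recruitment <- function(curve, window = 10L) {
  r <- curve$mean_R
  stopifnot(length(r) >= window, window >= 2L)
  w <- tail(r, window)
  m <- mean(w)
  sem <- if (!is.null(curve$sem_R) && all(is.finite(tail(curve$sem_R,
                                                         window))))
    mean(tail(curve$sem_R, window))
  else sd(w) / sqrt(window)
  out <- if (m > 1 + 2 * sem) "active" else "none"
  attr(out, "plateau") <- m
  attr(out, "sem") <- sem
  out
}

#' Fit the exponential recruitment model to a mean curve
#'
#' Least-squares fit of `R(t) = 1 + A (1 - exp(-(t - t_dmg)/tau))` over the
#' post-damage frames, multi-started over a grid of tau values (best RSS
#' wins) via Levenberg-Marquardt.
#'
#' @param curve data.frame with `t_s` and `mean_R` (from
#'   [aggregate_curves()]), or a normalized trace (its `R` is used).
#' @param damage_frame last pre-damage frame; fitting uses frames after it
#'   and `t_dmg = damage_frame * frame_interval`.
#' @param frame_interval seconds per frame (default: inferred from `t_s`).
#' @param tau_grid multi-start values for tau, seconds.
#' @return `list(A_hat, tau_hat, rss, converged)`.
#' @export
fit_kinetics <- function(curve, damage_frame = 5L, frame_interval = NULL,
                         tau_grid = c(15, 60, 150, 400, 1000)) {
  r <- if ("mean_R" %in% names(curve)) curve$mean_R else curve$R
  t_s <- curve$t_s
  if (is.null(frame_interval))
    frame_interval <- if (length(t_s) > 1L) t_s[2L] - t_s[1L] else
      stop("cannot infer frame_interval from a single frame")
  post <- seq_along(r) > damage_frame
  if (sum(post) < 4L)
    stop("insufficient data: need at least 4 post-damage frames")
  tt <- t_s[post] - damage_frame * frame_interval
  y <- r[post]
  best <- NULL
  for (tau0 in tau_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ 1 + A * (1 - exp(-tt / tau)),
        start = list(A = max(mean(tail(y, 5L)) - 1, 0.01), tau = tau0),
        lower = c(A = -1, tau = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(A_hat = unname(coef(fit)["A"]),
                   tau_hat = unname(coef(fit)["tau"]),
                   rss = rss, converged = TRUE)
  }
  if (is.null(best)) {
    # flat or degenerate data: report the plateau offset with no time constant
    best <- list(A_hat = mean(y) - 1, tau_hat = NA_real_,
                 rss = sum((y - mean(y))^2), converged = FALSE)
  }
  best
}
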