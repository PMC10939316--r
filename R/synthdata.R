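#' Genotype profile presets for synthetic data
#'
#' Qualitative stand-ins for the laminar distribution and motility of the
#' main experimental populations: `"control-like"` (more cells in upper
#' zones, fast and directional), `"ko-like"` (even distribution, slow,
#' weakly directional), `"mosaic-mutant-like"` (accumulation in lower
#' zones). Zone fractions are free parameters, not digitised figures.
#'
#' @param name Preset name.
#' @return An object of class `genotype_profile`: list with `name`,
#'   `zone_fractions` (10 zones, ventricular-first, summing to 1),
#'   `speed_um_min`, `directionality`.
#' @export
genotype_profile <- function(name = c("control-like", "ko-like",
                                      "mosaic-mutant-like")) {
  name <- match.arg(name)
  zf <- switch(name,
    "control-like" = c(4, 5, 6, 8, 10, 12, 14, 15, 14, 12),
    "ko-like" = c(10, 10, 10, 10, 10, 10, 10, 10, 10, 10),
    "mosaic-mutant-like" = c(18, 17, 16, 14, 12, 8, 6, 4, 3, 2))
  structure(list(name = name, zone_fractions = zf / sum(zf),
                 speed_um_min = switch(name, "control-like" = 0.8,
                                       "ko-like" = 0.3,
                                       "mosaic-mutant-like" = 0.4),
                 directionality = switch(name, "control-like" = 0.85,
                                         "ko-like" = 0.4,
                                         "mosaic-mutant-like" = 0.6)),
            class = "genotype_profile")
}

#' Generate marked neuron positions between two boundaries
#'
#' Samples neuron marks whose relative-distance binning recovers the
#' target zone fractions (multinomial zone assignment, uniform depth
#' within a zone). Boundaries are horizontal lines by default or curved
#' (sinusoidal) to exercise polyline geometry; curvature does not change
#' the recovered fractions because marks are placed by relative depth
#' between the local boundary ordinates.
#'
#' @param profile A [genotype_profile()] or a vector of zone fractions.
#' @param n Number of marks.
#' @param seed RNG seed.
#' @param width_um Lateral extent.
#' @param height_um Mean boundary separation.
#' @param curved Logical: curve the boundaries.
#' @param marker,genotype,animal_id,hemisphere_id Metadata for the marks.
#' @return A list with `marks` (data.frame: `x_um`, `y_um`, `marker`,
#'   `genotype`, `animal_id`, `hemisphere_id`, `zone_true`), `ventricular`
#'   and `pial` ([boundary_polyline()]).
#' @export
make_marks <- function(profile, n, seed = 1, width_um = 400,
                       height_um = 300, curved = FALSE, marker = "green",
                       genotype = "control", animal_id = "a1",
                       hemisphere_id = "h1") {
  fr <- if (inherits(profile, "genotype_profile")) profile$zone_fractions
        else as.numeric(profile) / sum(profile)
  nz <- length(fr)
  stopifnot(n >= 1)
  set.seed(seed)
  bx <- seq(0, width_um, length.out = 33L)
  amp <- if (curved) 0.06 * height_um else 0
  v_y <- amp * sin(2 * pi * bx / width_um)
  p_y <- height_um + amp * sin(2 * pi * bx / width_um + pi / 3)
  ventricular <- boundary_polyline(bx, v_y, "ventricular")
  pial <- boundary_polyline(bx, p_y, "pial")

  zone <- sample.int(nz, n, replace = TRUE, prob = fr)
  rel <- (zone - 1L + stats::runif(n)) / nz
  x <- stats::runif(n, 0.02 * width_um, 0.98 * width_um)
  # local boundary ordinates at x (linear interpolation along vertices)
  vy <- stats::approx(bx, v_y, xout = x)$y
  py <- stats::approx(bx, p_y, xout = x)$y
  y <- vy + rel * (py - vy)
  marks <- data.frame(x_um = x, y_um = y, marker = marker,
                      genotype = genotype, animal_id = animal_id,
                      hemisphere_id = hemisphere_id, zone_true = zone,
                      stringsAsFactors = FALSE)
  list(marks = marks, ventricular = ventricular, pial = pial)
}

#' Generate synthetic neuron tracks
#'
#' Biased-random-walk tracks sampled at a fixed frame interval over a
#' fixed duration, emulating a two-zone slice-culture time-lapse: start
#' positions follow the two-zone occupancy target, per-step headings mix
#' a pial-ward drift (set by the directionality target) with isotropic
#' noise, and step lengths realise the speed target. A configurable
#' fraction of yellow-labelled tracks is included to exercise the
#' exclusion rule.
#'
#' @param n Number of tracks.
#' @param seed RNG seed.
#' @param occupancy_upper Fraction of tracks starting in the upper zone.
#' @param speed_um_min Target mean straight-line speed for a perfectly
#'   straight track (um/min); realised speeds fall below it as
#'   directionality decreases.
#' @param directionality Target meandering index in `[0, 1]`; 1 yields
#'   perfectly straight pial-ward tracks.
#' @param duration_min,frame_interval_min Sampling grid (defaults: 725 min
#'   at 15-min spacing).
#' @param y_mid Zone boundary (um).
#' @param height_um Tissue height (um).
#' @param yellow_fraction Fraction of tracks labelled yellow.
#' @param channel Label for non-yellow tracks (`"green"` or `"red"`).
#' @return A list of [track()] objects.
#' @export
make_tracks <- function(n, seed = 1, occupancy_upper = 0.5,
                        speed_um_min = 0.5, directionality = 0.8,
                        duration_min = 725, frame_interval_min = 15,
                        y_mid = 150, height_um = 300,
                        yellow_fraction = 0, channel = "green") {
  stopifnot(n >= 1, directionality >= 0, directionality <= 1)
  set.seed(seed)
  nt <- as.integer(duration_min / frame_interval_min)
  times <- (0:nt) * frame_interval_min
  step_len <- speed_um_min * frame_interval_min
  # heading mixture: each step is pial-ward drift with probability
  # `directionality` and isotropic otherwise, so the expected meandering
  # index of a long track approaches the target; directionality = 1
  # gives a straight line (index exactly 1)
  lapply(seq_len(n), function(i) {
    upper <- stats::runif(1) < occupancy_upper
    y0 <- if (upper) stats::runif(1, y_mid, 0.95 * height_um)
          else stats::runif(1, 0.05 * height_um, y_mid)
    x0 <- stats::runif(1, 0, 400)
    drift <- stats::runif(nt) < directionality
    ang <- stats::runif(nt, 0, 2 * pi)
    dx <- step_len * ifelse(drift, 0, cos(ang))
    dy <- step_len * ifelse(drift, 1, sin(ang))
    x <- x0 + cumsum(c(0, dx))
    y <- pmin(pmax(y0 + cumsum(c(0, dy)), 0), height_um)
    ch <- if (stats::runif(1) < yellow_fraction) "yellow" else channel
    track(sprintf("synth_%03d", i), times, x, y, channel = ch)
  })
}

#' Generate a synthetic time-lapse movie with known drift
#'
#' A textured static background plus bright Gaussian-spot "cells" moving
#' independently, warped frame-by-frame with a known smooth global drift
#' field. Returns both the movie and the ground-truth cumulative drift so
#' that flow-recovery tests can compare against truth.
#'
#' @param n_frames Number of frames.
#' @param size Image size in px (square).
#' @param seed RNG seed.
#' @param drift `"constant"`, `"sinusoidal"` or `"none"`: per-frame global
#'   drift model.
#' @param drift_px For `"constant"`: per-frame (dy, dx) in px; for
#'   `"sinusoidal"`: amplitude in px.
#' @param n_cells Number of moving spots.
#' @param cell_speed_px Per-frame spot displacement magnitude.
#' @param noise_sd Additive Gaussian noise level.
#' @param cell_intensity Peak intensity of the cell spots relative to the
#'   unit-range background; kept comparable to the tissue texture so the
#'   spots do not dominate gradient-weighted flow estimates.
#' @return A list with `movie` (a [movie()]), `truth` (list of `n_frames`
#'   cumulative drift fields with matrices `dy`, `dx`), `cells`
#'   (data.frame of spot trajectories: `cell`, `frame`, `y`, `x`, in the
#'   drift-free scene frame).
#' @export
make_movie <- function(n_frames = 20, size = 256, seed = 1,
                       drift = c("sinusoidal", "constant", "none"),
                       drift_px = c(2, 1), n_cells = 6,
                       cell_speed_px = 1.5, noise_sd = 0.005,
                       cell_intensity = 0.6) {
  drift <- match.arg(drift)
  set.seed(seed)
  H <- W <- as.integer(size)
  # band-limited background texture at two spatial scales; the finer
  # scale keeps tissue gradients comparable to the cell spots so the
  # spots do not dominate gradient-weighted flow estimates
  bg <- 0.6 * .gauss_blur(matrix(stats::rnorm(H * W), H, W), 1.2) +
        0.4 * .gauss_blur(matrix(stats::rnorm(H * W), H, W), 4)
  bg <- (bg - min(bg)) / (max(bg) - min(bg))

  # spot trajectories in the static scene frame
  cy <- stats::runif(n_cells, 0.2 * H, 0.8 * H)
  cx <- stats::runif(n_cells, 0.2 * W, 0.8 * W)
  th <- stats::runif(n_cells, 0, 2 * pi)
  cells <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    data.frame(cell = i, frame = seq_len(n_frames),
               y = cy[i] + (seq_len(n_frames) - 1L) * cell_speed_px * sin(th[i]),
               x = cx[i] + (seq_len(n_frames) - 1L) * cell_speed_px * cos(th[i]))
  }))

  cum_drift <- function(t) {
    # cumulative drift at frame t (frame 1 = 0)
    switch(drift,
      none = c(0, 0),
      constant = (t - 1) * drift_px[c(1, 2)],
      sinusoidal = {
        a <- drift_px[1L]
        c(a * sin(2 * pi * (t - 1) / n_frames),
          a * (1 - cos(2 * pi * (t - 1) / n_frames)))
      })
  }

  gy <- rep(seq_len(H), W)
  gx <- rep(seq_len(W), each = H)
  arr <- array(0, c(n_frames, H, W))
  truth <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    d <- cum_drift(t)
    # frame_t(x) = scene(x - d): the scene drifts by +d, and sampling the
    # frame at x + d recovers the scene, so +d is the cumulative flow the
    # correction should recover
    fr <- matrix(.sample_bilinear(bg, gy - d[1L], gx - d[2L]), H, W)
    sel <- cells$frame == t
    for (i in which(sel)) {
      sy <- cells$y[i] + d[1L]
      sx <- cells$x[i] + d[2L]
      ry <- max(1L, floor(sy - 6)):min(H, ceiling(sy + 6))
      rx <- max(1L, floor(sx - 6)):min(W, ceiling(sx + 6))
      g <- outer(exp(-(ry - sy)^2 / (2 * 2^2)), exp(-(rx - sx)^2 / (2 * 2^2)))
      fr[ry, rx] <- fr[ry, rx] + cell_intensity * g
    }
    if (noise_sd > 0) fr <- fr + stats::rnorm(H * W, sd = noise_sd)
    arr[t, , ] <- fr
    truth[[t]] <- list(dy = matrix(d[1L], H, W), dx = matrix(d[2L], H, W))
  }
  list(movie = movie(arr), truth = truth, cells = cells)
}
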