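#' Time-lapse movie container
#'
#' An intensity stack indexed `(t, y, x)` per channel, with physical
#' metadata. Movies are 2D projections; all channels share one shape.
#'
#' @param channels A list of 3D numeric arrays `(t, y, x)` (a single array
#'   is wrapped); all with identical dimensions, at least 1 frame.
#' @param pixel_size_um Pixel size (um/px).
#' @param frame_interval_min Frame interval (min).
#' @return An object of class `movie`.
#' @export
movie <- function(channels, pixel_size_um = 1, frame_interval_min = 15) {
  if (is.array(channels) && length(dim(channels)) == 3L)
    channels <- list(channels)
  stopifnot(is.list(channels), length(channels) >= 1L)
  d <- dim(channels[[1L]])
  if (length(d) != 3L)
    stop("each channel must be a (t, y, x) array", call. = FALSE)
  for (ch in channels)
    if (!identical(dim(ch), d))
      stop("all channels must share the same dimensions", call. = FALSE)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf(
    "<movie> %d channel(s), %d frames, %d x %d px, %g um/px, %g min/frame\n",
    length(x$channels), d[1L], d[2L], d[3L], x$pixel_size_um,
    x$frame_interval_min))
  invisible(x)
}

.movie_frames <- function(mov) dim(mov$channels[[1L]])[1L]

# channel-averaged frame t as a (y, x) matrix
.avg_frame <- function(mov, t) {
  acc <- NULL
  for (ch in mov$channels) {
    fr <- ch[t, , ]
    acc <- if (is.null(acc)) fr else acc + fr
  }
  acc / length(mov$channels)
}

#' Pairwise dense optical flow of a movie
#'
#' Estimates the dense optical flow between every successive frame pair
#' using a Farneback-style polynomial-expansion method (quadratic local
#' models, iterative displacement refinement over an averaging window,
#' coarse-to-fine pyramid). Multi-channel movies are averaged across
#' channels before estimation. Defaults follow the drift-correction
#' protocol: 3 pyramid levels, 512 px averaging window (clipped to the
#' image for smaller inputs), 5 px polynomial neighbourhood, 0.4 px
#' derivative-smoothing Gaussian, 3 iterations per level.
#'
#' @param mov A [movie()] with at least 2 frames.
#' @param pyr_levels,winsize,poly_n,poly_sigma,iterations Farneback
#'   parameters (see above).
#' @return A list of `T - 1` flow fields; each is a list with matrices
#'   `dy`, `dx` (displacement in px mapping frame t onto frame t+1).
#' @export
estimate_pairwise_flow <- function(mov, pyr_levels = 3, winsize = 512,
                                   poly_n = 5, poly_sigma = 0.4,
                                   iterations = 3) {
  stopifnot(inherits(mov, "movie"))
  n <- .movie_frames(mov)
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  prev <- .avg_frame(mov, 1L)
  out <- vector("list", n - 1L)
  for (t in seq_len(n - 1L)) {
    nxt <- .avg_frame(mov, t + 1L)
    out[[t]] <- .farneback_flow(prev, nxt, pyr_levels = pyr_levels,
                                winsize = winsize, poly_n = poly_n,
                                poly_sigma = poly_sigma,
                                iterations = iterations)
    prev <- nxt
  }
  out
}

#' Spatio-temporal smoothing of pairwise flow fields
#'
#' Gaussian smoothing of each flow component over (t, y, x). The strong
#' spatial smoothing removes small-scale motion (single migrating cells)
#' while preserving spatially coherent tissue drift. Borders are handled
#' by reflection, so spatially constant flow is unchanged.
#'
#' @param flows List of flow fields from [estimate_pairwise_flow()].
#' @param sigma_t Temporal standard deviation (frames).
#' @param sigma_xy Spatial standard deviation (px).
#' @return Smoothed list of flow fields.
#' @export
smooth_flow <- function(flows, sigma_t = 1, sigma_xy = 25.6) {
  stopifnot(is.list(flows), length(flows) >= 1L)
  nt <- length(flows)
  sm_spatial <- lapply(flows, function(fl)
    list(dy = .gauss_blur(fl$dy, sigma_xy), dx = .gauss_blur(fl$dx, sigma_xy)))
  if (sigma_t <= 0 || nt == 1L) return(sm_spatial)
  kt <- .gauss_kernel(sigma_t)
  rt <- (length(kt) - 1L) %/% 2L
  idx <- .reflect_idx(nt, rt)
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    dy <- 0; dx <- 0
    for (i in seq_along(kt)) {
      src <- sm_spatial[[idx[t + i - 1L]]]
      dy <- dy + kt[i] * src$dy
      dx <- dx + kt[i] * src$dx
    }
    out[[t]] <- list(dy = dy, dx = dx)
  }
  out
}

#' Temporal integration of pairwise flows to a reference frame
#'
#' Composes the smoothed pairwise fields into cumulative displacement
#' fields relative to the first frame: the cumulative flow at frame k+1 is
#' the cumulative flow at frame k plus the k-th pairwise field sampled at
#' the displaced position (cubic interpolation), not a naive per-pixel
#' sum.
#'
#' @param flows List of `T - 1` (smoothed) pairwise flow fields, ordered
#'   in time.
#' @return List of `T` cumulative flow fields; the first is zero.
#' @export
integrate_flow <- function(flows) {
  stopifnot(is.list(flows), length(flows) >= 1L)
  H <- nrow(flows[[1L]]$dy); W <- ncol(flows[[1L]]$dy)
  gy <- rep(seq_len(H), W)
  gx <- rep(seq_len(W), each = H)
  cum <- vector("list", length(flows) + 1L)
  cum[[1L]] <- list(dy = matrix(0, H, W), dx = matrix(0, H, W))
  for (k in seq_along(flows)) {
    cy <- cum[[k]]$dy; cx <- cum[[k]]$dx
    yy <- gy + as.vector(cy)
    xx <- gx + as.vector(cx)
    inc_y <- .sample_bicubic(flows[[k]]$dy, yy, xx)
    inc_x <- .sample_bicubic(flows[[k]]$dx, yy, xx)
    cum[[k + 1L]] <- list(dy = cy + matrix(inc_y, H, W),
                          dx = cx + matrix(inc_x, H, W))
  }
  cum
}

#' Unwarp a movie with cumulative flow fields
#'
#' Renders a drift-corrected movie by resampling every frame at the
#' position given by its cumulative flow field (cubic interpolation for
#' intensities), so that coherent tissue drift is removed. The reference
#' frame (frame 1) is returned unchanged. Pixels that map outside the
#' field of view are filled with 0 and flagged in a validity mask
#' (nearest-neighbour logic, no interpolation on the mask).
#'
#' @param mov A [movie()].
#' @param cumulative List of `T` cumulative flow fields from
#'   [integrate_flow()].
#' @return A list with `movie` (corrected [movie()]) and `valid` (logical
#'   `(t, y, x)` array; `FALSE` where intensities were filled).
#' @export
unwarp <- function(mov, cumulative) {
  stopifnot(inherits(mov, "movie"), is.list(cumulative))
  n <- .movie_frames(mov)
  d <- dim(mov$channels[[1L]])
  if (length(cumulative) != n)
    stop("need one cumulative flow field per frame", call. = FALSE)
  H <- d[2L]; W <- d[3L]
  if (nrow(cumulative[[1L]]$dy) != H || ncol(cumulative[[1L]]$dy) != W)
    stop("flow-field shape does not match the movie", call. = FALSE)
  gy <- rep(seq_len(H), W)
  gx <- rep(seq_len(W), each = H)
  out <- lapply(mov$channels, function(ch) array(0, d))
  valid <- array(TRUE, d)
  for (t in seq_len(n)) {
    yy <- gy + as.vector(cumulative[[t]]$dy)
    xx <- gx + as.vector(cumulative[[t]]$dx)
    inside <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    for (c in seq_along(mov$channels)) {
      v <- .sample_bicubic(mov$channels[[c]][t, , ], yy, xx)
      v[!inside] <- 0
      out[[c]][t, , ] <- matrix(v, H, W)
    }
    valid[t, , ] <- matrix(inside, H, W)
  }
  list(movie = movie(out, mov$pixel_size_um, mov$frame_interval_min),
       valid = valid)
}

#' Full drift-correction pipeline
#'
#' Convenience wrapper: pairwise flow, spatio-temporal smoothing,
#' temporal integration and unwarping.
#'
#' @param mov A [movie()].
#' @param sigma_t,sigma_xy Smoothing parameters, see [smooth_flow()].
#' @param ... Flow parameters passed to [estimate_pairwise_flow()].
#' @return As [unwarp()], plus `cumulative` (the integrated flow fields).
#' @export
undrift_movie <- function(mov, sigma_t = 1, sigma_xy = 25.6, ...) {
  flows <- estimate_pairwise_flow(mov, ...)
  sm <- smooth_flow(flows, sigma_t = sigma_t, sigma_xy = sigma_xy)
  cum <- integrate_flow(sm)
  res <- unwarp(mov, cum)
  res$cumulative <- cum
  res
}
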