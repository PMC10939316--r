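#' Construct a track
#'
#' A timed 2D trajectory of one tracked neuron. Times must be strictly
#' increasing; frame gaps are permitted (statistics use the actual
#' timestamps, so no interpolation is needed).
#'
#' @param track_id Identifier (coerced to character).
#' @param t_min,x_um,y_um Numeric vectors of equal length: time (min) and
#'   position (um).
#' @param channel Channel/colour label (`"green"`, `"red"`; `"yellow"`
#'   allowed on input and excluded by analyses that follow the
#'   red/green-only rule).
#' @return An object of class `track`.
#' @export
track <- function(track_id, t_min, x_um, y_um, channel = "green") {
  stopifnot(length(t_min) == length(x_um), length(t_min) == length(y_um))
  if (length(t_min) >= 2L && any(diff(t_min) <= 0))
    stop("track times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(c(t_min, x_um, y_um))))
    stop("track coordinates and times must be finite", call. = FALSE)
  structure(list(track_id = as.character(track_id),
                 t_min = as.numeric(t_min), x_um = as.numeric(x_um),
                 y_um = as.numeric(y_um),
                 channel = as.character(channel)[1L]),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s> %d samples, %s, t = [%g, %g] min\n", x$track_id,
              length(x$t_min), x$channel, x$t_min[1L],
              x$t_min[length(x$t_min)]))
  invisible(x)
}

#' Total and net distance of a track
#'
#' `d_tot` is the sum of Euclidean distances between consecutive samples,
#' `d_net` the Euclidean distance between the first and last sample and
#' `t_net` the elapsed time.
#'
#' @param tr A [track()] with at least 2 samples.
#' @return A list with `d_tot`, `d_net` (um) and `t_net` (min).
#' @export
track_distances <- function(tr) {
  stopifnot(inherits(tr, "track"))
  n <- length(tr$t_min)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  seg <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  list(d_tot = sum(seg),
       d_net = sqrt((tr$x_um[n] - tr$x_um[1L])^2 +
                    (tr$y_um[n] - tr$y_um[1L])^2),
       t_net = tr$t_min[n] - tr$t_min[1L])
}

#' Mean straight-line speed
#'
#' Net displacement divided by elapsed time, in um/min. Because actual
#' timestamps are used, tracks with differing frame gaps are directly
#' comparable.
#'
#' @param tr A [track()].
#' @return Speed in um/min.
#' @export
mean_straight_line_speed <- function(tr) {
  d <- track_distances(tr)
  if (d$t_net <= 0) stop("t_net must be positive", call. = FALSE)
  d$d_net / d$t_net
}

#' Directionality (meandering) index
#'
#' Net distance divided by total distance; 1 for a straight monotone
#' path, 0 for a closed loop. Undefined (error) for a stationary track.
#'
#' @param tr A [track()].
#' @return Index in `[0, 1]`.
#' @export
directionality_index <- function(tr) {
  d <- track_distances(tr)
  if (d$d_tot <= 0)
    stop("directionality undefined for a stationary track (d_tot = 0)",
         call. = FALSE)
  d$d_net / d$d_tot
}

#' Per-track summary statistics
#'
#' @param tracks A list of [track()] objects.
#' @return A data.frame with one row per track: `track_id`, `channel`,
#'   `n_samples`, `d_tot`, `d_net`, `t_net`, `speed` (mean straight-line,
#'   um/min), `directionality` (`NA` if stationary).
#' @export
track_stats <- function(tracks) {
  stopifnot(is.list(tracks), all(vapply(tracks, inherits, TRUE, "track")))
  rows <- lapply(tracks, function(tr) {
    d <- track_distances(tr)
    data.frame(track_id = tr$track_id, channel = tr$channel,
               n_samples = length(tr$t_min), d_tot = d$d_tot,
               d_net = d$d_net, t_net = d$t_net,
               speed = if (d$t_net > 0) d$d_net / d$t_net else NA_real_,
               directionality = if (d$d_tot > 0) d$d_net / d$d_tot
                                else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Zone geometry for the two-zone analysis
#'
#' @param y_mid Boundary (um) between the lower zone (VZ/SVZ + IZ) and the
#'   upper zone (CP).
#' @param pial_side Which side of the boundary is pial: `"high"` (larger y
#'   toward the pia, the default) or `"low"`.
#' @return An object of class `zone_geometry`.
#' @export
zone_geometry <- function(y_mid, pial_side = c("high", "low")) {
  pial_side <- match.arg(pial_side)
  stopifnot(is.numeric(y_mid), length(y_mid) == 1L, is.finite(y_mid))
  structure(list(y_mid = y_mid, pial_side = pial_side),
            class = "zone_geometry")
}

.is_upper <- function(y, geometry) {
  if (geometry$pial_side == "high") y > geometry$y_mid else y < geometry$y_mid
}

#' Group tracks into upper and lower zones
#'
#' Any-frame rule: a track belongs to the upper zone if the cell was in
#' the upper-zone area in any frame, and to the lower zone only if it was
#' never there. Samples exactly on the boundary count as lower (strict
#' inequality).
#'
#' @param tracks List of [track()] objects.
#' @param geometry A [zone_geometry()].
#' @return A list with elements `upper` and `lower` (lists of tracks);
#'   every input track appears in exactly one.
#' @export
assign_zone_groups <- function(tracks, geometry) {
  stopifnot(inherits(geometry, "zone_geometry"))
  up <- vapply(tracks, function(tr) any(.is_upper(tr$y_um, geometry)), TRUE)
  list(upper = tracks[up], lower = tracks[!up])
}

#' Split a track at zone-boundary crossings
#'
#' A track is split into sub-tracks wherever consecutive samples lie
#' strictly on opposite sides of `y_mid`; the sample after the crossing
#' starts the new sub-track (no interpolated sample is inserted).
#' Sub-tracks inherit the parent id with a numeric suffix.
#'
#' @param tr A [track()].
#' @param y_mid Boundary position (um).
#' @return A list with `subtracks` (list of tracks) and `crossing`
#'   (logical: did the track cross at all).
#' @export
split_crossing_tracks <- function(tr, y_mid) {
  stopifnot(inherits(tr, "track"))
  side <- tr$y_um > y_mid
  cross_after <- which(side[-1L] != side[-length(side)])
  if (!length(cross_after))
    return(list(subtracks = list(tr), crossing = FALSE))
  # consecutive sub-tracks share the boundary sample so that sub-track
  # path lengths sum exactly to the parent's d_tot
  starts <- c(1L, cross_after + 1L)
  ends <- c(cross_after + 1L, length(tr$t_min))
  subtracks <- lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    track(paste0(tr$track_id, ".", i), tr$t_min[idx], tr$x_um[idx],
          tr$y_um[idx], tr$channel)
  })
  list(subtracks = subtracks, crossing = TRUE)
}

#' Top tracks by net distance
#'
#' Ranks tracks by decreasing `d_net`, breaking ties by `track_id`
#' (deterministic), and returns the first `min(n, length(tracks))`.
#'
#' @param tracks List of [track()] objects.
#' @param n Number of tracks to keep (default 15, the per-video ranking
#'   depth used for speed/directionality summaries).
#' @return A list of tracks in rank order.
#' @export
top_n_by_net_distance <- function(tracks, n = 15) {
  stopifnot(n >= 1)
  if (!length(tracks)) return(tracks)
  dn <- vapply(tracks, function(tr) track_distances(tr)$d_net, 0)
  ids <- vapply(tracks, function(tr) tr$track_id, "")
  tracks[order(-dn, ids)][seq_len(min(n, length(tracks)))]
}

#' Zone occupancy at the start and end of a time-lapse
#'
#' Fraction of cells per zone at two timepoints. A cell's position at a
#' timepoint is its nearest sample within `max_gap` minutes (tracks
#' without one are excluded with a warning). Yellow-labelled tracks are
#' excluded: only red and green tracks enter the analysis.
#'
#' @param tracks List of [track()] objects.
#' @param geometry A [zone_geometry()].
#' @param t_start,t_end Timepoints in minutes.
#' @param max_gap Largest tolerated distance (min) between a timepoint and
#'   the nearest sample; defaults to two 15-min frames.
#' @return A data.frame with columns `timepoint`, `zone`, `n`, `fraction`.
#' @export
start_end_distribution <- function(tracks, geometry, t_start = 0,
                                   t_end = 725, max_gap = 30) {
  stopifnot(inherits(geometry, "zone_geometry"))
  yellow <- vapply(tracks, function(tr) identical(tr$channel, "yellow"), TRUE)
  if (any(yellow)) {
    warning(sprintf("excluding %d yellow track(s)", sum(yellow)),
            call. = FALSE)
    tracks <- tracks[!yellow]
  }
  if (!length(tracks)) {
    warning("no red/green tracks to analyse", call. = FALSE)
    return(data.frame(timepoint = numeric(0), zone = character(0),
                      n = integer(0), fraction = numeric(0)))
  }
  zone_at <- function(tr, tp) {
    i <- which.min(abs(tr$t_min - tp))
    if (abs(tr$t_min[i] - tp) > max_gap) return(NA_character_)
    if (.is_upper(tr$y_um[i], geometry)) "upper" else "lower"
  }
  out <- lapply(c(start = t_start, end = t_end), function(tp) {
    z <- vapply(tracks, zone_at, "", tp)
    if (anyNA(z))
      warning(sprintf("%d track(s) have no sample within %g min of t = %g",
                      sum(is.na(z)), max_gap, tp), call. = FALSE)
    z <- z[!is.na(z)]
    data.frame(timepoint = tp,
               zone = c("lower", "upper"),
               n = c(sum(z == "lower"), sum(z == "upper")),
               fraction = if (length(z))
                 c(mean(z == "lower"), mean(z == "upper"))
               else c(NA_real_, NA_real_))
  })
  rbind(out$start, out$end)
}
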