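#' Read a TrackMate-style track table
#'
#' Reads a CSV export of tracked spots into a list of [track()] objects.
#' Column names are configurable; time is taken from a time column (min)
#' or computed as `FRAME * frame_interval`. Rows are sorted by time within
#' each track. Yellow-channel tracks are retained but flagged; analyses
#' that follow the red/green-only rule exclude them explicitly.
#'
#' @param path CSV file path.
#' @param columns Named list mapping roles to column names: `track_id`,
#'   `x`, `y`, and either `t` or `frame`; optionally `channel`.
#' @param frame_interval_min Frame interval used with a `frame` column.
#' @return A list of [track()] objects.
#' @export
read_tracks <- function(path,
                        columns = list(track_id = "TRACK_ID",
                                       x = "POSITION_X", y = "POSITION_Y",
                                       t = "POSITION_T",
                                       channel = "CHANNEL"),
                        frame_interval_min = 15) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # fall back to this package's native column names when the mapped
  # track-id column is absent (e.g. tables written by write_tracks())
  native <- list(track_id = "track_id", x = "x_um", y = "y_um",
                 t = "t_min", channel = "channel")
  if (!is.null(columns[["track_id"]]) &&
      !columns[["track_id"]] %in% names(df) &&
      all(unlist(native[c("track_id", "x", "y", "t")]) %in% names(df)))
    columns <- native
  need <- c("track_id", "x", "y")
  for (role in need) {
    cn <- columns[[role]]
    if (is.null(cn) || !cn %in% names(df))
      stop(sprintf("missing mapped column '%s' (role %s) in %s",
                   cn %||% "<unset>", role, path), call. = FALSE)
  }
  has_t <- !is.null(columns[["t"]]) && columns[["t"]] %in% names(df)
  has_f <- !is.null(columns[["frame"]]) && columns[["frame"]] %in% names(df)
  if (!has_t && !has_f)
    stop("need a time column ('t') or a frame column ('frame')",
         call. = FALSE)
  tcol <- if (has_t) as.numeric(df[[columns[["t"]]]])
          else as.numeric(df[[columns[["frame"]]]]) * frame_interval_min
  for (role in c("x", "y")) {
    v <- df[[columns[[role]]]]
    bad <- which(is.na(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop(sprintf("non-numeric %s value at row %d of %s", role, bad[1L],
                   path), call. = FALSE)
  }
  if (anyNA(tcol))
    stop("non-numeric time value in ", path, call. = FALSE)
  ch <- if (!is.null(columns[["channel"]]) &&
            columns[["channel"]] %in% names(df))
    as.character(df[[columns[["channel"]]]]) else rep("green", nrow(df))

  ids <- as.character(df[[columns[["track_id"]]]])
  out <- lapply(split(seq_len(nrow(df)), ids), function(idx) {
    o <- idx[order(tcol[idx])]
    tt <- tcol[o]
    if (any(diff(tt) <= 0))
      stop(sprintf("non-increasing time within track %s (row %d)",
                   ids[o[1L]], o[which(diff(tt) <= 0)[1L] + 1L]),
           call. = FALSE)
    track(ids[o[1L]], tt, as.numeric(df[[columns$x]])[o],
          as.numeric(df[[columns$y]])[o], channel = ch[o[1L]])
  })
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write tracks as a CSV table
#'
#' @param tracks List of [track()] objects or a trajectory data.frame
#'   (`cell_id`/`track_id`, `t_min`, `x_um`, `y_um`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- if (is.data.frame(tracks)) tracks else
    do.call(rbind, lapply(tracks, function(tr)
      data.frame(track_id = tr$track_id, channel = tr$channel,
                 t_min = tr$t_min, x_um = tr$x_um, y_um = tr$y_um,
                 stringsAsFactors = FALSE)))
  # 17 significant digits so numeric columns round-trip bit-exactly
  for (cn in names(df))
    if (is.numeric(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read boundary polylines from JSON
#'
#' Expects a JSON array of objects with fields `role` and `vertices`
#' (list of `[x, y]` pairs or an object with `x`/`y` arrays).
#'
#' @param path JSON file path.
#' @return A named list of [boundary_polyline()] (names = roles).
#' @export
read_boundaries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (b in js) {
    if (is.null(b$role) || is.null(b$vertices))
      stop("boundary entries need 'role' and 'vertices': ", path,
           call. = FALSE)
    v <- b$vertices
    if (!is.null(v$x)) {
      x <- as.numeric(unlist(v$x)); y <- as.numeric(unlist(v$y))
    } else {
      m <- do.call(rbind, lapply(v, unlist))
      x <- as.numeric(m[, 1L]); y <- as.numeric(m[, 2L])
    }
    out[[b$role]] <- boundary_polyline(x, y, b$role)
  }
  out
}

#' Write boundary polylines to JSON
#'
#' @param boundaries List of [boundary_polyline()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  js <- lapply(boundaries, function(b)
    list(role = b$role, vertices = list(x = b$x_um, y = b$y_um)))
  jsonlite::write_json(unname(js), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie from a multi-page TIFF
#'
#' Reads intensity data via [read_tiff()]; physical metadata comes from a
#' JSON sidecar (`<path>.json`, fields `pixel_size_um`,
#' `frame_interval_min`, optional `n_channels` for interleaved TCYX
#' stacks) when present.
#'
#' @param path TIFF file path.
#' @return A [movie()].
#' @export
read_movie <- function(path) {
  arr <- read_tiff(path)
  meta_path <- paste0(path, ".json")
  px <- 1; fi <- 15; nch <- 1L
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    px <- meta$pixel_size_um %||% 1
    fi <- meta$frame_interval_min %||% 15
    nch <- as.integer(meta$n_channels %||% 1L)
  }
  channels <- if (nch > 1L) {
    nt <- dim(arr)[1L] %/% nch
    lapply(seq_len(nch), function(c)
      arr[seq(c, by = nch, length.out = nt), , , drop = FALSE])
  } else {
    list(arr)
  }
  movie(channels, pixel_size_um = px, frame_interval_min = fi)
}

#' Write a movie to a multi-page TIFF (+ JSON sidecar)
#'
#' Multi-channel movies are interleaved as TCYX pages; the channel count
#' and physical metadata go into a `<path>.json` sidecar.
#'
#' @param mov A [movie()].
#' @param path Output TIFF path.
#' @param format Pixel format, see [write_tiff()].
#' @return `path`, invisibly.
#' @export
write_movie <- function(mov, path, format = "float32") {
  stopifnot(inherits(mov, "movie"))
  nch <- length(mov$channels)
  d <- dim(mov$channels[[1L]])
  arr <- array(0, c(d[1L] * nch, d[2L], d[3L]))
  for (t in seq_len(d[1L]))
    for (c in seq_len(nch))
      arr[(t - 1L) * nch + c, , ] <- mov$channels[[c]][t, , ]
  write_tiff(arr, path, format = format)
  jsonlite::write_json(list(pixel_size_um = mov$pixel_size_um,
                            frame_interval_min = mov$frame_interval_min,
                            n_channels = nch),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Provenance block for result files
#'
#' @param config A list of run parameters (hashed into the block).
#' @param seed The run seed.
#' @return A list with `package`, `version`, `seed`, `config_hash`,
#'   `config`.
#' @export
provenance <- function(config = list(), seed = NA_integer_) {
  ser <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  list(package = "corticowalk",
       version = as.character(utils::packageVersion("corticowalk")),
       seed = seed,
       config_hash = .simple_hash(as.character(ser)),
       config = config)
}

# small stable polynomial string hash (hex); avoids external digest
# packages and stays within exact double-precision integer arithmetic
.simple_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write an analysis result with a provenance block
#'
#' Tables are written as CSV next to a `<path>.json` summary carrying the
#' provenance (package version, seed, config hash).
#'
#' @param tables Named list of data.frames (written as `<stem>_<name>.csv`).
#' @param summary A list of summary values for the JSON file.
#' @param stem Output path stem (no extension).
#' @param config,seed Passed to [provenance()].
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, summary, stem, config = list(),
                          seed = NA_integer_) {
  paths <- character(0)
  for (nm in names(tables)) {
    p <- paste0(stem, "_", nm, ".csv")
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- paste0(stem, ".json")
  jsonlite::write_json(c(summary, list(provenance = provenance(config, seed))),
                       jp, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(c(paths, jp))
}
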