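# Track containers: a single cell trajectory and a collection of them.

#' QC flag vocabulary for tracks
#'
#' Flags carried by a [cell_track]: `edge_of_slice` and `near_glass` mark
#' tracks excluded by default during filtering; `interpolated_frames` marks
#' tracks containing gap-filled positions; `localization_noise` and `gapped`
#' are set by the synthetic imaging-artifact injector; `degenerate` marks
#' zero-length paths.
#'
#' @export
track_flag_vocabulary <- c(
  "edge_of_slice", "near_glass", "interpolated_frames",
  "localization_noise", "gapped", "degenerate"
)

#' Construct a single cell track
#'
#' A track is one cell's time-ordered 2D trajectory in physical units:
#' positions in micrometers, times in minutes, sampled on a fixed frame grid
#' (gaps, i.e. missing frames, are allowed until filtering interpolates or
#' splits them).
#'
#' @param track_id Unique track identifier (coerced to character).
#' @param x,y Numeric positions, micrometers. Equal length, finite.
#' @param frame Integer frame indices, strictly increasing. Defaults to
#'   `0:(n-1)`.
#' @param frame_interval Frame interval in minutes (default 2, the acquisition
#'   interval of the brain-slice movies this pipeline targets).
#' @param t Times in minutes; defaults to `frame * frame_interval`.
#' @param condition Experimental condition label.
#' @param flags Character subset of [track_flag_vocabulary].
#' @param interpolated Logical vector marking gap-filled points.
#' @param source Provenance string.
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(track_id, x, y, frame = NULL, frame_interval = 2,
                       t = NULL, condition = "default", flags = character(),
                       interpolated = NULL, source = "r") {
  n <- length(x)
  if (length(y) != n)
    stop("cell_track: x and y must have equal length", call. = FALSE)
  if (n < 2L)
    stop("cell_track: a track needs at least 2 points", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("cell_track: positions must be finite", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("cell_track: frame_interval must be a positive scalar (minutes)",
         call. = FALSE)
  if (is.null(frame)) frame <- seq_len(n) - 1L
  frame <- as.integer(round(frame))
  if (length(frame) != n || any(diff(frame) <= 0L))
    stop("cell_track: frame indices must be strictly increasing, one per point",
         call. = FALSE)
  if (is.null(t)) t <- frame * frame_interval
  if (length(t) != n || any(diff(t) <= 0))
    stop("cell_track: times must be strictly increasing", call. = FALSE)
  mult <- diff(t) / frame_interval
  if (any(abs(mult - round(mult)) > 1e-6))
    stop("cell_track: time spacing must be an integer multiple of frame_interval",
         call. = FALSE)
  bad <- setdiff(flags, track_flag_vocabulary)
  if (length(bad))
    stop("cell_track: unknown flags: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(interpolated)) interpolated <- rep(FALSE, n)
  stopifnot(length(interpolated) == n, is.logical(interpolated))
  structure(
    list(track_id = as.character(track_id), condition = as.character(condition),
         frame = frame, t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         frame_interval = frame_interval, flags = unique(flags),
         interpolated = interpolated, source = source),
    class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> %s [%s]: %d points, dt = %g min, flags: %s\n",
              x$track_id, x$condition, length(x$t), x$frame_interval,
              if (length(x$flags)) paste(x$flags, collapse = ",") else "none"))
  invisible(x)
}

#' @export
length.cell_track <- function(x) length(x$t)

# TRUE when the track sits on a complete frame grid (no missing frames)
is_uniform_track <- function(track) {
  all(diff(track$frame) == 1L)
}

#' Construct a collection of tracks
#'
#' @param tracks List of [cell_track] objects with unique `track_id`s.
#' @param metadata List of acquisition descriptors (e.g. `frame_interval`
#'   minutes, `pixel_size` micrometers, `conditions`). When tracks have mixed
#'   frame intervals, `metadata$mixed_acquisition` must be `TRUE`.
#' @return An object of class `track_collection`.
#' @export
track_collection <- function(tracks = list(), metadata = list()) {
  stopifnot(is.list(tracks))
  for (tr in tracks)
    if (!inherits(tr, "cell_track"))
      stop("track_collection: all elements must be cell_track objects",
           call. = FALSE)
  ids <- vapply(tracks, `[[`, character(1), "track_id")
  if (anyDuplicated(ids))
    stop("track_collection: duplicated track_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(tracks) <- ids
  if (length(tracks)) {
    dts <- vapply(tracks, `[[`, numeric(1), "frame_interval")
    if (length(unique(dts)) > 1L && !isTRUE(metadata$mixed_acquisition))
      stop("track_collection: tracks have mixed frame intervals; set ",
           "metadata$mixed_acquisition = TRUE to allow", call. = FALSE)
    if (is.null(metadata$frame_interval)) metadata$frame_interval <- dts[[1L]]
  }
  structure(list(tracks = tracks, metadata = metadata),
            class = "track_collection")
}

#' @export
print.track_collection <- function(x, ...) {
  cat(sprintf("<track_collection> %d tracks", length(x$tracks)))
  if (!is.null(x$metadata$frame_interval))
    cat(sprintf(", dt = %g min", x$metadata$frame_interval))
  cat("\n")
  invisible(x)
}

#' @export
length.track_collection <- function(x) length(x$tracks)

#' Flatten a track collection to a tidy data.frame
#'
#' One row per (track, frame) with columns `track_id`, `frame`, `t_min`,
#' `x_um`, `y_um`, `condition`, flag indicator columns, and `interpolated`.
#'
#' @param x A [track_collection].
#' @param row.names,optional,... Ignored; present for the generic.
#' @export
as.data.frame.track_collection <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  if (!length(x$tracks)) {
    return(data.frame(track_id = character(), frame = integer(),
                      t_min = numeric(), x_um = numeric(), y_um = numeric(),
                      condition = character(), edge_of_slice = logical(),
                      near_glass = logical(), interpolated = logical(),
                      stringsAsFactors = FALSE))
  }
  dfs <- lapply(x$tracks, function(tr) {
    data.frame(track_id = tr$track_id, frame = tr$frame, t_min = tr$t,
               x_um = tr$x, y_um = tr$y, condition = tr$condition,
               edge_of_slice = "edge_of_slice" %in% tr$flags,
               near_glass = "near_glass" %in% tr$flags,
               interpolated = tr$interpolated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}
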