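# Reading, validating, filtering and writing cell-track data.

#' Read a TrackMate results XML file
#'
#' Parses the TrackMate (v7) model subset: `Model/AllSpots` for spot
#' positions (`POSITION_X`/`POSITION_Y`, micrometers, and `FRAME`),
#' `Model/AllTracks` for the edge lists joining spots into tracks, and
#' `Model/FilteredTracks` (when present) to restrict to tracks that passed
#' TrackMate's own filters. Gaps left by the tracker's gap-closing are
#' preserved as missing frames; no interpolation happens here.
#'
#' @param path Path to a TrackMate XML file.
#' @param frame_interval Frame interval in minutes. Defaults to the
#'   `timeinterval` attribute of `Settings/ImageData` when present, else 2.
#' @param condition Condition label attached to every track.
#' @return A [track_collection] with one track per TrackMate track.
#' @export
read_trackmate_xml <- function(path, frame_interval = NULL,
                               condition = "default") {
  if (!file.exists(path))
    stop("read_trackmate_xml: file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("read_trackmate_xml: unreadable XML (", conditionMessage(e), ")",
         call. = FALSE))

  if (is.null(frame_interval)) {
    img <- xml2::xml_find_first(doc, ".//Settings/ImageData")
    ti <- if (!inherits(img, "xml_missing"))
      suppressWarnings(as.numeric(xml2::xml_attr(img, "timeinterval"))) else NA
    frame_interval <- if (is.finite(ti) && !is.na(ti) && ti > 0) ti else 2
  }

  spots <- xml2::xml_find_all(doc, ".//Model/AllSpots//Spot")
  spot_tab <- NULL
  if (length(spots)) {
    sid <- xml2::xml_attr(spots, "ID")
    sx <- suppressWarnings(as.numeric(xml2::xml_attr(spots, "POSITION_X")))
    sy <- suppressWarnings(as.numeric(xml2::xml_attr(spots, "POSITION_Y")))
    sf <- suppressWarnings(as.integer(xml2::xml_attr(spots, "FRAME")))
    bad <- which(is.na(sx) | is.na(sy) | is.na(sf))
    if (length(bad))
      stop("read_trackmate_xml: spot ", sid[bad[1L]],
           " lacks POSITION_X/POSITION_Y/FRAME", call. = FALSE)
    if (anyDuplicated(sid))
      stop("read_trackmate_xml: duplicated spot ID", call. = FALSE)
    spot_tab <- data.frame(id = sid, x = sx, y = sy, frame = sf,
                           stringsAsFactors = FALSE)
    rownames(spot_tab) <- sid
  }

  track_nodes <- xml2::xml_find_all(doc, ".//Model/AllTracks/Track")
  if (!length(track_nodes)) {
    warning("read_trackmate_xml: no tracks in ", path)
    return(track_collection(metadata = list(frame_interval = frame_interval,
                                            source = path)))
  }
  tids <- xml2::xml_attr(track_nodes, "TRACK_ID")
  if (anyDuplicated(tids))
    stop("read_trackmate_xml: duplicated TRACK_ID: ",
         paste(unique(tids[duplicated(tids)]), collapse = ", "), call. = FALSE)

  keep_ids <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//Model/FilteredTracks/TrackID"), "TRACK_ID")

  tracks <- list()
  for (i in seq_along(track_nodes)) {
    tid <- tids[[i]]
    if (length(keep_ids) && !(tid %in% keep_ids)) next
    edges <- xml2::xml_find_all(track_nodes[[i]], "Edge")
    sids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                     xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    missing <- setdiff(sids, spot_tab$id)
    if (length(missing))
      stop("read_trackmate_xml: track ", tid, " references unknown spot ",
           missing[1L], call. = FALSE)
    sub <- spot_tab[sids, , drop = FALSE]
    ord <- order(sub$frame)
    sub <- sub[ord, , drop = FALSE]
    if (anyDuplicated(sub$frame))
      stop("read_trackmate_xml: track ", tid,
           " has non-monotone/duplicated frames", call. = FALSE)
    tracks[[length(tracks) + 1L]] <- cell_track(
      track_id = tid, x = sub$x, y = sub$y, frame = sub$frame,
      frame_interval = frame_interval, condition = condition, source = path)
  }
  track_collection(tracks, metadata = list(frame_interval = frame_interval,
                                           source = path))
}

.required_csv_cols <- c("track_id", "frame", "t_min", "x_um", "y_um")

#' Read tracks from a tidy CSV
#'
#' Expects columns `track_id`, `frame`, `t_min`, `x_um`, `y_um` and
#' optionally `condition`, `edge_of_slice`, `near_glass`, `interpolated`.
#' Rows are grouped by `track_id` and sorted by `frame`.
#'
#' @param path Path to the CSV.
#' @param frame_interval Frame interval in minutes; by default inferred as the
#'   smallest positive within-track time difference.
#' @return A [track_collection].
#' @export
read_tracks_csv <- function(path, frame_interval = NULL) {
  if (!file.exists(path))
    stop("read_tracks_csv: file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "track_id"))
  miss <- setdiff(.required_csv_cols, names(dt))
  if (length(miss))
    stop("read_tracks_csv: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(dt)) {
    return(track_collection(metadata = list(source = path)))
  }
  if (anyDuplicated(paste(dt$track_id, dt$frame, sep = "\r")))
    stop("read_tracks_csv: duplicated (track_id, frame) rows", call. = FALSE)
  data.table::setorderv(dt, c("track_id", "frame"))
  df <- as.data.frame(dt)
  if (is.null(frame_interval)) {
    dts <- unlist(lapply(split(df$t_min, df$track_id), diff))
    dts <- dts[dts > 0]
    if (!length(dts))
      stop("read_tracks_csv: cannot infer frame interval", call. = FALSE)
    frame_interval <- min(dts)
  }
  tracks <- lapply(split(df, df$track_id), function(g) {
    flags <- character()
    if ("edge_of_slice" %in% names(g) && any(as.logical(g$edge_of_slice)))
      flags <- c(flags, "edge_of_slice")
    if ("near_glass" %in% names(g) && any(as.logical(g$near_glass)))
      flags <- c(flags, "near_glass")
    interp <- if ("interpolated" %in% names(g)) as.logical(g$interpolated)
              else NULL
    if (!is.null(interp) && any(interp)) flags <- c(flags, "interpolated_frames")
    cond <- if ("condition" %in% names(g)) as.character(g$condition[[1L]])
            else "default"
    cell_track(track_id = g$track_id[[1L]], x = g$x_um, y = g$y_um,
               frame = g$frame, frame_interval = frame_interval, t = g$t_min,
               condition = cond, flags = flags, interpolated = interp,
               source = path)
  })
  track_collection(unname(tracks),
                   metadata = list(frame_interval = frame_interval,
                                   source = path))
}

#' Write a track collection to tidy CSV
#'
#' Doubles are serialized with 17 significant digits so that
#' `read_tracks_csv(write_tracks_csv(x))` reproduces positions and times to
#' full precision.
#'
#' @param tracks A [track_collection].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_collection"))
  df <- as.data.frame(tracks)
  out <- data.table::as.data.table(df)
  for (col in c("t_min", "x_um", "y_um"))
    data.table::set(out, j = col, value = fmt_full(out[[col]]))
  ok <- tryCatch({ data.table::fwrite(out, path, quote = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("write_tracks_csv: cannot write ", path, " (",
         conditionMessage(ok), ")", call. = FALSE)
  invisible(path)
}

#' Track quality-control configuration
#'
#' Defaults follow the acquisition/tracking settings of 2-minute-interval
#' brain-slice movies: cells are not identifiable across more than 25 um per
#' minute, the tracker closes gaps of at most 2 frames, and tracks at the
#' slice edge or too close to the glass bottom are excluded.
#'
#' @param min_frames Minimum points per track (default 20; guarantees >= 7 MSD
#'   lags inside the 40% fitting window).
#' @param max_speed Maximum single-step speed, um/min (default 25).
#' @param max_gap_frames Largest gap (missing frames) filled by linear
#'   interpolation; larger gaps split the track (default 2).
#' @param exclude_flags Flags whose presence removes a track.
#' @return An object of class `track_filter_config`.
#' @export
track_filter_config <- function(min_frames = 20, max_speed = 25,
                                max_gap_frames = 2,
                                exclude_flags = c("edge_of_slice",
                                                  "near_glass")) {
  stopifnot(min_frames > 0, max_speed > 0, max_gap_frames >= 0)
  bad <- setdiff(exclude_flags, track_flag_vocabulary)
  if (length(bad))
    stop("track_filter_config: unknown flags: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(min_frames = as.integer(min_frames), max_speed = max_speed,
                 max_gap_frames = as.integer(max_gap_frames),
                 exclude_flags = exclude_flags),
            class = "track_filter_config")
}

# Interpolate gaps <= max_gap linearly (marking points), split at larger gaps.
# Returns a list of cell_track segments.
.regularize_track <- function(tr, max_gap) {
  gaps <- diff(tr$frame) - 1L
  cut_after <- which(gaps > max_gap)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, length(tr$frame))
  n_seg <- length(starts)
  segs <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    idx <- starts[s]:ends[s]
    if (length(idx) < 2L) next
    fr <- tr$frame[idx]
    full <- fr[1L]:fr[length(fr)]
    xi <- stats::approx(fr, tr$x[idx], xout = full)$y
    yi <- stats::approx(fr, tr$y[idx], xout = full)$y
    interp <- !(full %in% fr)
    orig_interp <- tr$interpolated[idx][match(full, fr)]
    interp_all <- interp | (!is.na(orig_interp) & orig_interp)
    flags <- tr$flags
    if (any(interp_all)) flags <- union(flags, "interpolated_frames")
    tid <- if (n_seg > 1L) paste0(tr$track_id, ".", s) else tr$track_id
    segs[[s]] <- cell_track(
      track_id = tid, x = xi, y = yi, frame = full,
      frame_interval = tr$frame_interval, condition = tr$condition,
      flags = flags, interpolated = interp_all, source = tr$source)
  }
  segs[!vapply(segs, is.null, logical(1))]
}

#' Apply quality-control filters to a track collection
#'
#' In order: (1) tracks carrying any `exclude_flags` are removed; (2) gaps of
#' at most `max_gap_frames` missing frames are filled by linear interpolation
#' (points flagged `interpolated_frames`), larger gaps split the track into
#' independently re-filtered segments; (3) tracks with fewer than `min_frames`
#' points are removed; (4) tracks containing any single-frame displacement
#' implying a speed above `max_speed` are removed. The returned collection is
#' uniformly sampled, and carries a per-rule removal report in
#' `metadata$filter_report` (also as attribute `"filter_report"`).
#'
#' Filtering is idempotent: re-applying the same configuration is a no-op.
#'
#' @param tracks A [track_collection].
#' @param config A [track_filter_config].
#' @return The filtered [track_collection].
#' @export
apply_track_filters <- function(tracks, config = track_filter_config()) {
  stopifnot(inherits(tracks, "track_collection"),
            inherits(config, "track_filter_config"))
  report <- list(n_in = length(tracks$tracks), excluded_flags = 0L,
                 split_gaps = 0L, min_frames = 0L, max_speed = 0L, n_out = 0L)

  kept <- list()
  for (tr in tracks$tracks) {
    if (length(intersect(tr$flags, config$exclude_flags))) {
      report$excluded_flags <- report$excluded_flags + 1L
      next
    }
    kept[[length(kept) + 1L]] <- tr
  }

  segs <- list()
  for (tr in kept) {
    pieces <- .regularize_track(tr, config$max_gap_frames)
    if (length(pieces) > 1L) report$split_gaps <- report$split_gaps + 1L
    segs <- c(segs, pieces)
  }

  out <- list()
  for (tr in segs) {
    if (length(tr$t) < config$min_frames) {
      report$min_frames <- report$min_frames + 1L
      next
    }
    speeds <- step_displacements(tr) / diff(tr$t)
    if (any(speeds > config$max_speed)) {
      report$max_speed <- report$max_speed + 1L
      next
    }
    out[[length(out) + 1L]] <- tr
  }
  report$n_out <- length(out)
  if (!report$n_out)
    message("apply_track_filters: no tracks survived filtering")

  md <- tracks$metadata
  md$filter_report <- report
  res <- track_collection(out, metadata = md)
  attr(res, "filter_report") <- report
  res
}
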