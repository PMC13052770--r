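# Per-track step and directionality statistics.

#' Frame-to-frame displacement magnitudes
#'
#' @param track A [cell_track] with at least 2 points.
#' @return Numeric vector of length `n - 1`, Euclidean step lengths in um.
#' @export
step_displacements <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  if (length(track$t) < 2L)
    stop("step_displacements: degenerate track (< 2 points)", call. = FALSE)
  sqrt(diff(track$x)^2 + diff(track$y)^2)
}

#' Summarize one track: step size, speed, and directionality
#'
#' Computes the one-lag statistics (median step size and median instantaneous
#' speed) and the two directionality statistics in TrackMate's sense:
#' * confinement ratio = net displacement / total path length (1 for a
#'   straight monotone path, 0 for a closed loop);
#' * linearity of forward progression = mean straight-line speed
#'   (net displacement / duration) divided by mean instantaneous speed.
#'
#' Under uniform sampling the two directionality statistics coincide
#' algebraically (duration cancels); both are reported because tracker
#' outputs conventionally carry both columns.
#'
#' A zero-path-length (stationary) track gets both statistics set to 0 and a
#' `degenerate` flag in the result.
#'
#' @param track A [cell_track] with at least 3 points and uniform sampling
#'   (run [apply_track_filters] first).
#' @return A one-row data.frame with columns `track_id`, `condition`,
#'   `median_step_size`, `median_speed`, `linearity_forward_progression`,
#'   `confinement_ratio`, `n_steps`, `degenerate`.
#' @export
summarize_track <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  if (length(track$t) < 3L)
    stop("summarize_track: need at least 3 points", call. = FALSE)
  if (!is_uniform_track(track))
    stop("summarize_track: track has gaps; apply_track_filters first",
         call. = FALSE)
  steps <- step_displacements(track)
  dt <- track$frame_interval
  path_len <- sum(steps)
  n <- length(track$t)
  net <- sqrt((track$x[n] - track$x[1L])^2 + (track$y[n] - track$y[1L])^2)
  duration <- track$t[n] - track$t[1L]
  if (path_len == 0) {
    conf <- 0; lin <- 0; degen <- TRUE
  } else {
    conf <- net / path_len
    lin <- (net / duration) / mean(steps / dt)
    degen <- FALSE
  }
  data.frame(track_id = track$track_id, condition = track$condition,
             median_step_size = median(steps),
             median_speed = median(steps) / dt,
             linearity_forward_progression = lin,
             confinement_ratio = conf, n_steps = length(steps),
             degenerate = degen, stringsAsFactors = FALSE)
}

#' Summarize every track in a collection
#'
#' @param tracks A [track_collection].
#' @return A data.frame, one row per track (see [summarize_track]).
#' @export
summarize_tracks <- function(tracks) {
  stopifnot(inherits(tracks, "track_collection"))
  if (!length(tracks$tracks))
    return(data.frame(track_id = character(), condition = character(),
                      median_step_size = numeric(), median_speed = numeric(),
                      linearity_forward_progression = numeric(),
                      confinement_ratio = numeric(), n_steps = integer(),
                      degenerate = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(tracks$tracks, summarize_track))
  rownames(out) <- NULL
  out
}
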