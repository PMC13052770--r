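# Immune-synapse quantification: calcium normalization and AUC, synapse-area
# intersection, response-speed regression, MTOC docking time, and
# center-of-mass distance to the synapse interface.

#' Construct a fluorescence intensity trace
#'
#' @param cell_id Cell identifier.
#' @param times Strictly increasing sample times, minutes.
#' @param values Non-negative finite fluorescence values (arbitrary units).
#' @param channel Channel label (e.g. `"calcium"`, `"car"`, `"f_actin"`,
#'   `"mtoc"`).
#' @param t_zero Declared interaction/activation onset time, minutes.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(cell_id, times, values, channel = "calcium",
                            t_zero = times[1L]) {
  stopifnot(length(times) == length(values), length(times) >= 2L)
  if (any(diff(times) <= 0))
    stop("intensity_trace: times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(values)) || any(values < 0))
    stop("intensity_trace: values must be finite and non-negative",
         call. = FALSE)
  structure(list(cell_id = as.character(cell_id), channel = channel,
                 times = as.numeric(times), values = as.numeric(values),
                 t_zero = t_zero, flags = character()),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %s [%s]: %d samples over [%g, %g] min, t_zero = %g\n",
              x$cell_id, x$channel, length(x$times), x$times[1L],
              x$times[length(x$times)], x$t_zero))
  invisible(x)
}

#' Normalize a calcium trace by its pre-peak baseline (F/F0)
#'
#' Finds the first local maximum at or after `t_zero` whose topographic
#' prominence is at least `peak_prominence` times the trace range, backtracks
#' from that peak to the last non-increasing frame (the rise onset), and
#' takes F0 as the mean of all samples strictly before the onset. Values are
#' divided by F0, making responses gain-invariant.
#'
#' When no qualifying peak exists, the trace is normalized by the mean of the
#' pre-`t_zero` samples (or the whole trace if none) and flagged `no_peak`.
#'
#' @param trace An [intensity_trace] with at least 5 samples and at least one
#'   sample after `t_zero`.
#' @param peak_prominence Minimum peak prominence as a fraction of the trace
#'   range (default 0.2).
#' @return The normalized [intensity_trace]; fields `f0`, `peak_index`,
#'   `onset_index`, `normalized_peak` are added, and `flags` may gain
#'   `"no_peak"`.
#' @export
normalize_calcium <- function(trace, peak_prominence = 0.2) {
  stopifnot(inherits(trace, "intensity_trace"))
  v <- trace$values
  n <- length(v)
  if (n < 5L)
    stop("normalize_calcium: need at least 5 samples", call. = FALSE)
  if (!any(trace$times >= trace$t_zero))
    stop("normalize_calcium: no samples at/after t_zero", call. = FALSE)
  rng <- diff(range(v))
  cand <- local_maxima(v)
  cand <- cand[trace$times[cand] >= trace$t_zero]
  peak <- NA_integer_
  if (rng > 0) {
    for (i in cand) {
      if (peak_prominence_at(v, i) >= peak_prominence * rng) {
        peak <- i
        break
      }
    }
  }
  if (is.na(peak)) {
    pre <- v[trace$times < trace$t_zero]
    f0 <- if (length(pre)) mean(pre) else mean(v)
    trace$flags <- union(trace$flags, "no_peak")
    onset <- NA_integer_
  } else {
    j <- peak
    while (j > 1L && v[j - 1L] < v[j]) j <- j - 1L
    onset <- j
    f0 <- if (onset > 1L) mean(v[seq_len(onset - 1L)]) else v[1L]
  }
  if (!is.finite(f0) || f0 == 0)
    stop("normalize_calcium: baseline F0 is zero", call. = FALSE)
  trace$values <- v / f0
  trace$f0 <- f0
  trace$peak_index <- peak
  trace$onset_index <- onset
  trace$normalized_peak <- max(trace$values)
  trace$normalized <- TRUE
  trace
}

#' Area under a normalized calcium trace over the interaction window
#'
#' Trapezoidal integral of the normalized trace over
#' `[t_zero, t_zero + t_max]`. Window endpoints falling between samples are
#' linearly interpolated, so the integral is exact for piecewise-linear
#' traces and invariant to re-sampling them. A trace ending before the window
#' does is integrated to its last sample and flagged `truncated`.
#'
#' @param trace A normalized [intensity_trace] (see [normalize_calcium]).
#' @param t_max Window length in minutes (default 30).
#' @return The AUC in normalized-units x minutes, with attribute
#'   `"truncated"`.
#' @export
calcium_auc <- function(trace, t_max = 30) {
  stopifnot(inherits(trace, "intensity_trace"), t_max > 0)
  t0 <- trace$t_zero
  t1 <- t0 + t_max
  tt <- trace$times
  vv <- trace$values
  if (tt[length(tt)] <= t0 || tt[1L] >= t1)
    stop("calcium_auc: no samples inside the integration window",
         call. = FALSE)
  truncated <- tt[length(tt)] < t1
  lo <- max(t0, tt[1L])
  hi <- min(t1, tt[length(tt)])
  inside <- tt > lo & tt < hi
  gt <- c(lo, tt[inside], hi)
  gv <- stats::approx(tt, vv, xout = gt)$y
  auc <- sum(diff(gt) * (head(gv, -1L) + tail(gv, -1L)) / 2)
  if (length(gt) < 2L)
    stop("calcium_auc: no samples inside the integration window",
         call. = FALSE)
  structure(auc, truncated = truncated)
}

#' Construct a binary mask movie
#'
#' @param frames List of same-shape logical (or 0/1) matrices, one per frame.
#' @param pixel_size Pixel edge length, micrometers.
#' @param times Frame times, minutes.
#' @param cell_id Identifier.
#' @return An object of class `mask_movie`.
#' @export
mask_movie <- function(frames, pixel_size = 1, times = NULL,
                       cell_id = "cell") {
  stopifnot(is.list(frames), length(frames) >= 1L, pixel_size > 0)
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("mask_movie: all frames must share one shape", call. = FALSE)
  frames <- lapply(frames, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  if (is.null(times)) times <- seq_along(frames) - 1
  stopifnot(length(times) == length(frames))
  structure(list(cell_id = cell_id, frames = frames,
                 pixel_size = pixel_size, times = as.numeric(times)),
            class = "mask_movie")
}

#' @export
print.mask_movie <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<mask_movie> %s: %d frames of %dx%d px (%g um/px)\n",
              x$cell_id, length(x$frames), d[1L], d[2L], x$pixel_size))
  invisible(x)
}

#' Intersection area of two binary masks
#'
#' @param mask_a,mask_b Same-shape logical matrices.
#' @param pixel_size Pixel edge length, micrometers.
#' @return Area of the pixelwise intersection, um^2. Symmetric in its
#'   arguments and bounded by the smaller mask's area.
#' @export
mask_intersection_area <- function(mask_a, mask_b, pixel_size = 1) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask_intersection_area: mask shapes differ", call. = FALSE)
  stopifnot(pixel_size > 0)
  sum(as.logical(mask_a) & as.logical(mask_b)) * pixel_size^2
}

#' Per-frame synapse area as the T-cell/tumor mask intersection
#'
#' The synapse at each frame is the intersection of the independently
#' segmented T-cell and tumor-cell masks; its area is returned per frame.
#'
#' @param movie_t_cell,movie_tumor Frame-aligned [mask_movie]s with equal
#'   pixel size. Frame times must agree within half a frame interval.
#' @return Numeric vector of per-frame intersection areas, um^2.
#' @export
synapse_area_series <- function(movie_t_cell, movie_tumor) {
  stopifnot(inherits(movie_t_cell, "mask_movie"),
            inherits(movie_tumor, "mask_movie"))
  if (movie_t_cell$pixel_size != movie_tumor$pixel_size)
    stop("synapse_area_series: pixel sizes differ", call. = FALSE)
  if (length(movie_t_cell$frames) != length(movie_tumor$frames))
    stop("synapse_area_series: frame counts differ", call. = FALSE)
  ta <- movie_t_cell$times
  tb <- movie_tumor$times
  half <- if (length(ta) > 1L) median(diff(ta)) / 2 else Inf
  if (any(abs(ta - tb) > half))
    stop("synapse_area_series: movies misaligned in time by more than half a frame",
         call. = FALSE)
  vapply(seq_along(ta), function(i)
    mask_intersection_area(movie_t_cell$frames[[i]], movie_tumor$frames[[i]],
                           movie_t_cell$pixel_size),
    numeric(1))
}

#' Single-channel synaptic area over time (TIRFM variant)
#'
#' Per-frame pixel count of one mask movie times the pixel area - the
#' spreading-area readout used when only the segmented actin footprint is
#' available.
#'
#' @param movie A [mask_movie].
#' @return Numeric vector of per-frame areas, um^2.
#' @export
mask_area_series <- function(movie) {
  stopifnot(inherits(movie, "mask_movie"))
  vapply(movie$frames, function(f) sum(f) * movie$pixel_size^2, numeric(1))
}

#' Response speed: regression slope over the first minute of activation
#'
#' Ordinary least-squares slope of the signal against time over
#' `[t_zero, t_zero + window]`, reported per minute.
#'
#' @param trace An [intensity_trace], or a data.frame with columns `t_min`
#'   and `value` plus a `t_zero` argument.
#' @param window Window length in seconds (default 60).
#' @param t_zero Activation onset (minutes) when `trace` is a data.frame.
#' @return Slope in signal units per minute.
#' @export
response_speed <- function(trace, window = 60, t_zero = NULL) {
  if (inherits(trace, "intensity_trace")) {
    tt <- trace$times; vv <- trace$values
    t0 <- t_zero %||% trace$t_zero
  } else {
    stopifnot(is.data.frame(trace), all(c("t_min", "value") %in% names(trace)))
    tt <- trace$t_min; vv <- trace$value
    t0 <- t_zero %||% tt[1L]
  }
  stopifnot(window > 0)
  keep <- tt >= t0 & tt <= t0 + window / 60
  if (sum(keep) < 3L)
    stop("response_speed: need at least 3 samples in the window",
         call. = FALSE)
  x <- tt[keep]; y <- vv[keep]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' MTOC docking time from the first derivative peak
#'
#' Smooths the recruitment trace with a centered moving average, takes the
#' central-difference first derivative, and reports the time of the first
#' local maximum of the derivative whose prominence is at least 10% of the
#' derivative range - the moment the MTOC arrives at the synapse.
#'
#' @param trace An [intensity_trace] (MTOC channel).
#' @param smooth_window Moving-average window in frames (default 3).
#' @return Docking time in minutes, or `NA` with attribute `no_docking =
#'   TRUE` when the derivative has no qualifying peak (e.g. a linear trace).
#' @export
docking_time <- function(trace, smooth_window = 3) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$times)
  if (n < smooth_window + 3L)
    stop("docking_time: trace too short for smoothing window", call. = FALSE)
  s <- moving_average(trace$values, smooth_window)
  tt <- trace$times
  # restrict to fully-smoothed samples: shrunken edge windows would otherwise
  # fabricate derivative structure (e.g. on a perfectly linear trace)
  half <- max(as.integer(smooth_window) %/% 2L, 0L)
  idx <- (2L + half):(n - 1L - half)
  deriv <- (s[idx + 1L] - s[idx - 1L]) / (tt[idx + 1L] - tt[idx - 1L])
  rng <- diff(range(deriv))
  if (rng <= 1e-9 * max(abs(deriv), 1e-300))
    return(structure(NA_real_, no_docking = TRUE))  # flat derivative
  peaks <- local_maxima(deriv)
  for (i in peaks) {
    if (peak_prominence_at(deriv, i) >= 0.1 * rng)
      return(tt[idx[i]])
  }
  # monotone rise: the derivative may peak at its ends without an interior max
  structure(NA_real_, no_docking = TRUE)
}

#' Distance from an intensity-weighted center of mass to the synapse interface
#'
#' Computes the intensity-weighted centroid of a 2D (or 3D) label image in
#' physical units and its Euclidean distance to the immune-synapse interface,
#' given as a line `a x + b y + c = 0` (2D) or plane
#' `a x + b y + c z + d = 0` (3D). Pixel `(i, j[, k])` sits at coordinates
#' `((i-1) ps, (j-1) ps[, (k-1) ps])` with `i` indexing x and `j` indexing y.
#' Smaller distances indicate stronger accumulation at the synapse.
#'
#' @param label_image Non-negative numeric matrix (2D) or 3D array with
#'   positive total intensity.
#' @param interface Numeric vector: length 3 (2D line) or 4 (3D plane)
#'   coefficients in micrometer units.
#' @param pixel_size Pixel edge length, micrometers.
#' @return Distance in micrometers.
#' @export
com_distance <- function(label_image, interface, pixel_size = 1) {
  stopifnot(is.numeric(label_image), pixel_size > 0)
  total <- sum(label_image)
  if (!is.finite(total) || total <= 0)
    stop("com_distance: image has zero total intensity", call. = FALSE)
  nd <- length(dim(label_image))
  if (nd == 2L) {
    if (length(interface) != 3L)
      stop("com_distance: 2D image needs a length-3 line (a, b, c)",
           call. = FALSE)
    ij <- which(label_image > 0, arr.ind = TRUE)
    wts <- label_image[ij]
    cx <- sum(wts * (ij[, 1L] - 1)) / total * pixel_size
    cy <- sum(wts * (ij[, 2L] - 1)) / total * pixel_size
    abs(interface[1L] * cx + interface[2L] * cy + interface[3L]) /
      sqrt(sum(interface[1:2]^2))
  } else if (nd == 3L) {
    if (length(interface) != 4L)
      stop("com_distance: 3D image needs a length-4 plane (a, b, c, d)",
           call. = FALSE)
    ijk <- which(label_image > 0, arr.ind = TRUE)
    wts <- label_image[ijk]
    com <- colSums(wts * (ijk - 1)) / total * pixel_size
    abs(sum(interface[1:3] * com) + interface[4L]) /
      sqrt(sum(interface[1:3]^2))
  } else {
    stop("com_distance: label_image must be 2D or 3D", call. = FALSE)
  }
}

#' Read intensity traces from a long CSV
#'
#' Expects columns `cell_id`, `channel`, `t_min`, `value` and optionally
#' `t_zero` (constant per cell/channel).
#'
#' @param path CSV path.
#' @return A list of [intensity_trace] objects.
#' @export
read_traces_csv <- function(path) {
  if (!file.exists(path))
    stop("read_traces_csv: file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  need <- c("cell_id", "channel", "t_min", "value")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("read_traces_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(dt)
  groups <- split(df, interaction(df$cell_id, df$channel, drop = TRUE))
  lapply(groups, function(g) {
    g <- g[order(g$t_min), ]
    tz <- if ("t_zero" %in% names(g)) g$t_zero[[1L]] else g$t_min[[1L]]
    intensity_trace(g$cell_id[[1L]], g$t_min, g$value,
                    channel = g$channel[[1L]], t_zero = tz)
  })
}

#' Write a mask movie as run-length-encoded CSV
#'
#' Plain-text mask exchange format: one row per horizontal run of TRUE
#' pixels, columns `frame`, `row`, `col_start`, `col_end`, plus a commented
#' header carrying shape, pixel size, and times.
#'
#' @param movie A [mask_movie].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_rle_csv <- function(movie, path) {
  stopifnot(inherits(movie, "mask_movie"))
  d <- dim(movie$frames[[1L]])
  hdr <- sprintf("# mask_rle nrow=%d ncol=%d pixel_size=%s times=%s",
                 d[1L], d[2L], fmt_full(movie$pixel_size),
                 paste(fmt_full(movie$times), collapse = ";"))
  rows <- list(data.frame(frame = integer(), row = integer(),
                          col_start = integer(), col_end = integer()))
  for (f in seq_along(movie$frames)) {
    m <- movie$frames[[f]]
    for (r in seq_len(d[1L])) {
      rl <- rle(as.logical(m[r, ]))
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      on <- which(rl$values)
      if (length(on))
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, row = r, col_start = starts[on], col_end = ends[on])
    }
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read a run-length-encoded mask movie CSV
#'
#' @param path Path written by [write_mask_rle_csv].
#' @param cell_id Identifier for the reconstructed movie.
#' @return A [mask_movie].
#' @export
read_mask_rle_csv <- function(path, cell_id = "cell") {
  if (!file.exists(path))
    stop("read_mask_rle_csv: file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "# mask_rle nrow=(\\d+) ncol=(\\d+) pixel_size=(\\S+) times=(\\S+)", hdr))[[1L]]
  if (length(m) != 5L)
    stop("read_mask_rle_csv: malformed header", call. = FALSE)
  nr <- as.integer(m[2L]); nc <- as.integer(m[3L])
  ps <- as.numeric(m[4L])
  times <- as.numeric(strsplit(m[5L], ";")[[1L]])
  tab <- utils::read.csv(path, skip = 1L)
  frames <- lapply(seq_along(times), function(f) {
    mk <- matrix(FALSE, nr, nc)
    sub <- tab[tab$frame == f, , drop = FALSE]
    for (r in seq_len(nrow(sub)))
      mk[sub$row[r], sub$col_start[r]:sub$col_end[r]] <- TRUE
    mk
  })
  mask_movie(frames, pixel_size = ps, times = times, cell_id = cell_id)
}
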