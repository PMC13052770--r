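# Seed-deterministic synthetic data: random-walk tracks with imaging
# artifacts, calcium transients, and mask movies with analytic ground truth.
#
# Defaults mirror the acquisition this pipeline targets: 2D positions sampled
# every 2 minutes over ~100 frames (movies run 90-270 frames).

.check_sim <- function(n_tracks, n_frames, frame_interval) {
  stopifnot(n_tracks >= 1, n_frames >= 2, frame_interval > 0)
}

.finish_walk <- function(xs, ys, frame_interval, condition, prefix,
                         localization_sigma, gap_rate, seed) {
  n_tracks <- ncol(xs)
  tracks <- lapply(seq_len(n_tracks), function(i)
    cell_track(track_id = sprintf("%s_%03d", prefix, i),
               x = xs[, i], y = ys[, i], frame_interval = frame_interval,
               condition = condition, source = "simulated"))
  coll <- track_collection(tracks,
                           metadata = list(frame_interval = frame_interval,
                                           source = "simulated"))
  if (localization_sigma > 0 || gap_rate > 0)
    coll <- add_imaging_artifacts(coll, localization_sigma, gap_rate,
                                  seed = if (is.null(seed)) NULL else seed + 1L)
  coll
}

#' Simulate Brownian tracks
#'
#' Independent Gaussian increments per coordinate with variance `2 D dt`,
#' so the ensemble MSD is `4 D tau` (2D).
#'
#' @param n_tracks Number of tracks.
#' @param n_frames Frames per track (default 100).
#' @param D Random motility coefficient, um^2/min.
#' @param frame_interval Frame interval, minutes (default 2).
#' @param localization_sigma Per-coordinate localization noise sd, um
#'   (default 0).
#' @param gap_rate Per-frame probability of opening a 1-2 frame gap
#'   (default 0; at most 0.2).
#' @param seed RNG seed (the generator is seed-deterministic).
#' @param condition Condition label.
#' @return A [track_collection].
#' @export
simulate_brownian <- function(n_tracks = 100, n_frames = 100, D = 1,
                              frame_interval = 2, localization_sigma = 0,
                              gap_rate = 0, seed = NULL,
                              condition = "brownian") {
  .check_sim(n_tracks, n_frames, frame_interval)
  stopifnot(D >= 0)
  with_seed(seed, {
    sd_step <- sqrt(2 * D * frame_interval)
    xs <- apply(matrix(rnorm((n_frames - 1L) * n_tracks, sd = sd_step),
                       n_frames - 1L, n_tracks), 2L, cumsum)
    ys <- apply(matrix(rnorm((n_frames - 1L) * n_tracks, sd = sd_step),
                       n_frames - 1L, n_tracks), 2L, cumsum)
    xs <- rbind(0, matrix(xs, n_frames - 1L, n_tracks))
    ys <- rbind(0, matrix(ys, n_frames - 1L, n_tracks))
    .finish_walk(xs, ys, frame_interval, condition, "brw",
                 localization_sigma, gap_rate, seed)
  })
}

#' Simulate persistent random walk (PRW) tracks
#'
#' The velocity of each coordinate follows a stationary Ornstein-Uhlenbeck
#' process with correlation time `P` and stationary mean-square speed `v^2`
#' (per-coordinate variance `v^2/2`); positions integrate the velocity. The
#' discrete-time update is the exact joint Gaussian law of
#' (velocity, displacement) over one frame - no Euler error - so the ensemble
#' MSD is exactly `2 v^2 P^2 (tau/P - (1 - e^{-tau/P}))`.
#'
#' @inheritParams simulate_brownian
#' @param v Root-mean-square (persistence) speed, um/min.
#' @param P Persistence time, minutes. A warning is issued when
#'   `frame_interval >= 5 P` (persistence unresolvable).
#' @return A [track_collection].
#' @export
simulate_prw <- function(n_tracks = 100, n_frames = 100, v = 5, P = 10,
                         frame_interval = 2, localization_sigma = 0,
                         gap_rate = 0, seed = NULL, condition = "prw") {
  .check_sim(n_tracks, n_frames, frame_interval)
  stopifnot(v > 0, P > 0)
  if (frame_interval >= 5 * P)
    warning("simulate_prw: frame_interval >= 5 P; persistence is not resolvable at this sampling")
  with_seed(seed, {
    sigma2 <- v^2 / 2          # stationary per-coordinate velocity variance
    h <- frame_interval / P
    mu <- exp(-h)
    s_vv <- sigma2 * (1 - mu^2)
    s_xx <- sigma2 * P^2 * (2 * h - 3 + 4 * mu - mu^2)
    s_xv <- sigma2 * P * (1 - mu)^2
    a <- sqrt(s_vv)
    b1 <- s_xv / a
    b2 <- sqrt(max(s_xx - b1^2, 0))
    step_one <- function() {
      vel <- matrix(rnorm(2L * n_tracks, sd = sqrt(sigma2)), n_tracks, 2L)
      pos <- matrix(0, n_tracks, 2L)
      xs <- matrix(0, n_frames, n_tracks)
      ys <- matrix(0, n_frames, n_tracks)
      for (f in 2:n_frames) {
        z1 <- matrix(rnorm(2L * n_tracks), n_tracks, 2L)
        z2 <- matrix(rnorm(2L * n_tracks), n_tracks, 2L)
        dx <- P * (1 - mu) * vel + b1 * z1 + b2 * z2
        vel <- mu * vel + a * z1
        pos <- pos + dx
        xs[f, ] <- pos[, 1L]
        ys[f, ] <- pos[, 2L]
      }
      list(xs = xs, ys = ys)
    }
    w <- step_one()
    .finish_walk(w$xs, w$ys, frame_interval, condition, "prw",
                 localization_sigma, gap_rate, seed)
  })
}

#' Simulate confined (constrained) tracks in a reflecting disc
#'
#' Brownian steps inside a reflecting disc of radius `disc_radius` centered
#' at each track's origin; positions never leave the disc and start from the
#' uniform (stationary) distribution, so the long-lag ensemble MSD plateaus
#' at `disc_radius^2` (the mean squared distance between two independent
#' uniform points in a disc of radius b is b^2).
#'
#' @inheritParams simulate_brownian
#' @param D Short-time motility coefficient, um^2/min.
#' @param disc_radius Confinement radius, um.
#' @return A [track_collection].
#' @export
simulate_confined <- function(n_tracks = 100, n_frames = 100, D = 1,
                              disc_radius = 15, frame_interval = 2,
                              localization_sigma = 0, gap_rate = 0,
                              seed = NULL, condition = "confined") {
  .check_sim(n_tracks, n_frames, frame_interval)
  stopifnot(D > 0, disc_radius > 0)
  with_seed(seed, {
    b <- disc_radius
    sd_step <- sqrt(2 * D * frame_interval)
    r0 <- b * sqrt(runif(n_tracks))
    th0 <- runif(n_tracks, 0, 2 * pi)
    px <- r0 * cos(th0)
    py <- r0 * sin(th0)
    xs <- matrix(0, n_frames, n_tracks)
    ys <- matrix(0, n_frames, n_tracks)
    xs[1L, ] <- px
    ys[1L, ] <- py
    for (f in 2:n_frames) {
      px <- px + rnorm(n_tracks, sd = sd_step)
      py <- py + rnorm(n_tracks, sd = sd_step)
      r <- sqrt(px^2 + py^2)
      it <- 0L
      while (any(out <- r > b) && it < 100L) {
        # radial mirror reflection at the boundary: r -> 2b - r
        scl <- (2 * b - r[out]) / r[out]
        px[out] <- px[out] * scl
        py[out] <- py[out] * scl
        r <- sqrt(px^2 + py^2)
        it <- it + 1L
      }
      if (any(out)) {  # pathological step size >> disc: clamp
        scl <- b / r[out]
        px[out] <- px[out] * scl
        py[out] <- py[out] * scl
      }
      xs[f, ] <- px
      ys[f, ] <- py
    }
    .finish_walk(xs, ys, frame_interval, condition, "cnf",
                 localization_sigma, gap_rate, seed)
  })
}

#' Inject imaging artifacts into simulated tracks
#'
#' Adds i.i.d. Gaussian localization noise (sd `localization_sigma` per
#' coordinate; a static error that offsets the MSD by `4 sigma^2` in 2D) and
#' removes interior frames in runs of 1-2 at per-frame rate `gap_rate`
#' (emulating tracker gap closing; gaps never exceed 2 frames and are always
#' separated by at least one observed frame). Affected tracks are flagged
#' `localization_noise` / `gapped`.
#'
#' @param tracks A [track_collection].
#' @param localization_sigma Noise sd per coordinate, um.
#' @param gap_rate Per-frame gap probability, in `[0, 0.2]`.
#' @param seed RNG seed.
#' @return The perturbed [track_collection].
#' @export
add_imaging_artifacts <- function(tracks, localization_sigma = 0,
                                  gap_rate = 0, seed = NULL) {
  stopifnot(inherits(tracks, "track_collection"),
            localization_sigma >= 0, gap_rate >= 0, gap_rate <= 0.2)
  if (localization_sigma == 0 && gap_rate == 0) return(tracks)
  with_seed(seed, {
    new_tracks <- lapply(tracks$tracks, function(tr) {
      n <- length(tr$t)
      x <- tr$x; y <- tr$y
      flags <- tr$flags
      if (localization_sigma > 0) {
        x <- x + rnorm(n, sd = localization_sigma)
        y <- y + rnorm(n, sd = localization_sigma)
        flags <- union(flags, "localization_noise")
      }
      keep <- rep(TRUE, n)
      if (gap_rate > 0 && n > 3L) {
        i <- 2L
        gapped <- FALSE
        while (i <= n - 1L) {
          if (runif(1L) < gap_rate) {
            len <- sample(1:2, 1L)
            drop <- i:min(i + len - 1L, n - 1L)
            keep[drop] <- FALSE
            gapped <- TRUE
            i <- max(drop) + 2L  # guarantee a kept frame between gaps
          } else i <- i + 1L
        }
        if (gapped) flags <- union(flags, "gapped")
      }
      cell_track(track_id = tr$track_id, x = x[keep], y = y[keep],
                 frame = tr$frame[keep], frame_interval = tr$frame_interval,
                 t = tr$t[keep], condition = tr$condition, flags = flags,
                 interpolated = tr$interpolated[keep], source = tr$source)
    })
    track_collection(unname(new_tracks), metadata = tracks$metadata)
  })
}

#' Simulate a calcium transient with known ground truth
#'
#' Baseline fluorescence until `peak_time`, then an instantaneous rise of
#' `peak_amplitude` decaying exponentially with time constant `decay_time`,
#' plus optional Gaussian noise. The analytic F0, normalized peak, and
#' normalized AUC over `[t_zero, t_zero + 30]` minutes are stored in
#' attribute `"ground_truth"`.
#'
#' @param baseline Baseline fluorescence (positive).
#' @param peak_amplitude Rise above baseline at the peak.
#' @param peak_time Peak onset time, minutes.
#' @param decay_time Exponential decay constant, minutes.
#' @param noise_sigma Gaussian noise sd.
#' @param duration Trace duration, minutes (default 40).
#' @param dt Sampling interval, minutes (default 0.5).
#' @param t_zero Declared interaction onset (default 0).
#' @param seed RNG seed.
#' @param cell_id Identifier.
#' @return An [intensity_trace] with attribute `"ground_truth"` (list with
#'   `f0`, `normalized_peak`, `auc_30min`).
#' @export
simulate_calcium_trace <- function(baseline = 100, peak_amplitude = 300,
                                   peak_time = 5, decay_time = 8,
                                   noise_sigma = 0, duration = 40, dt = 0.5,
                                   t_zero = 0, seed = NULL,
                                   cell_id = "sim_cell") {
  stopifnot(baseline > 0, peak_amplitude >= 0, peak_time > t_zero,
            decay_time > 0, duration > peak_time, dt > 0)
  with_seed(seed, {
    times <- seq(t_zero, t_zero + duration, by = dt)
    values <- ifelse(times < peak_time, baseline,
                     baseline + peak_amplitude *
                       exp(-(times - peak_time) / decay_time))
    if (noise_sigma > 0)
      values <- pmax(values + rnorm(length(values), sd = noise_sigma), 0)
    tr <- intensity_trace(cell_id, times, values, channel = "calcium",
                          t_zero = t_zero)
    t_hi <- min(30, duration)
    auc <- t_hi + (peak_amplitude / baseline) * decay_time *
      (-expm1(-(t_hi - (peak_time - t_zero)) / decay_time))
    attr(tr, "ground_truth") <- list(
      f0 = baseline,
      normalized_peak = 1 + peak_amplitude / baseline,
      auc_30min = auc)
    tr
  })
}

# area of the lens where two discs (radii ra, rb, center distance d) overlap
circle_overlap_area <- function(d, ra, rb) {
  if (d >= ra + rb) return(0)
  if (d <= abs(ra - rb)) return(pi * min(ra, rb)^2)
  t1 <- ra^2 * acos((d^2 + ra^2 - rb^2) / (2 * d * ra))
  t2 <- rb^2 * acos((d^2 + rb^2 - ra^2) / (2 * d * rb))
  t3 <- 0.5 * sqrt((-d + ra + rb) * (d + ra - rb) * (d - ra + rb) *
                   (d + ra + rb))
  t1 + t2 - t3
}

#' Simulate a pair of disc mask movies with analytic overlap ground truth
#'
#' Two discs move at constant velocity across a shared field of view; each
#' frame is rasterized to a binary mask (a pixel is TRUE when its center lies
#' inside the disc). The analytic circle-circle lens overlap area per frame
#' is stored in attribute `"ground_truth"` of the returned list.
#'
#' @param n_frames Number of frames.
#' @param shape Field of view in pixels, `c(nrow, ncol)`.
#' @param pixel_size Pixel edge, micrometers.
#' @param center_a,center_b Initial disc centers, um, `c(x, y)`.
#' @param velocity_a,velocity_b Velocities, um/frame.
#' @param radius_a,radius_b Disc radii, um.
#' @param frame_interval Frame interval, minutes.
#' @return List with elements `t_cell` and `tumor` ([mask_movie]s) and
#'   attribute `"ground_truth"` (per-frame analytic overlap areas, um^2).
#' @export
simulate_mask_movie <- function(n_frames = 20, shape = c(128, 128),
                                pixel_size = 1,
                                center_a = c(30, 64), velocity_a = c(2, 0),
                                center_b = c(98, 64), velocity_b = c(-2, 0),
                                radius_a = 20, radius_b = 20,
                                frame_interval = 1) {
  stopifnot(n_frames >= 1, all(shape >= 2), pixel_size > 0,
            radius_a > 0, radius_b > 0)
  fov_x <- shape[2L] * pixel_size
  fov_y <- shape[1L] * pixel_size
  # pixel centers: x along columns, y along rows
  cx <- (seq_len(shape[2L]) - 0.5) * pixel_size
  cy <- (seq_len(shape[1L]) - 0.5) * pixel_size
  xg <- matrix(cx, shape[1L], shape[2L], byrow = TRUE)
  yg <- matrix(cy, shape[1L], shape[2L])
  raster_disc <- function(center, radius)
    (xg - center[1L])^2 + (yg - center[2L])^2 <= radius^2
  frames_a <- vector("list", n_frames)
  frames_b <- vector("list", n_frames)
  truth <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    ca <- center_a + (f - 1L) * velocity_a
    cb <- center_b + (f - 1L) * velocity_b
    for (cc in list(c(ca, radius_a), c(cb, radius_b))) {
      if (cc[1L] - cc[3L] < 0 || cc[1L] + cc[3L] > fov_x ||
          cc[2L] - cc[3L] < 0 || cc[2L] + cc[3L] > fov_y)
        stop("simulate_mask_movie: disc leaves the field of view at frame ",
             f, call. = FALSE)
    }
    frames_a[[f]] <- raster_disc(ca, radius_a)
    frames_b[[f]] <- raster_disc(cb, radius_b)
    truth[f] <- circle_overlap_area(sqrt(sum((ca - cb)^2)), radius_a,
                                    radius_b)
  }
  times <- (seq_len(n_frames) - 1L) * frame_interval
  out <- list(
    t_cell = mask_movie(frames_a, pixel_size, times, cell_id = "t_cell"),
    tumor = mask_movie(frames_b, pixel_size, times, cell_id = "tumor"))
  attr(out, "ground_truth") <- truth
  out
}
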