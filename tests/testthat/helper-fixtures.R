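# Shared fixtures and independent oracles, built in code at test time.

# Brute-force double-loop MSD oracle (independent of compute_msd): every
# (i, i+k) pair is enumerated explicitly; the per-lag pair values are then
# averaged with the same mean() operator so the comparison is bit-exact.
brute_msd <- function(x, y, dt) {
  n <- length(x)
  K <- n - 1L
  msd <- numeric(K)
  np <- integer(K)
  for (k in seq_len(K)) {
    pair_sq <- numeric(n - k)
    for (i in seq_len(n - k))
      pair_sq[i] <- (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    msd[k] <- mean(pair_sq)
    np[k] <- length(pair_sq)
  }
  list(lags = seq_len(K) * dt, msd = msd, n_pairs = np)
}

# Random-walk test track (plain cumsum, independent of the simulators).
random_track <- function(n, seed, dt = 1, id = "rt") {
  set.seed(seed)
  cell_track(id, x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
             frame_interval = dt)
}

# Exact model curve wrapped as an msd_curve (for fitter tests).
exact_curve <- function(model, params, K = 19, dt = 2, id = "exact") {
  lags <- seq_len(K) * dt
  structure(list(track_id = id, condition = "test", lags = lags,
                 msd = eval_msd_model(model, params, lags),
                 n_pairs = rep(50L, K), frame_interval = dt,
                 fitted_window = NA_integer_),
            class = "msd_curve")
}

# Hand-written TrackMate XML fixture: two tracks of 3 and 5 spots.
trackmate_fixture_xml <- function(drop_position_y_of = NULL) {
  spot <- function(id, frame, x, y) {
    ya <- if (!is.null(drop_position_y_of) && id == drop_position_y_of) ""
          else sprintf(' POSITION_Y="%g"', y)
    sprintf('        <Spot ID="%s" name="%s" POSITION_X="%g"%s FRAME="%d" POSITION_T="%g"/>',
            id, id, x, ya, frame, frame * 2)
  }
  spots_t1 <- mapply(spot, c("s1", "s2", "s3"), 0:2, c(0, 1, 2), c(0, 0, 1))
  spots_t2 <- mapply(spot, c("s4", "s5", "s6", "s7", "s8"), 0:4,
                     c(10, 11, 13, 14, 15), c(5, 5, 6, 8, 9))
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<TrackMate version="7.11.1">\n',
    '  <Model spatialunits="micron" timeunits="min">\n',
    '    <AllSpots nspots="8">\n',
    '      <SpotsInFrame frame="0">\n',
    paste(c(spots_t1[1], spots_t2[1]), collapse = "\n"), "\n",
    '      </SpotsInFrame>\n',
    '      <SpotsInFrame frame="1">\n',
    paste(c(spots_t1[2], spots_t2[2]), collapse = "\n"), "\n",
    '      </SpotsInFrame>\n',
    '      <SpotsInFrame frame="2">\n',
    paste(c(spots_t1[3], spots_t2[3]), collapse = "\n"), "\n",
    '      </SpotsInFrame>\n',
    '      <SpotsInFrame frame="3">\n',
    spots_t2[4], "\n",
    '      </SpotsInFrame>\n',
    '      <SpotsInFrame frame="4">\n',
    spots_t2[5], "\n",
    '      </SpotsInFrame>\n',
    '    </AllSpots>\n',
    '    <AllTracks>\n',
    '      <Track TRACK_ID="0" NUMBER_SPOTS="3">\n',
    '        <Edge SPOT_SOURCE_ID="s1" SPOT_TARGET_ID="s2"/>\n',
    '        <Edge SPOT_SOURCE_ID="s2" SPOT_TARGET_ID="s3"/>\n',
    '      </Track>\n',
    '      <Track TRACK_ID="1" NUMBER_SPOTS="5">\n',
    '        <Edge SPOT_SOURCE_ID="s4" SPOT_TARGET_ID="s5"/>\n',
    '        <Edge SPOT_SOURCE_ID="s5" SPOT_TARGET_ID="s6"/>\n',
    '        <Edge SPOT_SOURCE_ID="s6" SPOT_TARGET_ID="s7"/>\n',
    '        <Edge SPOT_SOURCE_ID="s7" SPOT_TARGET_ID="s8"/>\n',
    '      </Track>\n',
    '    </AllTracks>\n',
    '    <FilteredTracks>\n',
    '      <TrackID TRACK_ID="0"/>\n',
    '      <TrackID TRACK_ID="1"/>\n',
    '    </FilteredTracks>\n',
    '  </Model>\n',
    '  <Settings>\n',
    '    <ImageData filename="movie.tif" pixelwidth="1.0" timeinterval="2.0"/>\n',
    '  </Settings>\n',
    '</TrackMate>\n')
}

trackmate_empty_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<TrackMate version="7.11.1">\n',
    '  <Model spatialunits="micron" timeunits="min">\n',
    '    <AllSpots nspots="0"/>\n',
    '    <AllTracks/>\n',
    '    <FilteredTracks/>\n',
    '  </Model>\n',
    '  <Settings><ImageData timeinterval="2.0"/></Settings>\n',
    '</TrackMate>\n')
}

write_fixture <- function(text, ext = ".xml") {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}

# 6-row CSV describing two 3-point tracks.
tracks_csv_fixture <- function() {
  paste(
    "track_id,frame,t_min,x_um,y_um,condition",
    "a,0,0,0,0,ctrl",
    "a,1,2,1,0,ctrl",
    "a,2,4,2,0,ctrl",
    "b,0,0,5,5,ko",
    "b,1,2,6,5,ko",
    "b,2,4,7,6,ko",
    sep = "\n")
}
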