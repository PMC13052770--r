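# synapse_metrics: calcium normalization/AUC, mask areas, response speed,
# MTOC docking, center-of-mass distance.

test_that("normalize_calcium finds the pre-peak baseline", {
  tr <- intensity_trace("c1", times = 0:4, values = c(100, 100, 100, 300, 200),
                        t_zero = 0)
  nt <- normalize_calcium(tr)
  expect_equal(nt$f0, 100)
  expect_equal(nt$values, c(1, 1, 1, 3, 2))
  expect_equal(nt$peak_index, 4L)
  expect_equal(nt$onset_index, 3L)
  expect_equal(nt$normalized_peak, 3)

  # constant trace: flagged no_peak, normalized ~ 1
  ct <- normalize_calcium(intensity_trace("c2", 0:9, rep(50, 10), t_zero = 3))
  expect_true("no_peak" %in% ct$flags)
  expect_equal(ct$values, rep(1, 10))

  # gain invariance: x10 gives identical normalized output
  tr10 <- intensity_trace("c3", 0:4, 10 * c(100, 100, 100, 300, 200),
                          t_zero = 0)
  expect_equal(normalize_calcium(tr10)$values, nt$values)

  expect_error(normalize_calcium(intensity_trace("c4", 0:3, rep(1, 4))),
               "at least 5")
  zero <- intensity_trace("c5", 0:5, c(0, 0, 0, 5, 3, 1), t_zero = 0)
  expect_error(normalize_calcium(zero), "zero")
})

test_that("calcium_auc integrates the 30-minute interaction window", {
  # constant 1.0 for 30 min -> 30
  flat <- intensity_trace("f", seq(0, 30, 1), rep(1, 31), t_zero = 0)
  expect_equal(as.numeric(calcium_auc(flat)), 30)
  # linear ramp 0 -> 2 over 30 min -> triangle area 30
  ramp <- intensity_trace("r", seq(0, 30, 1), seq(0, 2, length.out = 31),
                          t_zero = 0)
  expect_equal(as.numeric(calcium_auc(ramp)), 30)
  # trapezoid exactness: resampling a linear trace changes nothing
  ramp2 <- intensity_trace("r2", seq(0, 30, 0.5),
                           seq(0, 2, length.out = 61), t_zero = 0)
  expect_equal(as.numeric(calcium_auc(ramp2)), as.numeric(calcium_auc(ramp)),
               tolerance = 1e-9)
  # short trace integrates to its end, flagged truncated
  short <- intensity_trace("s", seq(0, 10, 1), rep(2, 11), t_zero = 0)
  a <- calcium_auc(short)
  expect_true(attr(a, "truncated"))
  expect_equal(as.numeric(a), 20)
  # no samples in window
  late <- intensity_trace("l", 40:50, rep(1, 11), t_zero = 0)
  expect_error(calcium_auc(late), "window")
  # AUC is linear in trace scaling
  tr3 <- intensity_trace("x", seq(0, 30, 1), 3 * seq(0, 2, length.out = 31),
                         t_zero = 0)
  expect_equal(as.numeric(calcium_auc(tr3)), 90)
})

test_that("mask intersection area counts overlapping pixels", {
  full <- matrix(TRUE, 10, 10)
  expect_equal(mask_intersection_area(full, full, 1), 100)
  empty <- matrix(FALSE, 10, 10)
  expect_equal(mask_intersection_area(full, empty, 1), 0)
  # two 10x10 squares offset by 5 px on both axes inside a larger field
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  b <- matrix(FALSE, 20, 20); b[6:15, 6:15] <- TRUE
  expect_equal(mask_intersection_area(a, b, 1), 25)
  # symmetric and bounded by the smaller area
  expect_equal(mask_intersection_area(b, a, 1), 25)
  expect_lte(mask_intersection_area(a, b, 1), min(sum(a), sum(b)))
  # pixel size scales quadratically
  expect_equal(mask_intersection_area(a, b, 0.5), 25 * 0.25)
  expect_error(mask_intersection_area(full, matrix(TRUE, 5, 5)), "shapes")
})

test_that("synapse_area_series follows the analytic overlap schedule", {
  sim <- simulate_mask_movie(n_frames = 12, shape = c(128, 128),
                             pixel_size = 1,
                             center_a = c(30, 64), velocity_a = c(2, 0),
                             center_b = c(98, 64), velocity_b = c(-2, 0),
                             radius_a = 20, radius_b = 20)
  series <- synapse_area_series(sim$t_cell, sim$tumor)
  truth <- attr(sim, "ground_truth")
  expect_true(all(diff(series) >= 0))      # approaching discs: non-decreasing
  expect_true(all(abs(series - truth) <= 2 * 20 * 1))  # one pixel-row

  # never-touching discs: all-zero series
  far <- simulate_mask_movie(n_frames = 5, shape = c(128, 128),
                             center_a = c(25, 30), velocity_a = c(0, 0),
                             center_b = c(100, 100), velocity_b = c(0, 0),
                             radius_a = 15, radius_b = 15)
  expect_equal(synapse_area_series(far$t_cell, far$tumor), rep(0, 5))

  # single-frame movies give a length-1 series
  one <- simulate_mask_movie(n_frames = 1, shape = c(64, 64),
                             center_a = c(32, 32), velocity_a = c(0, 0),
                             center_b = c(32, 32), velocity_b = c(0, 0),
                             radius_a = 10, radius_b = 10)
  s1 <- synapse_area_series(one$t_cell, one$tumor)
  expect_length(s1, 1L)
  # concentric equal discs: overlap = disc area (within rasterization)
  expect_equal(s1, pi * 100, tolerance = 0.02)

  # misalignment and pixel-size mismatch are errors
  shifted <- far$tumor; shifted$times <- shifted$times + 10
  expect_error(synapse_area_series(far$t_cell, shifted), "misaligned")
  resized <- one$tumor; resized$pixel_size <- 2
  expect_error(synapse_area_series(one$t_cell, resized), "pixel")
})

test_that("mask_area_series gives the single-channel spreading area", {
  m <- mask_movie(list(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2),
                       matrix(TRUE, 2, 2)), pixel_size = 2)
  expect_equal(mask_area_series(m), c(3 * 4, 4 * 4))
})

test_that("response_speed is the OLS slope over the first minute", {
  # y = 2t sampled at 0, 20, 40, 60 s
  tt <- c(0, 20, 40, 60) / 60
  tr <- intensity_trace("r", tt, 2 * tt, t_zero = 0)
  expect_equal(response_speed(tr), 2)
  expect_equal(response_speed(intensity_trace("c", tt, rep(5, 4))), 0)
  # symmetric zigzag around y = 2t leaves the slope intact
  zz <- 2 * tt + c(0.01, -0.01, 0.01, -0.01)
  expect_equal(response_speed(intensity_trace("z", tt, zz)), 2,
               tolerance = 0.02)
  # unbiased under symmetric zero-mean noise
  set.seed(5)
  slopes <- replicate(200, {
    t2 <- seq(0, 1, length.out = 7)
    response_speed(intensity_trace("n", t2, pmax(2 * t2 + rnorm(7, 0, 0.05), 0)))
  })
  expect_equal(mean(slopes), 2, tolerance = 0.05)
  # data.frame input and window errors
  df <- data.frame(t_min = tt, value = 2 * tt)
  expect_equal(response_speed(df, t_zero = 0), 2)
  expect_error(response_speed(intensity_trace("few", c(0, 2), c(0, 1))),
               "3 samples")
})

test_that("docking_time finds the first derivative peak", {
  tt <- seq(0, 20, 0.5)
  logi <- intensity_trace("m", tt, 1 / (1 + exp(-(tt - 10))), channel = "mtoc")
  expect_equal(docking_time(logi), 10, tolerance = 0.51)
  # monotone linear trace: constant derivative, no peak
  lin <- intensity_trace("l", tt, 0.3 * tt + 1)
  d <- docking_time(lin)
  expect_true(is.na(d))
  expect_true(attr(d, "no_docking"))
  # step increase at t = 5: derivative spikes at the step frame
  step <- intensity_trace("s", tt, ifelse(tt < 5, 1, 3))
  expect_equal(docking_time(step), 5, tolerance = 0.51)
  expect_error(docking_time(intensity_trace("x", 0:3, c(1, 2, 3, 4))),
               "too short")
})

test_that("com_distance measures centroid-to-interface distance", {
  # unit point mass at y = 3 um, interface y = 0 (line 0x + 1y + 0 = 0)
  img <- matrix(0, 10, 10)
  img[1, 4] <- 1  # x = 0, y = (4-1)*1 = 3
  expect_equal(com_distance(img, c(0, 1, 0), 1), 3)
  # two equal masses at y = 1 and y = 5 -> centroid y = 3
  img2 <- matrix(0, 10, 10)
  img2[1, 2] <- 2; img2[1, 6] <- 2
  expect_equal(com_distance(img2, c(0, 1, 0), 1), 3)
  # centroid on the interface -> 0
  expect_equal(com_distance(img2, c(0, 1, -3), 1), 0)
  # invariant under translation parallel to the interface (shift in x)
  img3 <- matrix(0, 10, 10)
  img3[5, 4] <- 1
  expect_equal(com_distance(img3, c(0, 1, 0), 1),
               com_distance(img, c(0, 1, 0), 1))
  # 3D plane variant
  arr <- array(0, c(4, 4, 4))
  arr[1, 1, 3] <- 1  # z = 2
  expect_equal(com_distance(arr, c(0, 0, 1, 0), 1), 2)
  # pixel size scales linearly
  expect_equal(com_distance(img, c(0, 1, 0), 0.5), 1.5)
  expect_error(com_distance(matrix(0, 5, 5), c(0, 1, 0)), "zero")
  expect_error(com_distance(img, c(0, 1)), "length-3")
})

test_that("trace CSV and mask RLE round-trips", {
  csv <- paste(
    "cell_id,channel,t_min,value,t_zero",
    "c1,calcium,0,100,0", "c1,calcium,1,100,0", "c1,calcium,2,300,0",
    "c1,mtoc,0,5,0", "c1,mtoc,1,6,0",
    sep = "\n")
  path <- write_fixture(csv, ext = ".csv")
  traces <- read_traces_csv(path)
  expect_length(traces, 2L)
  chans <- sort(vapply(traces, `[[`, character(1), "channel"))
  expect_identical(unname(chans), c("calcium", "mtoc"))

  sim <- simulate_mask_movie(n_frames = 3, shape = c(32, 32),
                             center_a = c(12, 16), velocity_a = c(1, 0),
                             center_b = c(20, 16), velocity_b = c(-1, 0),
                             radius_a = 6, radius_b = 6)
  p <- tempfile(fileext = ".csv")
  write_mask_rle_csv(sim$t_cell, p)
  back <- read_mask_rle_csv(p)
  expect_identical(back$frames, sim$t_cell$frames)
  expect_equal(back$pixel_size, sim$t_cell$pixel_size)
  expect_equal(back$times, sim$t_cell$times)
})
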