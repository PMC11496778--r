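test_that("preprocess forms background-corrected ratios and masks bad pixels", {
  d <- array(200, c(8, 8, 2))
  a <- array(300, c(8, 8, 2))
  st <- preprocess(d, a, background = 100, pixel_size = 2,
                   frame_interval = 5, smooth = "none")
  expect_equal(st$values, array(2, c(8, 8, 2)))
  # background at or above the donor masks those pixels with a warning
  d2 <- d; d2[1, 1, 1] <- 90
  expect_warning(
    st2 <- preprocess(d2, a, background = 100, pixel_size = 2,
                      frame_interval = 5, smooth = "none"),
    "masked")
  expect_true(is.na(st2$values[1, 1, 1]))
  expect_equal(st2$values[2, 2, 1], 2)
  # an entirely masked frame is an error
  expect_error(preprocess(array(50, c(4, 4, 1)), array(300, c(4, 4, 1)),
                          background = 100, pixel_size = 2,
                          frame_interval = 5, smooth = "none"),
               "entirely masked")
  expect_error(preprocess(d, array(300, c(4, 4, 2)), 0, 2, 5), "identical")
})

test_that("minimum-projection normalization makes each pixel's minimum one", {
  v <- array(1, c(2, 2, 3))
  v[1, 1, ] <- c(1.0, 1.3, 1.1)
  v[1, 2, ] <- c(1.2, 1.0, 1.5)
  v[2, 1, ] <- 2.0
  st <- normalize_by_min_projection(ratio_stack(v, 2, 5))
  expect_equal(st$values[1, 1, ], c(1.0, 1.3, 1.1))
  expect_equal(st$values[1, 2, ], c(1.2, 1.0, 1.5))
  expect_equal(st$values[2, 1, ], c(1, 1, 1))   # time-constant trace
  expect_equal(apply(st$values, c(1, 2), min), matrix(1, 2, 2))
  expect_error(normalize_by_min_projection(ratio_stack(v[, , 1, drop = FALSE],
                                                       2, 5)),
               "2 frames")
})

test_that("painted discs are segmented with pixel-level accuracy", {
  px <- 2
  frame <- paint_disc(200, px, cx_um = 150, cy_um = 220, radius_um = 50)
  cfg <- detection_config()
  reg <- segment_frame(frame, cfg, pixel_size = px)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$radius_um, 50, tolerance = px / 50)
  expect_equal(reg$x_um, 150, tolerance = px)
  expect_equal(reg$y_um, 220, tolerance = px)
  # discs below the detection limit are discarded
  small <- paint_disc(100, px, 100, 100, radius_um = 20)
  expect_equal(nrow(segment_frame(small, cfg, px)), 0L)
  # ... but kept when the limit allows them
  cfg_lo <- detection_config(min_radius = 10)
  expect_equal(nrow(segment_frame(small, cfg_lo, px)), 1L)
  # an all-baseline frame yields nothing
  expect_equal(nrow(segment_frame(matrix(1, 50, 50), cfg, px)), 0L)
})

test_that("segmentation radius error stays within one pixel on clean discs", {
  px <- 2
  cfg <- detection_config(min_radius = 0)
  for (r_um in c(10, 24, 40, 80)) {
    reg <- segment_frame(paint_disc(120, px, 120, 120, r_um), cfg, px)
    expect_equal(nrow(reg), 1L)
    expect_lt(abs(reg$radius_um - r_um), px)
  }
})

test_that("detection is invariant to a common intensity rescaling", {
  sc <- render_scene(small_scene_config(noise_sd_frac = 0.01, seed = 5))
  st1 <- preprocess(sc$donor, sc$acceptor, 100, 4, 5)
  st2 <- preprocess((sc$donor - 100) * 3 + 100, (sc$acceptor - 100) * 3 + 100,
                    100, 4, 5)
  ev1 <- detect_events(st1)
  ev2 <- detect_events(st2)
  expect_equal(as.data.frame(ev1), as.data.frame(ev2), tolerance = 1e-12)
})

test_that("tracking follows drifting events and respects the linking rule", {
  cfg <- detection_config()
  # one disc drifting 10 um per frame stays one event
  regs <- lapply(0:4, function(k) regions_df(c(100 + 10 * k, 200, 40)))
  ev <- track_events(regs, cfg, frame_interval = 60)
  expect_equal(unique(ev$event_id), 1L)
  expect_equal(nrow(ev), 5L)
  expect_equal(ev$t_s, 60 * (0:4))
  # two simultaneous discs 150 um apart are distinct events
  regs2 <- list(regions_df(c(100, 100, 40), c(250, 100, 40)),
                regions_df(c(100, 100, 40), c(250, 100, 40)))
  ev2 <- track_events(regs2, cfg)
  expect_equal(length(unique(ev2$event_id)), 2L)
  # the same-event rule only looks at successive frames: a one-frame gap
  # splits the track
  none <- data.frame(x_um = numeric(0), y_um = numeric(0),
                     radius_um = numeric(0))
  regs3 <- list(regions_df(c(100, 100, 40)), none, regions_df(c(100, 100, 40)))
  ev3 <- track_events(regs3, cfg)
  expect_equal(length(unique(ev3$event_id)), 2L)
  # centers farther than link_distance are never linked
  regs4 <- list(regions_df(c(100, 100, 40)), regions_df(c(210, 100, 40)))
  ev4 <- track_events(regs4, cfg)
  expect_equal(length(unique(ev4$event_id)), 2L)
})

test_that("greedy linking claims closest pairs first and one-to-one", {
  cfg <- detection_config()
  # one previous event, two candidates in range: the closer one wins
  regs <- list(regions_df(c(100, 100, 40)),
               regions_df(c(180, 100, 40), c(130, 100, 40)))
  ev <- track_events(regs, cfg)
  per <- split(ev, ev$event_id)
  cont <- per[[1]]
  expect_equal(nrow(cont), 2L)
  expect_equal(cont$x_um[2], 130)    # nearest candidate continues event 1
  expect_equal(length(per), 2L)      # the other starts a new event
})

test_that("event statistics summarise maxima, diameters and histograms", {
  ev <- structure(data.frame(
    event_id = c(1L, 1L, 2L), frame = c(1L, 2L, 1L), t_s = c(0, 60, 0),
    x_um = c(0, 0, 500), y_um = c(0, 0, 500), radius_um = c(80, 100, 120)),
    class = c("rspa_events", "data.frame"))
  st <- event_statistics(ev)
  expect_equal(st$events$max_radius_um, c(100, 120))
  expect_equal(st$summary$mean_diameter_um, 220)
  expect_equal(sum(st$histogram$count), 2L)
  empty <- event_statistics(track_events(list(), detection_config()))
  expect_equal(empty$summary$n_events, 0L)
  expect_equal(nrow(empty$events), 0L)
})
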