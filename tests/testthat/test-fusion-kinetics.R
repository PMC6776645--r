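# Event segmentation, trace extraction, power-law fitting, fusion times.

test_that("power-law fits recover exact laws", {
  t <- seq(0.03, 6, by = 0.03)
  fit <- fit_power_law(intensity_trace(t, 2 * t^(-0.23)))
  expect_equal(unname(coef(fit)), c(2, 0.23), tolerance = 1e-10)
  expect_gt(fit$r_squared, 0.9999)
  # constant trace: n = 0, a = level
  fc <- fit_power_law(intensity_trace(t, rep(5, length(t))))
  expect_equal(unname(coef(fc)), c(5, 0), tolerance = 1e-12)
  # 2-D point-source reference line
  f1 <- fit_power_law(intensity_trace(t, 7 * t^(-1)))
  expect_equal(unname(coef(f1))[2], 1, tolerance = 1e-10)
  # binned and Theil-Sen variants agree on clean data
  fb <- fit_power_law(intensity_trace(t, 2 * t^(-0.23)), log_bins = 8)
  expect_equal(fb$n, 0.23, tolerance = 1e-3)
  ft <- fit_power_law(intensity_trace(t, 2 * t^(-0.23)),
                      method = "theil_sen")
  expect_equal(ft$n, 0.23, tolerance = 1e-6)
})

test_that("fits are refused with too few usable points", {
  t <- seq(0.03, 0.18, by = 0.03)
  expect_error(fit_power_law(intensity_trace(t, 2 * t^(-0.2))),
               "refused")
  tr <- intensity_trace(seq(0.03, 6, 0.03),
                        rep(c(1, -1), 100), background_sigma = 5)
  expect_error(fit_power_law(tr), "refused")
})

test_that("fusion time inverts the decay law within one frame", {
  dt <- 0.03
  t <- seq(dt, 15, by = dt)
  # I = 2 t^(-1) crosses eps = 1 at t = 2
  tr <- intensity_trace(t, 2 * t^(-1), frame_interval = dt)
  ft <- fusion_time(tr, threshold = 1)
  expect_false(ft$censored)
  expect_equal(ft$fusion_time_s, 2 - dt, tolerance = dt)
  # closed form across exponents: t_cross = (a/eps)^(1/n)
  for (n in c(0.3, 0.6, 1)) {
    trn <- intensity_trace(t, 2 * t^(-n), frame_interval = dt)
    ftn <- fusion_time(trn, threshold = 1)
    expect_equal(ftn$fusion_time_s + dt, 2^(1 / n), tolerance = dt * 1.5)
  }
  # monotone: fusion time strictly decreases as n increases
  times_n <- vapply(c(0.3, 0.6, 1), function(n)
    fusion_time(intensity_trace(t, 2 * t^(-n), frame_interval = dt),
                threshold = 1)$fusion_time_s, numeric(1))
  expect_true(all(diff(times_n) < 0))
})

test_that("step traces and non-decaying traces are handled", {
  dt <- 0.03
  t <- seq(dt, 3, by = dt)
  step <- intensity_trace(t, c(100, rep(0, length(t) - 1)),
                          background_sigma = 1, frame_interval = dt)
  fs <- fusion_time(step)
  expect_equal(fs$fusion_time_s, dt)
  flat <- intensity_trace(t, rep(100, length(t)),
                          background_sigma = 1, frame_interval = dt)
  ff <- fusion_time(flat)
  expect_true(ff$censored)
  expect_equal(ff$fusion_time_s, max(t) - dt)
})

test_that("noiseless extraction reproduces the rendering law exactly", {
  mv <- single_noiseless_event(a = 2, n = 0.23)
  tru <- mv$truth
  tr <- extract_trace(mv, tru$x_um, tru$y_um,
                      landing_frame = tru$landing_frame,
                      onset_frame = tru$fusion_frame,
                      background_mode = "annulus")
  expect_equal(tr$intensity, 2 * tr$times^(-0.23), tolerance = 1e-3)
})

test_that("annulus background tolerates a sloped bilayer", {
  pat <- matrix(rep(seq(0.9, 1.1, length.out = 64), each = 64), 64, 64)
  sc <- tirf_scene(dim = c(64, 64), n_frames = 150, read_sigma = 0,
                   seed = 5, bilayer_pattern = pat)
  pos <- c(5.07, 5.11)
  ev <- tirf_event(landing_time = 0.3, position = pos, a = 2,
                   n = 0.23, dwell = 0.3, pre_landing_D = 0)
  mv <- render_movie(sc, list(ev), noise = FALSE)
  tr <- extract_trace(mv, pos[1], pos[2],
                      landing_frame = mv$truth$landing_frame,
                      onset_frame = mv$truth$fusion_frame,
                      background_mode = "annulus")
  expect_equal(tr$intensity, 2 * tr$times^(-0.23), tolerance = 0.02)
})

test_that("events at the movie start fall back to annulus background", {
  mv <- single_noiseless_event()
  expect_warning(
    extract_trace(mv, mv$truth$x_um, mv$truth$y_um, landing_frame = 2,
                  onset_frame = 20),
    "annulus")
})

test_that("overlapping concurrent events flag contamination", {
  mv <- single_noiseless_event()
  expect_warning(
    tr <- extract_trace(mv, mv$truth$x_um, mv$truth$y_um,
                        landing_frame = mv$truth$landing_frame,
                        onset_frame = mv$truth$fusion_frame,
                        background_mode = "annulus",
                        other_xy_um = cbind(mv$truth$x_um + 0.5,
                                            mv$truth$y_um)),
    "contaminated")
  expect_true(tr$contaminated)
})

test_that("segmentation finds scripted events at their true frames", {
  mv <- grid_event_movie(n_events = 9, seed = 21)
  tk <- track_movie(mv)
  segs <- segment_events(tk, mv)
  expect_gte(length(segs), 8)
  tru <- mv$truth
  dock_err <- vapply(segs, function(e) {
    k <- which.min((tru$x_um - e$x_um)^2 + (tru$y_um - e$y_um)^2)
    expect_lt(sqrt((tru$x_um[k] - e$x_um)^2 +
                     (tru$y_um[k] - e$y_um)^2), 0.16)  # within 1 px
    e$landing_frame - tru$landing_frame[k]
  }, numeric(1))
  expect_lte(stats::median(abs(dock_err)), 1)
})

test_that("mobile never-fusing particles produce no events", {
  sc <- tirf_scene(dim = c(96, 96), n_frames = 100, seed = 31)
  evs <- lapply(1:4, function(k)
    tirf_event(landing_time = 1e3, position = c(7.7, 7.7) +
                 (k - 2) * c(2, -1.5),
               a = amplitude_for_peak(120, 1 / 6, 0.03),
               pre_landing_D = 2))
  mv <- suppressWarnings(render_movie(sc, evs))
  segs <- segment_events(track_movie(mv), mv)
  expect_length(segs, 0)
})

test_that("a long scripted dwell is resolved to about a frame", {
  sc <- tirf_scene(dim = c(64, 64), n_frames = 900, seed = 41)
  pos <- c(5.1, 5.1)
  ev <- tirf_event(landing_time = 0.9, position = pos,
                   a = amplitude_for_peak(500, 1 / 6, 0.03),
                   dwell = 20, pre_landing_D = 2.45)
  mv <- render_movie(sc, list(ev))
  segs <- segment_events(track_movie(mv), mv)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$dwell_s, 20, tolerance = 0.0501)
})

test_that("aggregation reduces correctly and is label-invariant", {
  df <- data.frame(event_id = 1L, condition = "A", x_um = 1, y_um = 1,
                   t_land_s = 0.3, dwell_s = 0.45, fusion_time_s = 4.2,
                   censored = FALSE, a = 2, n = 0.17, r2 = 0.95)
  s1 <- aggregate_events(df)
  expect_equal(s1$n_events, 1)
  expect_equal(s1$mean_fusion_time, 4.2)
  expect_equal(s1$mean_n, 0.17)
  two <- rbind(transform(df, condition = "A"),
               transform(df, condition = "B"))
  two$n <- c(0.1, 0.1); two$fusion_time_s <- c(3, 3)
  s2 <- aggregate_events(two)
  expect_equal(s2$mean_n[1], s2$mean_n[2])
  expect_equal(s2$median_fusion_time[1], s2$median_fusion_time[2])
})

test_that("generated exponents are identifiable and ordered", {
  set.seed(51)
  dt <- 0.03
  t <- seq(dt, 8, by = dt)
  mean_fit <- vapply(c(1 / 6, 0.5, 1), function(n0) {
    fits <- vapply(1:25, function(r) {
      I <- 60 * t^(-n0) + rnorm(length(t), 0, 3)
      tr <- intensity_trace(t, I, background_sigma = 3,
                            frame_interval = dt)
      fit_power_law(tr, log_bins = 8)$n
    }, numeric(1))
    mean(fits)
  }, numeric(1))
  expect_true(all(diff(mean_fit) > 0))
  expect_equal(mean_fit, c(1 / 6, 0.5, 1), tolerance = 0.08)
})
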