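# Spot detection, linking, MSD estimation and Stokes-Einstein sizing.

make_spot_frame <- function(pos_px, amp = 100, dim = c(64, 64),
                            bg = 100, sigma = 1.3) {
  fr <- matrix(bg, dim[1], dim[2])
  for (k in seq_len(nrow(pos_px)))
    fr <- cubofuse:::add_gaussian_spot(fr, pos_px[k, 1] * 0.16,
                                       pos_px[k, 2] * 0.16, amp,
                                       sigma, 0.16)
  fr
}

test_that("a blank frame yields no detections", {
  expect_equal(nrow(detect_spots(matrix(100, 64, 64))), 0)
  # pure-noise frame: robust threshold rejects all maxima
  set.seed(1)
  noisy <- apply_camera_noise(matrix(100, 64, 64), read_sigma = 2)
  expect_equal(nrow(detect_spots(noisy)), 0)
})

test_that("well-separated spots are localised to sub-pixel accuracy", {
  set.seed(2)
  pos <- cbind(x = runif(10, 8, 56), y = runif(10, 8, 56))
  ok <- rep(TRUE, 10)  # enforce >= 8 px separation
  for (i in 2:10) ok[i] <- all(sqrt(rowSums((pos[seq_len(i - 1), ,
    drop = FALSE] - matrix(pos[i, ], i - 1, 2, byrow = TRUE))^2)) > 8)
  pos <- pos[ok, , drop = FALSE]
  fr <- make_spot_frame(pos)
  sp <- detect_spots(fr, threshold = 10)
  expect_equal(nrow(sp), nrow(pos))
  for (k in seq_len(nrow(pos))) {
    d <- sqrt((sp$x_px - pos[k, 1])^2 + (sp$y_px - pos[k, 2])^2)
    expect_lt(min(d), 0.2)
  }
})

test_that("detection and recall stay above 95% at SNR 10", {
  set.seed(3)
  hits <- 0; total <- 0; spurious <- 0
  for (f in 1:15) {
    pos <- cbind(runif(8, 8, 56), runif(8, 8, 56))
    keep <- rep(TRUE, 8)
    for (i in 2:8) keep[i] <- all(sqrt(rowSums((pos[seq_len(i - 1), ,
      drop = FALSE] - matrix(pos[i, ], i - 1, 2, byrow = TRUE))^2)) > 10)
    pos <- pos[keep, , drop = FALSE]
    fr <- apply_camera_noise(make_spot_frame(pos, amp = 102),
                             read_sigma = 2)
    sp <- detect_spots(fr)
    total <- total + nrow(pos)
    for (k in seq_len(nrow(pos))) {
      d <- sqrt((sp$x_px - pos[k, 1])^2 + (sp$y_px - pos[k, 2])^2)
      if (length(d) && min(d) < 1.5) hits <- hits + 1
    }
    spurious <- spurious + max(0, nrow(sp) - nrow(pos))
  }
  expect_gt(hits / total, 0.95)            # recall
  expect_gt(hits / (hits + spurious), 0.95) # precision
})

test_that("a close pair is never reported as duplicates", {
  fr <- make_spot_frame(cbind(c(30, 33), c(30, 30)))
  sp <- detect_spots(fr, diameter_px = 7, threshold = 10)
  near <- sum(sqrt((sp$x_px - 31.5)^2 + (sp$y_px - 30)^2) < 6)
  expect_lte(near, 1)
})

test_that("linking keeps one persistent spot in one track", {
  sp <- data.frame(frame = 1:50, x_px = 20 + 0.05 * sin(1:50),
                   y_px = 20.2)
  tr <- link_tracks(sp, max_disp_px = 3)
  expect_equal(unique(tr$track_id), 1L)
  expect_equal(nrow(tr), 50)
})

test_that("two passing particles keep their identities", {
  fr <- rep(1:60, each = 2)
  sp <- data.frame(frame = fr,
                   x_px = ifelse(seq_along(fr) %% 2 == 1,
                                 5 + 0.5 * fr, 35 - 0.5 * fr),
                   y_px = ifelse(seq_along(fr) %% 2 == 1, 20, 20.8))
  tr <- link_tracks(sp, max_disp_px = 2)
  expect_equal(length(unique(tr$track_id)), 2)
  for (id in unique(tr$track_id)) {
    y <- tr$y_px[tr$track_id == id]
    expect_equal(length(unique(y)), 1)  # no identity swap
  }
})

test_that("gap memory bridges short disappearances only", {
  sp <- data.frame(frame = c(1:10, 13:20), x_px = 15, y_px = 15)
  tr2 <- link_tracks(sp, max_disp_px = 3, memory = 2)
  expect_equal(length(unique(tr2$track_id)), 1)
  tr0 <- link_tracks(sp, max_disp_px = 3, memory = 1)
  expect_equal(length(unique(tr0$track_id)), 2)
})

test_that("MSD of degenerate motions behaves as expected", {
  still <- data.frame(frame = 1:40, x_um = 2, y_um = 3)
  m <- compute_msd(still, frame_interval = 0.1)
  expect_equal(m$D_um2_s, 0)
  expect_equal(max(m$msd_um2), 0)
  ball <- data.frame(frame = 1:100, x_um = 0.5 * (1:100) * 0.1,
                     y_um = 0)
  mb <- compute_msd(ball, frame_interval = 0.1)
  expect_equal(mb$msd_um2, 0.25 * mb$lag_s^2, tolerance = 1e-10)
  expect_lt(mb$r_squared, 0.99)  # flagged as poorly linear
  expect_error(compute_msd(still[1:5, ], frame_interval = 0.1),
               "short")
})

test_that("Brownian tracks recover their diffusion coefficient", {
  set.seed(11)
  p <- brownian_path(D = 2, n_steps = 999, frame_interval = 0.03)
  tr <- data.frame(frame = 1:1000, x_um = p[, 1], y_um = p[, 2])
  m <- compute_msd(tr, frame_interval = 0.03)
  expect_equal(m$D_um2_s, 2, tolerance = 0.15)
  expect_gt(m$r_squared, 0.98)
})

test_that("full detection pipeline recovers D across seeded movies", {
  errs <- vapply(1:50, function(s) {
    sc <- tirf_scene(dim = c(96L, 96L), n_frames = 80L, seed = 100 + s)
    ev <- tirf_event(landing_time = 1e3, position = c(7.68, 7.68),
                     a = amplitude_for_peak(120, 1 / 6, 0.03),
                     pre_landing_D = 1)
    mv <- suppressWarnings(render_movie(sc, list(ev)))
    tk <- track_movie(mv, max_disp_px = 6, memory = 2)
    main <- names(which.max(table(tk$track_id)))
    tr <- tk[tk$track_id == as.integer(main), ]
    if (nrow(tr) < 40) return(NA_real_)
    abs(compute_msd(tr, frame_interval = 0.03)$D_um2_s - 1)
  }, numeric(1))
  errs <- errs[!is.na(errs)]
  expect_gt(length(errs), 40)
  expect_lt(stats::median(errs), 0.1)
  # unbiased within Monte-Carlo error: mean signed error small
  expect_lt(abs(stats::median(errs)), 0.1)
})

test_that("Stokes-Einstein sizing and its inverse agree", {
  D <- stokes_einstein_D(200, temperature = 298, viscosity = 0.89e-3)
  expect_equal(D, 2.45, tolerance = 0.005)
  expect_equal(stokes_einstein_diameter(D), 200, tolerance = 1e-12)
  expect_equal(stokes_einstein_diameter(2 * D),
               stokes_einstein_diameter(D) / 2)
  expect_error(stokes_einstein_diameter(-1), "positive")
})
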