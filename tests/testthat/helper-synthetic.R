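# Shared fixture builders; everything is generated in code at test time.

# Scene noise scale for the default 100-count background, 2-count read
# noise: sqrt(background + read_sigma^2).
default_noise_sd <- function(background = 100, read_sigma = 2) {
  sqrt(background + read_sigma^2)
}

# A movie with `n_events` scripted fusion events on a jittered grid,
# decaying with exponent n_exp; mirrors the conditions of the ensemble
# study at adjustable size.
grid_event_movie <- function(n_events = 9, dim = c(96L, 96L),
                             n_frames = 220L, n_exp = 1 / 6,
                             peak_snr = 10, dwell_frames = 15L,
                             seed = 42L, noise = TRUE,
                             read_sigma = 2) {
  sc <- tirf_scene(dim = dim, n_frames = n_frames,
                   read_sigma = read_sigma, seed = seed)
  nsd <- default_noise_sd(sc$background_level, read_sigma)
  set.seed(seed + 1L)
  ncol_g <- ceiling(sqrt(n_events))
  nrow_g <- ceiling(n_events / ncol_g)
  cw <- dim[2] / ncol_g; ch <- dim[1] / nrow_g
  evs <- lapply(seq_len(n_events), function(k) {
    gi <- (k - 1) %/% ncol_g; gj <- (k - 1) %% ncol_g
    pos <- c((gj * cw + cw / 2 + runif(1, -2, 2)) * sc$pixel_size,
             (gi * ch + ch / 2 + runif(1, -2, 2)) * sc$pixel_size)
    tirf_event(landing_time = sample(10:30, 1) * sc$frame_interval,
               position = pos,
               a = amplitude_for_peak(peak_snr * nsd, n_exp,
                                      sc$frame_interval),
               n = n_exp, dwell = dwell_frames * sc$frame_interval,
               pre_landing_D = 2.45)
  })
  render_movie(sc, evs, noise = noise)
}

# One noiseless event at an off-centre sub-pixel position.
single_noiseless_event <- function(a = 2, n = 0.23, dwell = 0.45,
                                   n_frames = 250L, seed = 3L) {
  sc <- tirf_scene(dim = c(64L, 64L), n_frames = n_frames,
                   read_sigma = 0, seed = seed)
  ev <- tirf_event(landing_time = 0.3, position = c(5.07, 5.11),
                   a = a, n = n, dwell = dwell, pre_landing_D = 2.45)
  render_movie(sc, list(ev), noise = FALSE)
}
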