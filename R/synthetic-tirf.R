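#' Scene prescription for a synthetic TIRF movie
#'
#' Describes everything about a synthetic movie except the fusion events:
#' geometry, calibration, bilayer background pattern, camera noise and
#' the random seed. Identical prescriptions with identical seeds render
#' bit-identical movies.
#'
#' @param dim frame shape in pixels, `c(ny, nx)` (rows, columns).
#' @param pixel_size pixel calibration (um/px); default 0.16.
#' @param frame_interval time between frames (s); default 0.03.
#' @param n_frames number of frames.
#' @param background_level mean bilayer fluorescence (counts) of a
#'   single-bilayer region.
#' @param bilayer_pattern per-pixel background multiplier matrix of shape
#'   `dim` (1 = single bilayer, 2 = stacked double-layer patch, < 1 =
#'   dark domain); `NULL` means uniform 1.
#' @param gain camera gain applied before Poisson shot noise.
#' @param read_sigma Gaussian read-noise standard deviation (counts).
#' @param psf_sigma_px point-spread-function sigma (px); ~diffraction
#'   limited at the default calibration.
#' @param seed integer seed controlling every random draw in rendering.
#' @return An object of class `tirf_scene`.
#' @export
tirf_scene <- function(dim = c(128L, 128L), pixel_size = 0.16,
                       frame_interval = 0.03, n_frames = 100L,
                       background_level = 100, bilayer_pattern = NULL,
                       gain = 1, read_sigma = 2, psf_sigma_px = 1.3,
                       seed = 1L) {
  stopifnot(length(dim) == 2, all(dim >= 8), pixel_size > 0,
            frame_interval > 0, n_frames >= 1, background_level >= 0,
            gain > 0, read_sigma >= 0, psf_sigma_px > 0)
  if (is.null(bilayer_pattern)) bilayer_pattern <- matrix(1, dim[1], dim[2])
  if (!identical(dim(bilayer_pattern), as.integer(dim)))
    stop("'bilayer_pattern' must be a matrix of shape dim")
  if (any(bilayer_pattern < 0)) stop("bilayer multipliers must be >= 0")
  structure(list(dim = as.integer(dim), pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 background_level = background_level,
                 bilayer_pattern = bilayer_pattern, gain = gain,
                 read_sigma = read_sigma, psf_sigma_px = psf_sigma_px,
                 seed = as.integer(seed)),
            class = "tirf_scene")
}

#' @export
print.tirf_scene <- function(x, ...) {
  cat(sprintf(paste0("TIRF scene: %d x %d px (%.3g um/px), %d frames @ ",
                     "%.3g s, background %g counts, seed %d\n"),
              x$dim[1], x$dim[2], x$pixel_size, x$n_frames,
              x$frame_interval, x$background_level, x$seed))
  invisible(x)
}

#' Prescription of one synthetic fusion event
#'
#' A particle diffuses above the bilayer, docks at `position` at
#' `landing_time`, dwells for `dwell` seconds, then fuses: its peak
#' intensity above background decays as `I(tau) = a (tau + t_off)^(-n)`
#' (`tau` = time since fusion start) while its Gaussian footprint sigma
#' grows as `sqrt(psf^2 + (footprint_growth^2) tau)`. The amplitude `a`
#' is the power-law coefficient in counts s^n, i.e. the same `a` a fit of
#' `I = a t^(-n)` to the extracted trace reports; the rendered peak at
#' fusion start is `a * t_off^(-n)` counts (see [amplitude_for_peak()]).
#'
#' @param landing_time docking time (s from movie start).
#' @param position docking position `c(x, y)` in um.
#' @param a power-law amplitude (counts s^n).
#' @param n decay exponent (>= 0); the fusion model predicts 1/6.
#' @param t_off time offset regularising the law at fusion start (s);
#'   `NA` means one frame interval, resolved at render time.
#' @param dwell docked time before fusion starts (s).
#' @param pre_landing_D Brownian diffusion coefficient before docking
#'   (um^2/s).
#' @param footprint_growth footprint spreading rate (um s^-1/2).
#' @return An object of class `tirf_event`.
#' @export
tirf_event <- function(landing_time, position, a, n = 1 / 6, t_off = NA,
                       dwell = 0.45, pre_landing_D = 2.45,
                       footprint_growth = 0.3) {
  stopifnot(landing_time >= 0, length(position) == 2, a > 0, n >= 0,
            is.na(t_off) || t_off > 0, dwell >= 0, pre_landing_D >= 0,
            footprint_growth >= 0)
  structure(list(landing_time = landing_time,
                 position = as.numeric(position), a = a, n = n,
                 t_off = t_off, dwell = dwell,
                 pre_landing_D = pre_landing_D,
                 footprint_growth = footprint_growth),
            class = "tirf_event")
}

#' Convert a desired docking peak intensity into a power-law amplitude
#'
#' @param peak_counts desired rendered peak intensity above background at
#'   fusion start (counts).
#' @param n decay exponent.
#' @param t_off time offset of the rendered law (s).
#' @return Amplitude `a = peak_counts * t_off^n` (counts s^n).
#' @export
amplitude_for_peak <- function(peak_counts, n, t_off) {
  stopifnot(peak_counts > 0, n >= 0, t_off > 0)
  peak_counts * t_off^n
}

#' 2-D Brownian path
#'
#' Gaussian random walk with per-axis, per-step displacement variance
#' `2 D dt` (so the 2-D mean-squared displacement grows as `4 D t`).
#'
#' @param D diffusion coefficient (um^2/s).
#' @param n_steps number of steps; the path has `n_steps + 1` positions.
#' @param frame_interval time step (s).
#' @param seed optional integer seed (`NULL` = use current RNG state).
#' @param origin starting position `c(x, y)` in um.
#' @return A `(n_steps + 1) x 2` matrix of positions (um), columns
#'   `x`, `y`.
#' @export
brownian_path <- function(D, n_steps, frame_interval, seed = NULL,
                          origin = c(0, 0)) {
  stopifnot(D >= 0, n_steps >= 1, frame_interval > 0)
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(2 * D * frame_interval)
  steps <- matrix(stats::rnorm(2L * n_steps, 0, sd), ncol = 2)
  pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
  pos <- sweep(pos, 2, as.numeric(origin), "+")
  colnames(pos) <- c("x", "y")
  pos
}

#' Apply EMCCD-style camera noise to a frame
#'
#' Poisson shot noise on the gain-scaled signal plus additive Gaussian
#' read noise, clipped at zero. The expectation over many realisations
#' equals the noiseless frame.
#'
#' @param frame numeric matrix of noiseless counts (>= 0).
#' @param gain camera gain (> 0).
#' @param read_sigma read-noise sd in counts (>= 0).
#' @param seed optional integer seed (`NULL` = current RNG state).
#' @return Noisy frame, same shape, clipped at 0.
#' @export
apply_camera_noise <- function(frame, gain = 1, read_sigma = 2,
                               seed = NULL) {
  stopifnot(gain > 0, read_sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- stats::rpois(length(frame), pmax(frame, 0) * gain) / gain
  if (read_sigma > 0)
    out <- out + stats::rnorm(length(frame), 0, read_sigma)
  matrix(pmax(out, 0), nrow(frame), ncol(frame))
}

#' Lognormal particle-size sample with a prescribed arithmetic mean
#'
#' Particle sizes in these preparations are right-skewed; a lognormal
#' with arithmetic mean `mean_nm` reproduces that. Sizes modulate the
#' event amplitude (proportional to size) and the pre-landing diffusion
#' coefficient (inversely proportional, per Stokes-Einstein).
#'
#' @param mean_nm arithmetic mean size (nm).
#' @param sigma_log log-scale sd of the lognormal.
#' @param n sample size.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` sizes (nm).
#' @export
sample_size_distribution <- function(mean_nm = 200, sigma_log = 0.3, n,
                                     seed = NULL) {
  stopifnot(mean_nm > 0, sigma_log >= 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (sigma_log == 0) return(rep(mean_nm, n))
  stats::rlnorm(n, meanlog = log(mean_nm) - sigma_log^2 / 2,
                sdlog = sigma_log)
}

# Add a Gaussian spot (amplitude at its centre = amp) to a frame in
# place-of-copy style; positions in um, pixel centres at (j - 0.5) px.
add_gaussian_spot <- function(frame, x_um, y_um, amp, sigma_px,
                              pixel_size) {
  ny <- nrow(frame); nx <- ncol(frame)
  cx <- x_um / pixel_size + 0.5
  cy <- y_um / pixel_size + 0.5
  w <- ceiling(4 * sigma_px)
  j0 <- max(1L, floor(cx - w)); j1 <- min(nx, ceiling(cx + w))
  i0 <- max(1L, floor(cy - w)); i1 <- min(ny, ceiling(cy + w))
  if (j0 > j1 || i0 > i1) return(frame)
  jj <- j0:j1; ii <- i0:i1
  gx <- exp(-((jj - cx)^2) / (2 * sigma_px^2))
  gy <- exp(-((ii - cy)^2) / (2 * sigma_px^2))
  frame[ii, jj] <- frame[ii, jj] + amp * outer(gy, gx)
  frame
}

#' Render a synthetic TIRF movie
#'
#' Renders the bilayer background (`background_level * bilayer_pattern`),
#' each event's pre-landing Brownian spot, docked dwell and post-fusion
#' decaying/spreading halo, and finally camera noise. With
#' `intensity_mode = "peak_law"` the peak pixel of an event follows
#' `a (tau + t_off)^(-n)` above background; with `"conserved"` the
#' background-subtracted integral of the spot is held constant while it
#' spreads (dye conservation), so the peak decays as the footprint area
#' grows.
#'
#' @param scene a [tirf_scene()].
#' @param events list of [tirf_event()] objects (may be empty).
#' @param noise apply camera noise (`FALSE` gives the noiseless movie).
#' @param intensity_mode `"peak_law"` (default) or `"conserved"`.
#' @return An object of class `tirf_movie`: list with `frames` (array
#'   `ny x nx x n_frames`, counts), `scene`, `truth` (ground-truth data
#'   frame, one row per event: positions, landing/fusion frames and the
#'   generating `(a, n, t_off)` and `pre_landing_D`), and `paths` (list
#'   of per-event pre-landing trajectories, columns `frame`, `x_um`,
#'   `y_um`).
#' @examples
#' sc <- tirf_scene(dim = c(48, 48), n_frames = 60, seed = 7)
#' ev <- tirf_event(landing_time = 0.3, position = c(3.8, 3.8),
#'                  a = amplitude_for_peak(100, 1/6, 0.03))
#' mv <- render_movie(sc, list(ev))
#' @export
render_movie <- function(scene, events = list(), noise = TRUE,
                         intensity_mode = c("peak_law", "conserved")) {
  stopifnot(inherits(scene, "tirf_scene"))
  intensity_mode <- match.arg(intensity_mode)
  ny <- scene$dim[1]; nx <- scene$dim[2]
  nf <- scene$n_frames; dt <- scene$frame_interval
  px <- scene$pixel_size
  frame_times <- (seq_len(nf) - 1) * dt
  duration <- frame_times[nf]
  base <- scene$background_level * scene$bilayer_pattern

  # resolve events, seed-derived pre-landing paths
  set.seed(scene$seed)
  ev_list <- lapply(seq_along(events), function(k) {
    e <- events[[k]]
    stopifnot(inherits(e, "tirf_event"))
    if (is.na(e$t_off)) e$t_off <- dt
    if (e$landing_time + e$dwell > duration)
      warning(sprintf("event %d starts fusing after the movie ends", k))
    if (e$position[1] < 0 || e$position[1] > nx * px ||
        e$position[2] < 0 || e$position[2] > ny * px)
      warning(sprintf("event %d lies outside the field of view; clipped", k))
    e$landing_frame <- as.integer(min(nf, floor(e$landing_time / dt) + 1))
    fusion_start <- e$landing_time + e$dwell
    e$fusion_start <- fusion_start
    ff <- which(frame_times >= fusion_start - 1e-9)
    e$fusion_frame <- as.integer(if (length(ff)) ff[1] else nf)
    # Brownian approach path, translated to end at the docking position
    n_pre <- e$landing_frame - 1L
    if (n_pre >= 1 && e$pre_landing_D >= 0) {
      p <- brownian_path(e$pre_landing_D, n_pre, dt)
      p <- sweep(p, 2, p[n_pre + 1L, ] - e$position, "-")
      e$path <- p[seq_len(n_pre), , drop = FALSE]
    } else e$path <- matrix(numeric(0), 0, 2)
    e
  })

  frames <- array(0, dim = c(ny, nx, nf))
  s_psf <- scene$psf_sigma_px
  for (f in seq_len(nf)) {
    fr <- base
    t <- frame_times[f]
    for (e in ev_list) {
      if (f < e$landing_frame) {
        if (f <= nrow(e$path))
          fr <- add_gaussian_spot(fr, e$path[f, 1], e$path[f, 2],
                                  e$a * e$t_off^(-e$n), s_psf, px)
      } else if (t < e$fusion_start - 1e-9) {
        fr <- add_gaussian_spot(fr, e$position[1], e$position[2],
                                e$a * e$t_off^(-e$n), s_psf, px)
      } else {
        tau <- max(0, t - e$fusion_start)
        sig <- sqrt(s_psf^2 + (e$footprint_growth * sqrt(tau) / px)^2)
        amp <- if (intensity_mode == "peak_law")
          e$a * (tau + e$t_off)^(-e$n)
        else
          e$a * e$t_off^(-e$n) * s_psf^2 / sig^2
        fr <- add_gaussian_spot(fr, e$position[1], e$position[2],
                                amp, sig, px)
      }
    }
    frames[, , f] <- fr
  }
  if (noise) {
    for (f in seq_len(nf))
      frames[, , f] <- apply_camera_noise(frames[, , f], scene$gain,
                                          scene$read_sigma)
  }
  truth <- if (length(ev_list)) data.frame(
    event = seq_along(ev_list),
    x_um = vapply(ev_list, function(e) e$position[1], 0),
    y_um = vapply(ev_list, function(e) e$position[2], 0),
    landing_time_s = vapply(ev_list, `[[`, 0, "landing_time"),
    landing_frame = vapply(ev_list, `[[`, 0L, "landing_frame"),
    dwell_s = vapply(ev_list, `[[`, 0, "dwell"),
    fusion_start_s = vapply(ev_list, `[[`, 0, "fusion_start"),
    fusion_frame = vapply(ev_list, `[[`, 0L, "fusion_frame"),
    a = vapply(ev_list, `[[`, 0, "a"),
    n = vapply(ev_list, `[[`, 0, "n"),
    t_off = vapply(ev_list, `[[`, 0, "t_off"),
    pre_landing_D = vapply(ev_list, `[[`, 0, "pre_landing_D"),
    footprint_growth = vapply(ev_list, `[[`, 0, "footprint_growth")
  ) else data.frame()
  paths <- lapply(ev_list, function(e) {
    if (nrow(e$path) == 0) return(data.frame())
    data.frame(frame = seq_len(nrow(e$path)), x_um = e$path[, 1],
               y_um = e$path[, 2])
  })
  structure(list(frames = frames, scene = scene, truth = truth,
                 paths = paths),
            class = "tirf_movie")
}

#' @export
print.tirf_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Synthetic TIRF movie: %d x %d px, %d frames, %d events\n",
              d[1], d[2], d[3], nrow(x$truth)))
  print(x$scene)
  invisible(x)
}
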