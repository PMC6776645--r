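# TIFF stack I/O, YAML run configuration and the pipeline driver.
# All coordinates in output tables are pixel-centred, origin top-left,
# x = column index, physical units um; times are seconds from the first
# frame, with the frame index also emitted.

#' Write a multi-frame 16-bit grayscale TIFF stack
#'
#' Counts are rounded to integers and stored as 16-bit samples, so a
#' [read_stack()] round trip restores integer count frames
#' bit-identically. The calibration (`pixel_size_um`,
#' `frame_interval_s`) travels in a YAML sidecar `<path>.meta.yaml`
#' next to the stack (the linked TIFF library does not expose the
#' description tag on write).
#'
#' @param frames `ny x nx x nf` array of counts in `[0, 65535]`.
#' @param path output file.
#' @param pixel_size um/px.
#' @param frame_interval s.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, pixel_size = 0.16,
                        frame_interval = 0.03) {
  if (inherits(frames, "tirf_movie")) {
    pixel_size <- frames$scene$pixel_size
    frame_interval <- frames$scene$frame_interval
    frames <- frames$frames
  }
  stopifnot(length(dim(frames)) == 3)
  if (max(frames) > 65535 || min(frames) < 0)
    stop("counts must lie in [0, 65535] for 16-bit storage")
  pages <- lapply(seq_len(dim(frames)[3]), function(f)
    round(frames[, , f]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16,
                  compression = "none", reduce = FALSE)
  yaml::write_yaml(list(pixel_size_um = pixel_size,
                        frame_interval_s = frame_interval,
                        n_frames = dim(frames)[3], unit = "um"),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a multi-frame grayscale TIFF stack
#'
#' Frames are returned in acquisition order as counts. Calibration is
#' taken from the YAML sidecar written by [write_stack()], or from the
#' TIFF description tag when one carries `pixel_size_um=` /
#' `frame_interval_s=` entries; when neither exists, `pixel_size` and
#' `frame_interval` must be supplied (a notice is logged that
#' configuration values were used).
#'
#' @param path TIFF file (8/16-bit grayscale, multi-page).
#' @param pixel_size,frame_interval fallback calibration when the file
#'   has no embedded metadata.
#' @return List with `frames` (`ny x nx x nf` counts array),
#'   `pixel_size`, `frame_interval`.
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop("unreadable TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!length(pages)) stop("TIFF '", path, "' contains no frames")
  if (length(dim(pages[[1]])) == 3)
    stop("RGB input; expected 8/16-bit grayscale frames")
  meta_px <- meta_dt <- NULL
  sidecar <- paste0(path, ".meta.yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    meta_px <- meta$pixel_size_um
    meta_dt <- meta$frame_interval_s
  }
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && is.null(meta_px)) {
    m <- regmatches(desc, regexec("pixel_size_um=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2) meta_px <- as.numeric(m[2])
    m <- regmatches(desc, regexec("frame_interval_s=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2) meta_dt <- as.numeric(m[2])
  }
  if (is.null(meta_px)) {
    if (is.null(pixel_size))
      stop("TIFF has no pixel-size metadata; supply 'pixel_size'")
    message("pixel size not in TIFF metadata; using configured value ",
            pixel_size, " um/px")
    meta_px <- pixel_size
  }
  if (is.null(meta_dt)) {
    if (is.null(frame_interval))
      stop("TIFF has no frame-interval metadata; supply 'frame_interval'")
    message("frame interval not in TIFF metadata; using configured value ",
            frame_interval, " s")
    meta_dt <- frame_interval
  }
  d1 <- dim(pages[[1]])
  frames <- array(0, dim = c(d1[1], d1[2], length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]] * 65535
  frames <- round(frames)
  list(frames = frames, pixel_size = meta_px, frame_interval = meta_dt)
}

default_config <- function() {
  list(
    input = NULL, out_dir = "cubofuse_out", seed = 1L,
    pixel_size = 0.16, frame_interval = 0.03, condition = "default",
    simulate = list(dim = c(128L, 128L), n_frames = 300L,
                    background_level = 100, read_sigma = 2, gain = 1,
                    n_events = 20L, exponent = 1 / 6,
                    mean_size_nm = 200, sigma_log = 0.3,
                    mean_peak_snr = 10, dwell_frames = 15L,
                    noise = TRUE),
    detection = list(diameter_px = 7L, min_mass = 0, threshold = NA),
    linking = list(max_disp_px = 8, memory = 2L),
    events = list(aperture_px = 4, immobility_radius_px = 2,
                  min_peak_snr = 5, noise_floor_k = 2, k_sigma = 2),
    coverage = list(threshold = NA, connectivity = 8L, min_area = 4L)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", paste0(path, k))
    if (is.list(base[[k]]) && !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], as.list(user[[k]]),
                                paste0(path, k, "."))
    else base[[k]] <- user[[k]]
  }
  base
}

#' Load and materialise a pipeline run configuration
#'
#' Reads a YAML configuration (or takes a list), validates it against
#' the known schema — unknown keys are rejected — and fills every
#' missing field with its default, so the returned object is the
#' complete, reproducible description of a run. [run_pipeline()] echoes
#' it into the output directory for provenance.
#'
#' @param config path to a YAML file, a list, or `NULL` (defaults only).
#' @param overrides named list applied on top, dotted keys allowed
#'   (e.g. `list("linking.max_disp_px" = 10)`).
#' @return The materialised configuration list (class `run_config`).
#' @export
run_config <- function(config = NULL, overrides = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else if (is.list(config)) config
  else stop("'config' must be a YAML path or a list")
  cfg <- merge_config(default_config(), user)
  for (k in names(overrides)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      cfg <- merge_config(cfg, stats::setNames(list(overrides[[k]]), k))
    } else {
      blk <- stats::setNames(list(stats::setNames(list(overrides[[k]]),
                                                  parts[2])), parts[1])
      cfg <- merge_config(cfg, blk)
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

write_csv_ <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

simulate_stage <- function(cfg, out) {
  s <- cfg$simulate
  noise_sd <- sqrt(s$background_level + s$read_sigma^2)
  sc <- tirf_scene(dim = s$dim, pixel_size = cfg$pixel_size,
                   frame_interval = cfg$frame_interval,
                   n_frames = s$n_frames,
                   background_level = s$background_level,
                   gain = s$gain, read_sigma = s$read_sigma,
                   seed = cfg$seed)
  sizes <- sample_size_distribution(s$mean_size_nm, s$sigma_log,
                                    n = s$n_events, seed = cfg$seed)
  set.seed(cfg$seed + 7L)
  ncol_g <- ceiling(sqrt(s$n_events))
  nrow_g <- ceiling(s$n_events / ncol_g)
  cw <- s$dim[2] / ncol_g; ch <- s$dim[1] / nrow_g
  evs <- lapply(seq_len(s$n_events), function(k) {
    gi <- (k - 1) %/% ncol_g; gj <- (k - 1) %% ncol_g
    pos <- c((gj * cw + cw / 2 + stats::runif(1, -2, 2)) * cfg$pixel_size,
             (gi * ch + ch / 2 + stats::runif(1, -2, 2)) * cfg$pixel_size)
    peak <- s$mean_peak_snr * noise_sd * sizes[k] / s$mean_size_nm
    tirf_event(landing_time = sample(10:40, 1) * cfg$frame_interval,
               position = pos,
               a = amplitude_for_peak(peak, s$exponent,
                                      cfg$frame_interval),
               n = s$exponent, dwell = s$dwell_frames * cfg$frame_interval,
               pre_landing_D = stokes_einstein_D(sizes[k]))
  })
  movie <- render_movie(sc, evs, noise = isTRUE(s$noise))
  tif <- file.path(out, "movie.tif")
  write_stack(movie, tif)
  write_csv_(movie$truth, file.path(out, "ground_truth.csv"))
  movie
}

track_stage <- function(cfg, out, frames) {
  det <- cfg$detection; lnk <- cfg$linking
  thr <- if (is.na(det$threshold)) NULL else det$threshold
  tracks <- track_movie(frames, pixel_size = cfg$pixel_size,
                        frame_interval = cfg$frame_interval,
                        diameter_px = det$diameter_px,
                        min_mass = det$min_mass, threshold = thr,
                        max_disp_px = lnk$max_disp_px,
                        memory = lnk$memory)
  write_csv_(tracks[, c("track_id", "frame", "t_s", "x_um", "y_um",
                        "mass", "peak")],
             file.path(out, "tracks.csv"))
  ids <- unique(tracks$track_id)
  msd_rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    if (nrow(tr) < 10) return(NULL)
    m <- compute_msd(tr, frame_interval = cfg$frame_interval)
    data.frame(track_id = id, n_points = nrow(tr),
               D_um2_s = m$D_um2_s, diameter_nm = m$diameter_nm,
               r_squared = m$r_squared)
  })
  msd <- do.call(rbind, msd_rows)
  if (!is.null(msd)) write_csv_(msd, file.path(out, "msd.csv"))
  tracks
}

fuse_stage <- function(cfg, out, frames, tracks) {
  ev <- cfg$events
  segs <- segment_events(tracks, frames,
                         immobility_radius_px = ev$immobility_radius_px,
                         min_peak_snr = ev$min_peak_snr,
                         aperture_px = ev$aperture_px,
                         condition = cfg$condition,
                         pixel_size = cfg$pixel_size,
                         frame_interval = cfg$frame_interval)
  df <- fit_events(segs, noise_floor_k = ev$noise_floor_k,
                   k_sigma = ev$k_sigma)
  write_csv_(df, file.path(out, "events.csv"))
  if (nrow(df)) {
    summ <- aggregate_events(df)
    jsonlite::write_json(as.data.frame(summ),
                         file.path(out, "summaries.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  df
}

coverage_stage <- function(cfg, out, frames) {
  cv <- cfg$coverage
  thr <- if (is.na(cv$threshold)) "otsu" else cv$threshold
  curve <- coverage_curve(frames, threshold = thr,
                          frame_interval = cfg$frame_interval)
  write_csv_(as.data.frame(curve)[, c("t_s", "theta")],
             file.path(out, "coverage.csv"))
  dom <- domain_count_series(frames, attr(curve, "threshold"),
                             connectivity = cv$connectivity,
                             min_area = cv$min_area,
                             frame_interval = cfg$frame_interval)
  write_csv_(dom, file.path(out, "domains.csv"))
  fit <- tryCatch(fit_erf_growth(curve), error = function(e) NULL)
  if (!is.null(fit))
    jsonlite::write_json(list(theta_max = fit$theta_max, t_c = fit$t_c,
                              tau = fit$tau, max_slope = fit$max_slope,
                              r_squared = fit$r_squared,
                              flagged = fit$flagged),
                         file.path(out, "coverage_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  curve
}

#' Run the analysis pipeline
#'
#' Executes one stage (or all of them) against a configuration,
#' writing versioned artifacts and a MANIFEST into the output
#' directory. `"simulate"` renders a synthetic movie (TIFF + ground
#' truth); `"track"` detects and links spots (tracks + MSD tables);
#' `"fuse"` segments and fits fusion events (event table + summaries);
#' `"coverage"` computes bilayer-formation kinetics; `"model-check"`
#' runs the analytic scaling oracles of the fusion model; `"all"` runs
#' simulate, track and fuse in sequence. Any stage failure leaves the
#' artifacts produced so far in place, with the MANIFEST marking the
#' run incomplete.
#'
#' @param config configuration (path, list or [run_config()] result).
#' @param command one of `"simulate"`, `"track"`, `"fuse"`,
#'   `"coverage"`, `"model-check"`, `"all"`.
#' @param out_dir output directory (overrides the configured one).
#' @param overrides passed to [run_config()].
#' @return Invisibly, a list with the stage results; the MANIFEST and
#'   artifact files are the primary output.
#' @export
run_pipeline <- function(config = NULL,
                         command = c("simulate", "track", "fuse",
                                     "coverage", "model-check", "all"),
                         out_dir = NULL, overrides = NULL) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "run_config")) config
  else run_config(config, overrides)
  out <- if (is.null(out_dir)) cfg$out_dir else out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out, "config_echo.yaml"))
  artifacts <- list()
  status <- "complete"
  res <- tryCatch({
    frames <- NULL; tracks <- NULL
    load_input <- function() {
      if (is.null(cfg$input)) stop("'input' TIFF required for this command")
      st <- read_stack(cfg$input, cfg$pixel_size, cfg$frame_interval)
      cfg$pixel_size <<- st$pixel_size
      cfg$frame_interval <<- st$frame_interval
      st$frames
    }
    if (command %in% c("simulate", "all")) {
      movie <- simulate_stage(cfg, out)
      artifacts$movie <- movie
      frames <- movie$frames
    }
    if (command %in% c("track", "all")) {
      if (is.null(frames)) frames <- load_input()
      tracks <- track_stage(cfg, out, frames)
      artifacts$tracks <- tracks
    }
    if (command %in% c("fuse", "all")) {
      if (is.null(frames)) frames <- load_input()
      if (is.null(tracks)) {
        tp <- file.path(out, "tracks.csv")
        if (file.exists(tp)) tracks <- utils::read.csv(tp)
        else tracks <- track_stage(cfg, out, frames)
        if (!"x_px" %in% names(tracks)) {
          tracks$x_px <- tracks$x_um / cfg$pixel_size
          tracks$y_px <- tracks$y_um / cfg$pixel_size
        }
      }
      artifacts$events <- fuse_stage(cfg, out, frames, tracks)
    }
    if (command == "coverage") {
      frames <- load_input()
      artifacts$coverage <- coverage_stage(cfg, out, frames)
    }
    if (command == "model-check") {
      chk <- model_check()
      print(chk)
      jsonlite::write_json(chk, file.path(out, "model_check.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts$model_check <- chk
    }
    artifacts
  }, error = function(e) {
    status <<- paste("INCOMPLETE:", conditionMessage(e))
    e
  })
  writeLines(c(sprintf("command: %s", command),
               sprintf("status: %s", status),
               sprintf("seed: %s", cfg$seed),
               "artifacts:",
               paste(" ", list.files(out))),
             file.path(out, "MANIFEST"))
  if (inherits(res, "error")) stop(res)
  invisible(res)
}

#' Export a model trajectory as CSV
#'
#' Writes the columns `t_s`, `R_m`, `L_m`, `delta_c`, `I_max`.
#'
#' @param trajectory a `model_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "model_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
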