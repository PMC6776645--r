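# Supported-lipid-bilayer formation kinetics: surface coverage, an
# error-function growth fit, domain counting and a nucleation-and-growth
# simulator used as the testing oracle.

#' Surface-coverage curve of a forming bilayer
#'
#' Per-frame fraction of pixels whose intensity exceeds a binarization
#' threshold. The threshold is either fixed (counts) or derived once for
#' the whole stack by Otsu's method on the pooled first/middle/last
#' frames, so the same cut applies to every frame.
#'
#' @param movie `ny x nx x nf` array or `tirf_movie`.
#' @param threshold `"otsu"` (default) or a fixed numeric threshold in
#'   counts.
#' @param frame_interval s per frame (from the movie's scene when
#'   available).
#' @return Object of class `coverage_curve`: data frame `t_s`, `theta`,
#'   with the threshold in `attr(, "threshold")`.
#' @export
coverage_curve <- function(movie, threshold = "otsu",
                           frame_interval = 1) {
  if (inherits(movie, "tirf_movie")) {
    frame_interval <- movie$scene$frame_interval
    movie <- movie$frames
  }
  if (inherits(movie, "nucleation_sim")) {
    frame_interval <- movie$frame_interval
    movie <- movie$frames
  }
  nf <- dim(movie)[3]
  if (identical(threshold, "otsu")) {
    pool <- movie[, , unique(c(1L, (nf + 1L) %/% 2L, nf))]
    rng <- range(pool)
    if (diff(rng) == 0) {
      threshold <- rng[1] + 1  # flat movie: nothing above threshold
    } else {
      img <- EBImage::Image(matrix((pool - rng[1]) / diff(rng),
                                   ncol = 1))
      threshold <- rng[1] +
        EBImage::otsu(img, range = c(0, 1)) * diff(rng)
    }
  }
  theta <- vapply(seq_len(nf), function(f) mean(movie[, , f] > threshold),
                  numeric(1))
  structure(data.frame(t_s = (seq_len(nf) - 1) * frame_interval,
                       theta = theta),
            class = c("coverage_curve", "data.frame"),
            threshold = threshold)
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Error-function fit of sigmoidal coverage growth
#'
#' Least-squares fit of
#' `theta(t) = (theta_max / 2) * (1 + erf((t - t_c) / (sqrt(2) tau)))`
#' to a coverage curve (equivalently `theta_max * pnorm((t - t_c)/tau)`),
#' by Levenberg-Marquardt (`minpack.lm::nlsLM`). The fitted gradient is
#' the Gaussian derivative with peak `theta_max / (tau sqrt(2 pi))` at
#' `t_c`. Clearly non-sigmoidal data (R^2 < 0.5) are fitted anyway but
#' flagged.
#'
#' @param curve a [coverage_curve()] or data frame with `t_s`, `theta`.
#' @return Object of class `erf_growth_fit`: `theta_max`, `t_c`, `tau`,
#'   `max_slope`, `r_squared`, `flagged`, plus the data. Supports
#'   `print`, `coef`, `predict` (with `deriv = TRUE` for the gradient),
#'   `residuals` and `plot`.
#' @export
fit_erf_growth <- function(curve) {
  t <- curve$t_s; th <- curve$theta
  stopifnot(length(t) >= 5)
  th_max0 <- max(th)
  if (th_max0 <= 0) stop("coverage never rises above zero")
  half <- which(th >= th_max0 / 2)[1]
  tc0 <- t[half]
  q16 <- t[which(th >= 0.16 * th_max0)[1]]
  q84 <- t[which(th >= 0.84 * th_max0)[1]]
  tau0 <- max((q84 - q16) / 2, diff(range(t)) / 50)
  fit <- minpack.lm::nlsLM(
    th ~ theta_max * pnorm((t - t_c) / tau),
    start = list(theta_max = th_max0, t_c = tc0, tau = tau0),
    lower = c(1e-6, -Inf, 1e-9), upper = c(1, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  pred <- stats::predict(fit)
  ss_tot <- sum((th - mean(th))^2)
  r2 <- if (ss_tot > 0) 1 - sum((th - pred)^2) / ss_tot else 1
  flagged <- r2 < 0.5
  if (flagged)
    warning("coverage data look non-sigmoidal (R^2 < 0.5); fit flagged")
  structure(list(theta_max = unname(cf["theta_max"]),
                 t_c = unname(cf["t_c"]), tau = unname(cf["tau"]),
                 max_slope = unname(cf["theta_max"] /
                                      (cf["tau"] * sqrt(2 * pi))),
                 r_squared = r2, flagged = flagged, t_s = t, theta = th),
            class = "erf_growth_fit")
}

#' @export
print.erf_growth_fit <- function(x, ...) {
  cat("Error-function coverage growth fit\n")
  cat(sprintf("  theta_max = %.4g, t_c = %.4g s, tau = %.4g s\n",
              x$theta_max, x$t_c, x$tau))
  cat(sprintf("  max growth rate %.4g /s at t_c; R^2 = %.4f%s\n",
              x$max_slope, x$r_squared,
              if (x$flagged) "  [flagged: non-sigmoidal]" else ""))
  invisible(x)
}

#' @export
coef.erf_growth_fit <- function(object, ...) {
  c(theta_max = object$theta_max, t_c = object$t_c, tau = object$tau)
}

#' @export
#' @rdname fit_erf_growth
#' @param object,times,deriv `predict` arguments: evaluation times and
#'   whether to return the fitted gradient instead of the coverage.
#' @param ... unused.
predict.erf_growth_fit <- function(object, times = object$t_s,
                                   deriv = FALSE, ...) {
  z <- (times - object$t_c) / object$tau
  if (deriv) object$theta_max * stats::dnorm(z) / object$tau
  else object$theta_max * stats::pnorm(z)
}

#' @export
residuals.erf_growth_fit <- function(object, ...) {
  object$theta - predict(object)
}

#' @export
plot.erf_growth_fit <- function(x, ...) {
  graphics::plot(x$t_s, x$theta, xlab = "t (s)", ylab = "coverage", ...)
  graphics::lines(x$t_s, predict(x), lty = 2)
  graphics::lines(x$t_s, predict(x, deriv = TRUE) /
                    max(predict(x, deriv = TRUE)) * x$theta_max * 0.5,
                  col = 2)
  invisible(x)
}

# Connected-component labelling by iterative minimum-label propagation;
# vectorised, supports 4- and 8-connectivity.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0, ny, nx)
  lab[mask] <- seq_len(sum(mask))
  shifts <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    old <- lab
    for (s in shifts) {
      sh <- matrix(Inf, ny, nx)
      ri <- max(1, 1 + s[1]):min(ny, ny + s[1])
      rj <- max(1, 1 + s[2]):min(nx, nx + s[2])
      sh[ri, rj] <- lab[ri - s[1], rj - s[2]]
      sh[sh == 0] <- Inf
      upd <- mask & sh < lab
      lab[upd] <- sh[upd]
    }
    if (identical(lab, old)) break
  }
  # relabel 1..k
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

#' Count bilayer domains in a frame
#'
#' Number of connected components of the above-threshold mask, under
#' 4- or 8-connectivity, after removing components smaller than
#' `min_area` pixels (shot-noise suppression).
#'
#' @param frame numeric matrix (counts).
#' @param threshold binarization threshold (counts).
#' @param connectivity 4 or 8.
#' @param min_area minimum component area in px (default 4).
#' @return Integer domain count.
#' @export
count_domains <- function(frame, threshold, connectivity = 8,
                          min_area = 4) {
  mask <- frame > threshold
  if (!any(mask)) return(0L)
  lab <- label_components(mask, connectivity)
  areas <- tabulate(lab[lab > 0])
  sum(areas >= min_area)
}

#' Domain-count trajectory of a movie
#'
#' @inheritParams coverage_curve
#' @inheritParams count_domains
#' @return Data frame `t_s`, `count`.
#' @export
domain_count_series <- function(movie, threshold, connectivity = 8,
                                min_area = 4, frame_interval = 1) {
  if (inherits(movie, "nucleation_sim")) {
    frame_interval <- movie$frame_interval
    movie <- movie$frames
  }
  nf <- dim(movie)[3]
  data.frame(t_s = (seq_len(nf) - 1) * frame_interval,
             count = vapply(seq_len(nf), function(f)
               count_domains(movie[, , f], threshold, connectivity,
                             min_area), integer(1)))
}

#' Nucleation-and-growth bilayer formation simulator
#'
#' Bilayer domains nucleate as a Poisson process in space and time and
#' grow radially at constant speed, merging on contact — the classic
#' Avrami picture whose coverage follows a sigmoid. Frames render
#' uncovered substrate at `glass_level` and covered bilayer at
#' `bilayer_level` counts. The event log records every nucleation and,
#' analytically, every pairwise first-contact (merge) time.
#'
#' @param rate nucleation rate (nuclei / (s um^2)).
#' @param growth_speed radial growth speed (um/s).
#' @param dim frame shape (px).
#' @param pixel_size um/px.
#' @param frame_interval s.
#' @param n_frames movie length.
#' @param glass_level,bilayer_level counts of bare and covered pixels.
#' @param seed integer seed.
#' @return Object of class `nucleation_sim`: `frames`, `nuclei`
#'   (data frame `t_s`, `x_um`, `y_um`), `merges` (data frame `i`, `j`,
#'   `t_s` of first contact), `frame_interval`, `pixel_size`.
#' @export
simulate_nucleation_growth <- function(rate, growth_speed,
                                       dim = c(96L, 96L),
                                       pixel_size = 0.16,
                                       frame_interval = 1,
                                       n_frames = 100L,
                                       glass_level = 10,
                                       bilayer_level = 100,
                                       seed = 1L) {
  stopifnot(rate > 0, growth_speed > 0)
  set.seed(seed)
  w_um <- dim[2] * pixel_size; h_um <- dim[1] * pixel_size
  duration <- (n_frames - 1) * frame_interval
  n_nuc <- max(1L, stats::rpois(1, rate * w_um * h_um * duration))
  nuc <- data.frame(t_s = sort(stats::runif(n_nuc, 0, 0.8 * duration)),
                    x_um = stats::runif(n_nuc, 0, w_um),
                    y_um = stats::runif(n_nuc, 0, h_um))
  # analytic merge log: pairwise first contact is when the sum of the
  # radii reaches the separation (or the younger birth, if born inside
  # an existing domain); union-find over contact times keeps only the
  # events that actually join two distinct clusters
  merges <- NULL
  if (n_nuc > 1) {
    pr <- utils::combn(n_nuc, 2)
    d <- sqrt((nuc$x_um[pr[1, ]] - nuc$x_um[pr[2, ]])^2 +
                (nuc$y_um[pr[1, ]] - nuc$y_um[pr[2, ]])^2)
    tm <- pmax((d / growth_speed + nuc$t_s[pr[1, ]] +
                  nuc$t_s[pr[2, ]]) / 2,
               pmax(nuc$t_s[pr[1, ]], nuc$t_s[pr[2, ]]))
    o <- order(tm)
    parent <- seq_len(n_nuc)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep_i <- keep_j <- integer(0); keep_t <- numeric(0)
    for (k in o) {
      if (tm[k] > duration) break
      ri <- find(pr[1, k]); rj <- find(pr[2, k])
      if (ri != rj) {
        parent[ri] <- rj
        keep_i <- c(keep_i, pr[1, k]); keep_j <- c(keep_j, pr[2, k])
        keep_t <- c(keep_t, tm[k])
      }
    }
    merges <- data.frame(i = keep_i, j = keep_j, t_s = keep_t)
  }
  xs <- (seq_len(dim[2]) - 0.5) * pixel_size
  ys <- (seq_len(dim[1]) - 0.5) * pixel_size
  # per-nucleus squared distance field, reused across frames
  d2 <- lapply(seq_len(n_nuc), function(k)
    outer((ys - nuc$y_um[k])^2, (xs - nuc$x_um[k])^2, "+"))
  frames <- array(glass_level, dim = c(dim[1], dim[2], n_frames))
  for (f in seq_len(n_frames)) {
    t <- (f - 1) * frame_interval
    covered <- matrix(FALSE, dim[1], dim[2])
    for (k in seq_len(n_nuc)) {
      r <- growth_speed * (t - nuc$t_s[k])
      if (r > 0) covered <- covered | (d2[[k]] <= r^2)
    }
    fr <- frames[, , f]
    fr[covered] <- bilayer_level
    frames[, , f] <- fr
  }
  structure(list(frames = frames, nuclei = nuc, merges = merges,
                 frame_interval = frame_interval,
                 pixel_size = pixel_size),
            class = "nucleation_sim")
}

#' @export
print.nucleation_sim <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(paste0("Nucleation-growth simulation: %d x %d px, %d ",
                     "frames, %d nuclei, %d merges\n"),
              d[1], d[2], d[3], nrow(x$nuclei),
              if (is.null(x$merges)) 0L else nrow(x$merges)))
  invisible(x)
}
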