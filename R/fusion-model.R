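#' @useDynLib cubofuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Physical parameters of the finite-source fusion model
#'
#' Bundles the physical constants of the mass-transfer model for a single
#' lipid nanoparticle (cubosome) fusing into a supported lipid bilayer.
#' The particle of side length `R` sheds lipid into the bilayer of height
#' `h`; transport in the bilayer is diffusive with coefficient `D`, driven
#' by the lateral concentration gradient `delta_c` across the expanding
#' fluorescent footprint of diameter `L`.
#'
#' The driving gradient is modelled as
#' `delta_c(t) = (c_max(t) - c_edge) / (L(t)/2)` with `c_max = c_amp / t`
#' (2-D point-source peak decay), `c_edge = 0` (no lipid outside the
#' footprint) and `L = l_amp * sqrt(t)` (diffusive footprint growth),
#' giving `delta_c = 2 c_amp / l_amp * t^(-3/2)`.
#'
#' The `t^(-3/2)` law diverges at `t = 0`, so all model evaluations start
#' at a regularisation time `t_start > 0` (by convention one frame
#' interval of the acquisition).
#'
#' @param R0 initial particle side length (m).
#' @param D lipid diffusion coefficient in the bilayer (m^2/s).
#' @param h bilayer height (m).
#' @param rho particle lipid mass density (kg/m^3).
#' @param t_start regularisation start time (s), strictly positive.
#' @param c_amp amplitude A of the peak concentration law `c_max = A/t`.
#' @param l_amp amplitude B of the footprint law `L = B*sqrt(t)`.
#' @param i_coef proportionality between predicted peak intensity and `R`
#'   (`I_max = i_coef * R`); intensity is reported in arbitrary units.
#'
#' @return An object of class `fusion_model_params`.
#' @examples
#' p <- fusion_model_params(R0 = 2e-7, D = 5e-12, h = 5e-9, rho = 1e3)
#' p
#' @export
fusion_model_params <- function(R0 = 2e-7, D = 5e-12, h = 5e-9, rho = 1e3,
                                t_start = 0.03, c_amp = 1, l_amp = 1,
                                i_coef = 1) {
  vals <- c(R0 = R0, D = D, h = h, rho = rho, t_start = t_start,
            c_amp = c_amp, l_amp = l_amp, i_coef = i_coef)
  if (!all(is.finite(vals)))
    stop("all model parameters must be finite numbers")
  if (D < 0) stop("'D' must be non-negative")
  pos <- vals[c("R0", "h", "rho", "t_start", "c_amp", "l_amp", "i_coef")]
  if (any(pos <= 0))
    stop("'", names(pos)[which(pos <= 0)[1L]], "' must be strictly positive")
  structure(as.list(vals), class = "fusion_model_params")
}

#' @export
print.fusion_model_params <- function(x, ...) {
  cat("Finite-source bilayer fusion model parameters\n")
  cat(sprintf("  R0 = %.4g m, D = %.4g m^2/s, h = %.4g m, rho = %.4g kg/m^3\n",
              x$R0, x$D, x$h, x$rho))
  cat(sprintf("  gradient law: delta_c = 2*%.4g/%.4g * t^(-3/2), t >= %.4g s\n",
              x$c_amp, x$l_amp, x$t_start))
  invisible(x)
}

# Lumped shrinkage constant C = 2 c_amp D h / (l_amp rho): with it the
# cube of the side length obeys d(R^3)/dt = -3 C t^(-3/2).
shrinkage_constant <- function(params) {
  2 * params$c_amp * params$D * params$h / (params$l_amp * params$rho)
}

#' Lateral concentration gradient driving fusion
#'
#' Evaluates the modelled concentration gradient
#' `delta_c(t) = (c_max - c_edge) / (L/2)` with `c_max = c_amp/t`,
#' `c_edge = 0` and `L = l_amp*sqrt(t)`, i.e.
#' `delta_c = (2 c_amp / l_amp) * t^(-3/2)`. Its log-log slope against
#' time is exactly -3/2.
#'
#' @param params a [fusion_model_params()] object.
#' @param times evaluation times (s); all must be `>= t_start`.
#' @return Numeric vector of `delta_c` values (arbitrary conc / m).
#' @examples
#' p <- fusion_model_params(c_amp = 1, l_amp = 2)
#' delta_c_profile(p, c(1, 4))  # 1, 1/8
#' @export
delta_c_profile <- function(params, times) {
  stopifnot(inherits(params, "fusion_model_params"))
  if (any(!is.finite(times)) || any(times <= 0))
    stop("'times' must be finite and strictly positive")
  if (any(times < params$t_start))
    stop("all 'times' must be >= t_start (the model is regularised there)")
  2 * params$c_amp / params$l_amp * times^(-1.5)
}

# Closed-form cube of the side length:
#   R^3(t) = R0^3 - 6 C (t_start^(-1/2) - t^(-1/2)),  clamped at 0.
# Serves as the analytic oracle for the numerical integrator.
shrinkage_closed_form <- function(params, times) {
  C <- shrinkage_constant(params)
  r3 <- params$R0^3 - 6 * C * (params$t_start^(-0.5) - times^(-0.5))
  pmax(r3, 0)^(1 / 3)
}

# Depletion time (R reaches 0), or Inf if the particle never empties.
depletion_time <- function(params) {
  C <- shrinkage_constant(params)
  if (C <= 0) return(Inf)
  a <- params$t_start^(-0.5) - params$R0^3 / (6 * C)
  if (a <= 0) Inf else a^(-2)
}

new_model_trajectory <- function(params, times, R, method) {
  out <- data.frame(
    t_s = times,
    R_m = R,
    L_m = params$l_amp * sqrt(times),
    delta_c = delta_c_profile(params, times),
    I_max = params$i_coef * R
  )
  structure(out, class = c("model_trajectory", "data.frame"),
            params = params, method = method)
}

#' @export
print.model_trajectory <- function(x, ...) {
  cat(sprintf("Model trajectory (%s), %d time points, t in [%.4g, %.4g] s\n",
              attr(x, "method"), nrow(x), min(x$t_s), max(x$t_s)))
  dep <- attr(x, "depletion_time")
  if (!is.null(dep) && is.finite(dep))
    cat(sprintf("  particle fully fused at t = %.4g s\n", dep))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Integrate the particle-shrinkage ODE
#'
#' Numerically integrates the mass-transfer balance
#' `rho R^2 dR/dt = -D h delta_c(t)` (the sign is chosen so the particle
#' sheds mass) from `R(times[1]) = R0`, using `deSolve::lsoda` with a root
#' event that clamps `R` at zero once the particle has fully fused. The
#' closed form `R^3(t) = R0^3 - 6C (t_start^(-1/2) - t^(-1/2))`,
#' `C = 2 c_amp D h / (l_amp rho)`, is the analytic solution the
#' integrator is validated against.
#'
#' @param params a [fusion_model_params()] object.
#' @param times strictly increasing output times (s), `times[1] >= t_start`.
#' @param rtol,atol solver tolerances passed to `deSolve::lsoda`.
#' @return A `model_trajectory` data frame with columns `t_s`, `R_m`,
#'   `L_m`, `delta_c`, `I_max`; the attribute `depletion_time` holds the
#'   time at which `R` reached zero (`Inf` if it never does).
#' @examples
#' p <- fusion_model_params(R0 = 2e-7, D = 5e-12, h = 5e-9, rho = 1e3)
#' tr <- integrate_shrinkage_ode(p, seq(0.03, 6, by = 0.03))
#' head(tr)
#' @export
integrate_shrinkage_ode <- function(params, times, rtol = 1e-10,
                                    atol = 0) {
  stopifnot(inherits(params, "fusion_model_params"))
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with at least two points")
  if (times[1] < params$t_start * (1 - 1e-9))
    stop("'times[1]' must be >= t_start")
  times[1] <- max(times[1], params$t_start)
  # integrate u = R^3: du/dt = -3 C t^(-3/2); linear in u, immune to the
  # dR/dt singularity as R -> 0, and still a genuine numerical quadrature
  # cross-checked against the closed form.
  C <- shrinkage_constant(params)
  if (atol <= 0) atol <- 1e-12 * params$R0^3
  deriv <- function(t, u, p) list(-3 * C * t^(-1.5))
  sol <- deSolve::lsodar(
    y = c(u = params$R0^3), times = times, func = deriv, parms = NULL,
    rtol = rtol, atol = atol,
    rootfunc = function(t, u, p) u
  )
  if (attr(sol, "istate")[1L] < 0)
    stop("shrinkage ODE integration failed (lsoda istate = ",
         attr(sol, "istate")[1L], "); check parameter magnitudes")
  u <- rep(0, length(times))
  got <- match(round(sol[, "time"], 12), round(times, 12))
  u[got[!is.na(got)]] <- sol[!is.na(got), "u"]
  R <- pmax(u, 0)^(1 / 3)
  tr <- new_model_trajectory(params, times, R, method = "lsoda")
  attr(tr, "depletion_time") <- depletion_time(params)
  tr
}

#' Self-similar power-law branch of the fusion model
#'
#' Returns the exact self-similar solution of the shrinkage ODE, the
#' branch on which the constant terms of the integrated law cancel:
#' `R(t) = (6C)^(1/3) t^(-1/6)` with `C = 2 c_amp D h / (l_amp rho)`, and
#' hence a predicted peak intensity `I_max = i_coef R` proportional to
#' `(D h / rho)^(1/3) t^(-1/6)`. Fitting `I = a t^(-n)` to this branch
#' recovers the model's hallmark exponent `n = 1/6`.
#'
#' @inheritParams integrate_shrinkage_ode
#' @return A `model_trajectory` data frame (see
#'   [integrate_shrinkage_ode()]). The `R0` field of `params` is ignored:
#'   the branch fixes `R(t_start)` to the self-similar value.
#' @examples
#' p <- fusion_model_params(D = 5e-12, h = 5e-9, rho = 1e3)
#' tr <- power_law_branch(p, seq(0.03, 6, by = 0.03))
#' @export
power_law_branch <- function(params, times) {
  stopifnot(inherits(params, "fusion_model_params"))
  if (any(times < params$t_start))
    stop("all 'times' must be >= t_start")
  C <- shrinkage_constant(params)
  R <- (6 * C)^(1 / 3) * times^(-1 / 6)
  new_model_trajectory(params, times, R, method = "self-similar")
}

#' Explicit 2-D diffusion of an instantaneous point release
#'
#' Solves `dc/dt = D laplacian(c)` on a square grid with zero-flux
#' boundaries from a single-cell release of mass `M`, by explicit finite
#' differences (FTCS, compiled). This is the brute-force oracle behind
#' the `c_max ~ 1/t` peak-decay law of a 2-D point source: the peak of
#' the solution matches the free-space Green's function
#' `c_max(t) = M / (4 pi D t)` once the release has spread over a few
#' cells and before it feels the boundary.
#'
#' @param D diffusion coefficient (grid units^2 / s).
#' @param M released mass (arbitrary units).
#' @param grid_n grid side length in cells.
#' @param dx grid spacing (grid units).
#' @param times strictly increasing save times (s).
#' @param dt explicit time step; defaults to 90% of the stability limit
#'   `dx^2/(4D)`. A `dt` above the limit is a configuration error.
#' @param keep_fields if `TRUE` (default) the full concentration field at
#'   every save time is retained (needed by [footprint_diameter()]).
#' @return An object of class `diffusion_field`: list with `dx`, `times`,
#'   `c_max` (peak value per save time), `mass` (total mass per save
#'   time), `M`, `D` and, if kept, `fields` (list of matrices).
#' @examples
#' f <- simulate_point_release_2d(D = 1, M = 1, grid_n = 101, dx = 1,
#'                                times = c(4, 8, 16))
#' f$c_max * 4 * pi * f$times  # ~ 1 once spread over a few cells
#' @export
simulate_point_release_2d <- function(D, M, grid_n = 256, dx = 1,
                                      times, dt = NULL,
                                      keep_fields = TRUE) {
  if (D <= 0 || M <= 0 || grid_n < 5) stop("need D > 0, M > 0, grid_n >= 5")
  if (any(diff(times) <= 0) || any(times <= 0))
    stop("'times' must be positive and strictly increasing")
  dt_max <- dx^2 / (4 * D)
  if (is.null(dt)) dt <- 0.9 * dt_max
  if (dt > dt_max)
    stop(sprintf(paste0("explicit step dt = %g violates the CFL stability",
                        " limit dx^2/(4D) = %g; choose a smaller step"),
                 dt, dt_max))
  con <- matrix(0, grid_n, grid_n)
  ctr <- (grid_n + 1) %/% 2
  con[ctr, ctr] <- M / dx^2
  # march save-point to save-point with an integer number of equal steps
  c_max <- mass <- numeric(length(times))
  fields <- if (keep_fields) vector("list", length(times)) else NULL
  t_now <- 0
  for (k in seq_along(times)) {
    span <- times[k] - t_now
    nstep <- max(1L, as.integer(ceiling(span / dt)))
    con <- .diffuse_steps_cpp(con, D, dx, span / nstep, nstep)
    t_now <- times[k]
    c_max[k] <- max(con)
    mass[k] <- sum(con) * dx^2
    if (keep_fields) fields[[k]] <- con
  }
  structure(list(dx = dx, times = times, c_max = c_max, mass = mass,
                 M = M, D = D, fields = fields),
            class = "diffusion_field")
}

#' @export
print.diffusion_field <- function(x, ...) {
  cat(sprintf("2-D point-release diffusion field: D = %g, M = %g, dx = %g\n",
              x$D, x$M, x$dx))
  cat(sprintf("  %d save times in [%.4g, %.4g] s; peak %.4g -> %.4g\n",
              length(x$times), min(x$times), max(x$times),
              x$c_max[1], x$c_max[length(x$c_max)]))
  invisible(x)
}

#' Footprint diameter of a spreading release
#'
#' For each saved time of a [simulate_point_release_2d()] field, measures
#' the diameter of the region where the concentration is at least
#' `threshold_fraction` of the instantaneous peak, as the equivalent-area
#' diameter `2 sqrt(area / pi)`. For a Gaussian point-release profile the
#' closed form is `L = 4 sqrt(D t ln(1/f))` (so `L = 4 sqrt(D t ln 2)` at
#' half maximum), growing as `sqrt(t)`.
#'
#' @param field a `diffusion_field` with retained fields.
#' @param threshold_fraction fraction of the peak defining the footprint,
#'   in (0, 1).
#' @return Numeric vector of footprint diameters (grid units), one per
#'   save time. An empty region yields 0 with a warning.
#' @export
footprint_diameter <- function(field, threshold_fraction = 0.5) {
  stopifnot(inherits(field, "diffusion_field"))
  if (is.null(field$fields))
    stop("field was simulated with keep_fields = FALSE")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must be in (0, 1)")
  L <- vapply(seq_along(field$times), function(k) {
    con <- field$fields[[k]]
    area <- sum(con >= threshold_fraction * max(con)) * field$dx^2
    2 * sqrt(area / pi)
  }, numeric(1))
  if (any(L == 0))
    warning("threshold produced an empty footprint at some times")
  L
}

#' Fit a power-law exponent on log-log axes
#'
#' Ordinary least squares of `log(y)` on `log(t)`; returns the slope.
#' Used throughout for scaling-law checks (`c_max ~ t^-1`,
#' `delta_c ~ t^-3/2`, `I_max ~ t^-1/6`).
#'
#' @param t,y positive numeric vectors of equal length.
#' @return The fitted log-log slope (a single number).
#' @export
loglog_slope <- function(t, y) {
  ok <- is.finite(t) & is.finite(y) & t > 0 & y > 0
  if (sum(ok) < 2) stop("need at least two positive points")
  stats::coef(stats::lm(log(y[ok]) ~ log(t[ok])))[[2L]]
}

#' Analytic-oracle self-checks of the fusion model
#'
#' Recomputes the model's three hallmark scalings from scratch and
#' compares them with theory: the numerical 2-D point-release peak decay
#' (exponent 1), the driving-gradient decay (exponent 3/2) and the
#' self-similar intensity decay of the shrinkage model (exponent 1/6).
#'
#' @param grid_n grid side for the point-release oracle.
#' @return A data frame with columns `check`, `expected`, `measured`,
#'   `tol`, `pass`; printed by the pipeline's `model-check` command.
#' @export
model_check <- function(grid_n = 256) {
  ts <- exp(seq(log(10), log(200), length.out = 10))
  fld <- simulate_point_release_2d(D = 1, M = 1, grid_n = grid_n,
                                   times = ts, keep_fields = FALSE)
  e_point <- -loglog_slope(fld$times, fld$c_max)
  p <- fusion_model_params()
  tt <- exp(seq(log(1), log(100), length.out = 40))
  e_dc <- -loglog_slope(tt, delta_c_profile(p, tt))
  br <- power_law_branch(p, exp(seq(log(0.1), log(10), length.out = 60)))
  e_br <- -loglog_slope(br$t_s, br$I_max)
  out <- data.frame(
    check = c("point-source c_max decay", "delta_c decay",
              "self-similar I_max decay"),
    expected = c(1, 1.5, 1 / 6),
    measured = c(e_point, e_dc, e_br),
    tol = c(0.02, 1e-6, 1e-3)
  )
  out$pass <- abs(out$measured - out$expected) <= out$tol
  out
}
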