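# The diffusion-limited shrinkage model and its numerical oracles.

test_that("parameter constructor enforces positivity", {
  expect_s3_class(fusion_model_params(), "fusion_model_params")
  expect_error(fusion_model_params(R0 = -1), "R0")
  expect_error(fusion_model_params(t_start = 0), "t_start")
  expect_error(fusion_model_params(rho = 0), "rho")
})

test_that("concentration gradient follows the -3/2 law", {
  p <- fusion_model_params(c_amp = 1, l_amp = 2, t_start = 0.01)
  expect_equal(delta_c_profile(p, 1), 1)
  expect_equal(delta_c_profile(p, 4), 0.125)
  tt <- exp(seq(log(1), log(100), length.out = 50))
  expect_equal(loglog_slope(tt, delta_c_profile(p, tt)), -1.5,
               tolerance = 1e-9)
  expect_error(delta_c_profile(p, c(1, -2)), "positive")
  expect_error(delta_c_profile(p, 0.001), "t_start")
})

test_that("shrinkage ODE matches the closed-form solution", {
  p <- fusion_model_params(R0 = 2e-7, D = 5e-12, h = 5e-9, rho = 1e3,
                           t_start = 0.03, c_amp = 1, l_amp = 1)
  tt <- seq(0.03, 6, by = 0.03)
  tr <- integrate_shrinkage_ode(p, tt)
  cf <- cubofuse:::shrinkage_closed_form(p, tt)
  expect_lt(max(abs(tr$R_m - cf) / cf), 1e-6)
  expect_true(all(diff(tr$R_m) <= 0))
  expect_true(all(diff(tr$L_m) >= 0))
  # I_max / R constant across the trajectory
  expect_equal(stats::sd(tr$I_max / tr$R_m), 0)
})

test_that("no flux means no shrinkage", {
  p <- fusion_model_params(R0 = 1e-7, D = 0, t_start = 1)
  tr <- integrate_shrinkage_ode(p, seq(1, 50, by = 1))
  expect_equal(tr$R_m, rep(1e-7, 50))
})

test_that("ODE reproduces the analytic power-law branch value", {
  # C = 2 c_amp D h / (l_amp rho) = 1 with these choices; the branch
  # initial condition R0^3 = 6 C t_start^(-1/2) at t_start = 1 gives
  # R(t) = 6^(1/3) t^(-1/6), so R(4) = 6^(1/3) 4^(-1/6)
  p <- fusion_model_params(R0 = 6^(1 / 3), D = 1, h = 1, rho = 1,
                           c_amp = 1, l_amp = 2, t_start = 1)
  tr <- integrate_shrinkage_ode(p, c(1, 2, 4))
  expect_equal(tr$R_m[3], 6^(1 / 3) * 4^(-1 / 6), tolerance = 1e-8)
})

test_that("small particles deplete at the closed-form root", {
  # R0^3 = 1 < 6 C t_start^(-1/2) = 6: depletion when
  # 6(1 - t^(-1/2)) = 1, i.e. t = (6/5)^2 = 1.44
  p <- fusion_model_params(R0 = 1, D = 1, h = 1, rho = 1, c_amp = 1,
                           l_amp = 2, t_start = 1)
  tr <- integrate_shrinkage_ode(p, seq(1, 4, by = 0.01))
  expect_equal(attr(tr, "depletion_time"), 1.44, tolerance = 1e-10)
  expect_equal(tr$R_m[tr$t_s > 1.45], rep(0, sum(tr$t_s > 1.45)))
  expect_gt(min(tr$R_m[tr$t_s < 1.43]), 0)
})

test_that("faster bilayer diffusion never slows shrinkage", {
  tt <- seq(0.05, 5, length.out = 60)
  base <- fusion_model_params(R0 = 2e-7, D = 3e-12, h = 5e-9,
                              rho = 1e3, t_start = 0.05)
  fast <- fusion_model_params(R0 = 2e-7, D = 6e-12, h = 5e-9,
                              rho = 1e3, t_start = 0.05)
  expect_true(all(integrate_shrinkage_ode(fast, tt)$R_m <=
                    integrate_shrinkage_ode(base, tt)$R_m + 1e-15))
})

test_that("self-similar branch scales as t^(-1/6) with (Dh/rho)^(1/3)", {
  p <- fusion_model_params(D = 1 / 6, h = 1, rho = 1, c_amp = 1,
                           l_amp = 2, t_start = 0.1)
  tt <- exp(seq(log(0.1), log(10), length.out = 61))  # includes t = 1
  br <- power_law_branch(p, tt)
  expect_equal(br$R_m[31], 1, tolerance = 1e-9)
  expect_equal(loglog_slope(br$t_s, br$I_max), -1 / 6,
               tolerance = 1e-9)
  p2 <- fusion_model_params(D = 1 / 3, h = 1, rho = 1, c_amp = 1,
                            l_amp = 2, t_start = 0.1)
  br2 <- power_law_branch(p2, tt)
  expect_equal(br2$I_max / br$I_max, rep(2^(1 / 3), length(tt)))
})

test_that("point release reproduces the 2-D Green's function", {
  f <- simulate_point_release_2d(D = 1, M = 1, grid_n = 101,
                                 times = c(16, 25),
                                 keep_fields = FALSE)
  expect_equal(f$c_max, 1 / (4 * pi * c(16, 25)), tolerance = 0.01)
  expect_equal(f$mass, c(1, 1), tolerance = 1e-6)
})

test_that("point-release peak decays with exponent 1", {
  ts <- exp(seq(log(10), log(100), length.out = 8))
  f <- simulate_point_release_2d(D = 1, M = 1, grid_n = 201,
                                 times = ts, keep_fields = FALSE)
  expect_equal(-loglog_slope(f$times, f$c_max), 1, tolerance = 0.02)
})

test_that("explicit step beyond the stability limit is refused", {
  expect_error(simulate_point_release_2d(D = 1, M = 1, grid_n = 51,
                                         times = 1, dt = 1),
               "stability")
})

test_that("footprint diameter matches the Gaussian closed form", {
  ts <- c(12, 24, 48)
  f <- simulate_point_release_2d(D = 1, M = 1, grid_n = 201,
                                 times = ts)
  L <- footprint_diameter(f, 0.5)
  expect_equal(L, 4 * sqrt(ts * log(2)), tolerance = 0.05)
  expect_equal(loglog_slope(ts, L), 0.5, tolerance = 0.03)
  # threshold near 1 leaves only the peak cell
  expect_lte(max(footprint_diameter(f, 0.999)), 2.1)
})

test_that("model self-checks all pass", {
  chk <- model_check(grid_n = 192)
  expect_true(all(chk$pass))
})
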