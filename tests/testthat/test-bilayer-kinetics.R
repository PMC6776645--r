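# Bilayer-formation kinetics: coverage, erf fits, domain counting,
# nucleation-growth simulation.

test_that("coverage fraction counts pixels above threshold", {
  fr <- array(10, dim = c(10, 10, 2))
  fr[, 1:5, 1] <- 200
  fr[, , 2] <- 200
  cv <- coverage_curve(fr, threshold = 100)
  expect_equal(cv$theta, c(0.5, 1))
  # all-background movie is valid with zero coverage
  cv0 <- coverage_curve(array(10, dim = c(8, 8, 3)), threshold = 100)
  expect_equal(cv0$theta, rep(0, 3))
})

test_that("erf growth fit round-trips exact and shifted curves", {
  t <- seq(0, 150, by = 0.5)
  th <- 0.9 * pnorm((t - 60) / 20)
  fit <- fit_erf_growth(data.frame(t_s = t, theta = th))
  expect_equal(unname(coef(fit)), c(0.9, 60, 20), tolerance = 0.005)
  expect_equal(fit$max_slope, 0.9 / (20 * sqrt(2 * pi)),
               tolerance = 0.005)
  # time shift moves t_c only
  sh <- fit_erf_growth(data.frame(t_s = t + 25,
                                  theta = 0.9 * pnorm((t - 60) / 20)))
  expect_equal(sh$t_c, 85, tolerance = 0.005)
  expect_equal(sh$tau, 20, tolerance = 0.005)
  # gradient peaks at t_c
  g <- predict(fit, deriv = TRUE)
  expect_equal(fit$t_s[which.max(g)], 60, tolerance = 0.02)
})

test_that("erf parameters are recovered from noisy coverage curves", {
  t <- seq(0, 150, by = 1)
  errs <- t(vapply(1:50, function(s) {
    set.seed(300 + s)
    th <- pmin(pmax(pnorm((t - 60) / 20) +
                      rnorm(length(t), 0, 0.02), 0), 1)
    f <- fit_erf_growth(data.frame(t_s = t, theta = th))
    c(abs(f$t_c - 60) / 60, abs(f$tau - 20) / 20)
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.02)
  expect_lt(stats::median(errs[, 2]), 0.05)
})

test_that("clearly non-sigmoidal data are flagged", {
  t <- seq(0, 99, by = 1)
  set.seed(9)
  th <- runif(100, 0.3, 0.7)
  expect_warning(f <- fit_erf_growth(data.frame(t_s = t, theta = th)),
                 "non-sigmoidal")
  expect_true(f$flagged)
})

test_that("domain counting respects connectivity and minimum area", {
  fr <- matrix(0, 20, 20)
  fr[2:4, 2:4] <- 10; fr[10:12, 10:12] <- 10; fr[16:18, 3:5] <- 10
  expect_equal(count_domains(fr, 5), 3L)
  # single isolated pixel removed by the area filter
  fr[1, 20] <- 10
  expect_equal(count_domains(fr, 5, min_area = 4), 3L)
  expect_equal(count_domains(fr, 5, min_area = 1), 4L)
  # two blocks touching at one corner: joined under 8, split under 4
  fr2 <- matrix(0, 9, 9)
  fr2[2:4, 2:4] <- 10; fr2[5:7, 5:7] <- 10
  expect_equal(count_domains(fr2, 5, connectivity = 8), 1L)
  expect_equal(count_domains(fr2, 5, connectivity = 4), 2L)
  expect_equal(count_domains(matrix(0, 5, 5), 5), 0L)
})

test_that("in-package labelling matches EBImage on 4-connectivity", {
  set.seed(12)
  mask <- matrix(runif(400) > 0.6, 20, 20)
  ours <- cubofuse:::label_components(mask, connectivity = 4)
  ref <- EBImage::bwlabel(matrix(as.numeric(mask), 20, 20))
  expect_equal(max(ours), max(ref))
})

test_that("a single nucleus grows quadratically in coverage", {
  sim <- simulate_nucleation_growth(rate = 1e-6, growth_speed = 0.08,
                                    dim = c(96L, 96L), n_frames = 60,
                                    seed = 2)
  expect_equal(nrow(sim$nuclei), 1)
  cv <- coverage_curve(sim, threshold = 50)
  t0 <- sim$nuclei$t_s[1]
  tt <- cv$t_s - t0
  sel <- tt > 5 & cv$theta > 0.005 & cv$theta < 0.25
  expect_gt(sum(sel), 5)
  expect_equal(loglog_slope(tt[sel], cv$theta[sel]), 2,
               tolerance = 0.05)
})

test_that("nucleation-growth movies cover monotonically and end whole", {
  sim <- simulate_nucleation_growth(rate = 0.002, growth_speed = 0.25,
                                    dim = c(96L, 96L), n_frames = 80,
                                    seed = 4)
  cv <- coverage_curve(sim, threshold = 50)
  expect_true(all(diff(cv$theta) >= 0))
  expect_equal(cv$theta[nrow(cv)], 1)
  dc <- domain_count_series(sim, 50)
  expect_equal(dc$count[nrow(dc)], 1L)
  # counts rise to an interior peak before merging down to one
  expect_gt(max(dc$count), 3)
  expect_gt(which.max(dc$count), 1)
  expect_lt(which.max(dc$count), nrow(dc))
  # the fitted gradient peaks near the peak merge activity
  fit <- fit_erf_growth(cv)
  expect_gt(fit$r_squared, 0.95)
  dens <- stats::density(sim$merges$t_s)
  merge_mode <- dens$x[which.max(dens$y)]
  expect_lt(abs(fit$t_c - merge_mode), 15)
  # determinism under the seed
  sim2 <- simulate_nucleation_growth(rate = 0.002, growth_speed = 0.25,
                                     dim = c(96L, 96L), n_frames = 80,
                                     seed = 4)
  expect_identical(sim$frames, sim2$frames)
})
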