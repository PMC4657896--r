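test_that("walk configuration enforces the step-size invariant", {
  expect_error(
    walk_config(a_eta = 1e-6, b = 5e-6, kappa_radial = 1e-13, t_max = 10,
                n_walkers = 10, seed = 1, dt = 1e6),
    "dt too coarse"
  )
  cfg <- walk_config(a_eta = 1e-6, b = 5e-6, kappa_radial = 1e-13,
                     t_max = 10, n_walkers = 10, seed = 1)
  expect_lte(sqrt(1e-13 * cfg$dt), (5e-6 - 1e-6) / 100 * (1 + 1e-9))
})

test_that("radial ensembles are reproducible and walker streams are stable", {
  cfg <- walk_config(a_eta = 1e-6, b = 5e-6, kappa_radial = 1e-13,
                     t_max = 5, n_walkers = 300, seed = 9)
  e1 <- simulate_radial_fpt(cfg, 3e-6)
  e2 <- simulate_radial_fpt(cfg, 3e-6)
  expect_identical(e1$times, e2$times)
  expect_identical(e1$censored, e2$censored)
  # enlarging the ensemble leaves existing walkers' trajectories untouched
  cfg_big <- walk_config(a_eta = 1e-6, b = 5e-6, kappa_radial = 1e-13,
                         t_max = 5, n_walkers = 600, seed = 9)
  e3 <- simulate_radial_fpt(cfg_big, 3e-6)
  expect_identical(e3$times[1:300], e1$times)
  # times positive, censored walkers carry the horizon
  expect_true(all(e1$times > 0))
  expect_true(all(e1$times[e1$censored] == cfg$t_max))
})

test_that("a start on the absorber is an immediate hit", {
  cfg <- walk_config(a_eta = 1e-6, b = 5e-6, kappa_radial = 1e-13,
                     t_max = 1, n_walkers = 50, seed = 2)
  ens <- simulate_radial_fpt(cfg, 1e-6)
  expect_true(all(ens$times == 0))
  expect_false(any(ens$censored))
})

test_that("unreflected walk matches the single-term Levy law", {
  a <- 1e-6; kr <- 1e-13; gamma <- 2.5e-6
  t_win <- 40
  b_far <- a + 40 * sqrt(kr * t_win)
  cfg <- walk_config(a_eta = a, b = b_far, kappa_radial = kr, t_max = t_win,
                     n_walkers = 4000, seed = 3, dt = ((5e-6 - a) / 100)^2 / kr)
  ens <- simulate_radial_fpt(cfg, gamma)
  expect_lt(walk_cdf_distance(ens, single_term = TRUE), 0.02)
})

test_that("mixture law matches the walk inside its small-time window", {
  a <- 1e-6; b <- 5e-6; kr <- 1e-13
  cfg <- walk_config(a_eta = a, b = b, kappa_radial = kr,
                     t_max = 0.1 * (b - a)^2 / kr, n_walkers = 4000, seed = 4)
  ens <- simulate_radial_fpt(cfg, 0.9 * b)
  expect_lt(walk_cdf_distance(ens), 0.02)
})

test_that("halving dt moves the median first-passage time by little", {
  a <- 1e-6; kr <- 1e-13; gamma <- 2.5e-6
  b_far <- a + 40 * sqrt(kr * 40)
  dt0 <- ((5e-6 - a) / 100)^2 / kr
  for (s in c(6, 7)) {
    d <- fpt_convergence_check(a, b_far, kr, gamma, t_max = 10,
                               n_walkers = 3000, dt = dt0 / 2, seed = s)
    expect_lt(d, 0.02)
  }
})

test_that("radial step decomposition is Pythagorean to high accuracy", {
  withr::local_seed(8)
  r <- 10^stats::runif(200, -6, -4)
  s <- r * stats::runif(200, -1e-3, 1e-3)
  eps <- r * stats::runif(200, 0, 1e-3)
  exact <- sqrt((r + s)^2 + eps^2)
  approx <- sqrt(r^2 + 2 * r * s)
  expect_lt(max(abs(exact - approx) / r), 1e-6)
})

test_that("3-d ensemble reproduces and projects onto the radial walk", {
  a <- 1e-6; b <- 5e-5; kr <- 1e-13
  gamma <- 1.05e-6  # near the absorber: curvature correction ~ (gamma-a)/a
  dt <- ((gamma - a) / 20)^2 / kr
  t_max <- 20 * (gamma - a)^2 / kr
  cfg3 <- walk_config(a_eta = a, b = b, kappa_radial = kr, t_max = t_max,
                      n_walkers = 2000, seed = 12, dt = dt, mode = "full-3d",
                      kappa_3d = kr)
  e3 <- simulate_3d_fpt(cfg3, gamma)
  e3b <- simulate_3d_fpt(cfg3, gamma)
  expect_identical(e3$times, e3b$times)
  # start on the absorber
  e0 <- simulate_3d_fpt(cfg3, a)
  expect_true(all(e0$times == 0))
  # radial 1-d projection with matched radial variance: medians close
  cfg1 <- walk_config(a_eta = a, b = b, kappa_radial = kr, t_max = t_max,
                      n_walkers = 2000, seed = 13, dt = dt)
  e1 <- simulate_radial_fpt(cfg1, gamma)
  m3 <- glance(e3)$fpt_median
  m1 <- glance(e1)$fpt_median
  expect_lt(abs(m3 - m1) / m1, 0.25)
})

test_that("Monte-Carlo replication estimate is deterministic and bounded", {
  p <- param_set(a_eta = 2e-5, c_eta = 1e9, c_nu = 1e14, c_beta = 1e9,
                 q = 46, rho = 0.5)
  r1 <- estimate_pr_mc(p, n_trials = 2000, seed = 21, dt_refine = 8)
  r2 <- estimate_pr_mc(p, n_trials = 2000, seed = 21, dt_refine = 8)
  expect_identical(r1$p_r_mc, r2$p_r_mc)
  expect_true(r1$p_r_mc >= 0 && r1$p_r_mc <= 1)
  expect_true(r1$p_r_mc_lo <= r1$p_r_mc && r1$p_r_mc <= r1$p_r_mc_hi)
  # replication timescale far below any first-passage time: certain doubling
  fast <- dplyr::mutate(p, q = 0.2)
  expect_equal(estimate_pr_mc(fast, n_trials = 500, seed = 22,
                              dt_refine = 64)$p_r_mc, 1)
})

test_that("walk ensembles tidy, summarise and plot", {
  cfg <- walk_config(a_eta = 1e-6, b = 5e-6, kappa_radial = 1e-13,
                     t_max = 5, n_walkers = 100, seed = 14)
  ens <- simulate_radial_fpt(cfg, 4e-6)
  td <- tidy(ens)
  expect_identical(nrow(td), 100L)
  expect_named(td, c("walker_id", "fpt_seconds", "censored", "start_radius"))
  gl <- glance(ens)
  expect_equal(gl$censored_fraction, mean(ens$censored))
  expect_s3_class(autoplot(ens), "ggplot")
})
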