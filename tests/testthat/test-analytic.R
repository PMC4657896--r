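test_that("derived scales match hand-evaluated definitions", {
  p <- param_set(a_eta = 1e-6, a_nu = 1e-10, a_beta = 5e-8, c_eta = 1e9,
                 c_nu = 1e13, c_beta = 1e9, q = 100, rho = 1,
                 kappa_nu = 1e-9)
  dq <- derive_quantities(p)
  expect_equal(dq$uptake_rate, 4 * pi * 1e-2, tolerance = 1e-12)  # fg/s
  expect_equal(dq$tau_r, 100 / (4 * pi * 1e-2), tolerance = 1e-12)
  expect_equal(dq$b, (5 / 18) * 1e-3, tolerance = 1e-12)
  expect_equal(dq$kappa_radial, (1 - 2 / pi)^2 * dq$kappa_beta)
  expect_equal(dq$n_beta, (4 * pi / 3) * 1 * 1e9 * dq$b^3)
  # halving rho halves uptake and expected viruses, doubles tau_r
  dq2 <- derive_quantities(dplyr::mutate(p, rho = 0.5))
  expect_equal(dq2$uptake_rate, dq$uptake_rate / 2)
  expect_equal(dq2$n_beta, dq$n_beta / 2)
  expect_equal(dq2$tau_r, dq$tau_r * 2)
  # B/A is exactly the dining prefactor over ln 2 times c_beta/c_eta
  expect_equal(dq$coef_B / dq$coef_A,
               colim_constants$dining_prefactor / log(2) * 1e9 / 1e9,
               tolerance = 1e-14)
})

test_that("exact replication probability agrees with a fine-grid quadrature oracle", {
  p <- derive_quantities(param_set(a_eta = 3e-5, c_eta = 1e9, c_nu = 1e12,
                                   c_beta = 1e9, q = 1000, rho = 0.5))
  g <- seq(p$a_eta, p$b, length.out = 100001)
  h <- g[2] - g[1]
  law <- fpt_law(g, p$a_eta, p$b, p$kappa_radial)
  # trapezoid over the shell-volume-weighted mixture CDF
  w <- 3 * g^2 / (p$b^3 - p$a_eta^3) * invasion_time_cdf(law, p$tau_r)
  oracle <- 1 - (sum(w) - (w[1] + w[length(w)]) / 2) * h
  expect_equal(replication_prob(p, method = "exact")$p_r, oracle,
               tolerance = 1e-6)
})

test_that("replication probability limits and monotonicities hold", {
  p <- mid_params()
  # instant replication beats any walk
  expect_equal(replication_prob(dplyr::mutate(p, q = 1e-12))$p_r, 1,
               tolerance = 1e-9)
  # frozen virus cannot invade
  slow <- dplyr::mutate(p, kappa_beta = 1e-30)
  expect_equal(replication_prob(slow)$p_r, 1, tolerance = 1e-6)
  # p_r decreases as the host grows at fixed replication timescale (the
  # quota is co-scaled so tau_r stays put; with q fixed a larger host also
  # replicates faster, which can mask the geometric effect at small radii)
  tau0 <- derive_quantities(p)$tau_r
  a_grid <- seq(1e-5, 9e-5, length.out = 9)
  prs <- vapply(a_grid, function(a) {
    q_a <- tau0 * 4 * pi * p$rho * a * p$kappa_nu * p$c_nu
    replication_prob(dplyr::mutate(p, a_eta = a, q = q_a),
                     method = "exact")$p_r
  }, numeric(1))
  expect_true(all(diff(prs) < 0))
  expect_true(all(prs >= 0 & prs <= 1))
})

test_that("small-time approximation tracks the exact quadrature where valid", {
  sets <- sample_parameters(30, seed = 11)
  dq <- derive_quantities(sets)
  strong <- (dq$b - dq$a_eta) / sqrt(dq$kappa_radial * dq$tau_r) >= 10
  # compare where the small-time condition holds with margin
  idx <- which(strong)[1:min(10, sum(strong))]
  ex <- replication_prob(sets[idx, ], method = "exact")$p_r
  ap <- replication_prob(sets[idx, ], method = "approx")$p_r
  expect_lt(max(abs(ex - ap)), 0.01)
  # the flag itself is carried through
  expect_true(all(replication_prob(sets[idx, ])$small_time_valid))
})

test_that("total replication probability composes independent viral trials", {
  p <- mid_params()
  t0 <- total_replication_prob(dplyr::mutate(p, c_beta = 0))
  expect_equal(t0$P_r, 1)
  tr <- total_replication_prob(p)
  expect_equal(tr$P_r, tr$p_r^tr$n_beta)
  # more viruses, lower P_r
  cb <- 10^seq(8, 12, length.out = 9)
  prs <- vapply(cb, function(x) {
    total_replication_prob(dplyr::mutate(p, c_beta = x))$P_r
  }, numeric(1))
  expect_true(all(diff(prs) < 0))
  # as-printed path stays in [0, 1] and is labelled distinctly
  pp <- total_replication_prob(p, method = "printed")
  expect_true(pp$P_r >= 0 && pp$P_r <= 1)
})

test_that("virus-free growth is exact doubling at rate A*rho", {
  p <- param_set(c_beta = 0, rho = 0.7)
  for (m in c("compositional", "coefficients")) {
    g <- growth_rate(p, method = m, classify = FALSE)
    expect_equal(g$mu, g$coef_A * 0.7, tolerance = 1e-12)
    expect_equal(g$mu, log(2) / g$tau_r, tolerance = 1e-12)
  }
})

test_that("growth rate is affine and decreasing in virus concentration", {
  p <- mid_params()
  cb <- seq(1e8, 1e10, length.out = 7)
  tab <- sensitivity_report(p, "c_beta", cb)
  fit <- stats::lm(mu ~ value, data = tab)
  expect_lt(max(abs(stats::residuals(fit))) / abs(mean(tab$mu)), 1e-10)
  expect_lt(stats::coef(fit)[["value"]], 0)
})

test_that("growth increases superlinearly in nutrients and inversely in quota", {
  p <- mid_params()
  g1 <- growth_rate(p, classify = FALSE)$mu
  g2 <- growth_rate(dplyr::mutate(p, c_nu = 3 * p$c_nu),
                    classify = FALSE)$mu
  expect_gt(g2, 3 * g1)  # lambda > 1 scaling beats linear
  # with no viruses, mu * q is a constant
  q_grid <- c(10, 100, 1000, 1e4)
  mus <- vapply(q_grid, function(q) {
    growth_rate(param_set(c_beta = 0, q = q), method = "coefficients",
                classify = FALSE)$mu
  }, numeric(1))
  expect_equal(mus * q_grid, rep(mus[1] * q_grid[1], 4), tolerance = 1e-12)
})

test_that("joint diffusivity scaling (temperature) scales growth linearly", {
  p <- mid_params()
  lam <- 1.7
  p2 <- dplyr::mutate(p, kappa_nu = lam * kappa_nu,
                      kappa_beta = lam * kappa_beta)
  for (m in c("coefficients", "compositional")) {
    g1 <- growth_rate(p, method = m, classify = FALSE)
    g2 <- growth_rate(p2, method = m, classify = FALSE)
    expect_equal(g2$mu, lam * g1$mu, tolerance = 1e-7)
  }
  # C is invariant under the joint scaling, A is proportional
  d1 <- derive_quantities(p); d2 <- derive_quantities(p2)
  expect_equal(d2$coef_C, d1$coef_C, tolerance = 1e-12)
  expect_equal(d2$coef_A, lam * d1$coef_A, tolerance = 1e-12)
})

test_that("the viral term only ever depresses growth (mu <= A rho)", {
  sets <- sample_parameters(30, seed = 5)
  for (m in c("compositional", "coefficients")) {
    g <- growth_rate(sets, method = m, classify = FALSE)
    expect_true(all(g$mu <= g$coef_A * g$rho + 1e-12 * abs(g$coef_A)))
  }
})

test_that("coefficient form equals the compositional form built on the same p_r", {
  p <- example_params("II")[, -1]
  dq <- replication_prob(p, method = "approx")
  mu_comp <- (log(2) + dq$n_beta * log(dq$p_r)) / dq$tau_r
  mu_coef <- growth_rate(p, method = "coefficients", classify = FALSE)$mu
  expect_equal(mu_coef, mu_comp, tolerance = 1e-10)
})

test_that("as-printed two-digit form tracks the full-precision coefficients", {
  # printed constants are 2-significant-digit roundings; on a baseline where
  # the viral term is a modest correction the paths agree to ~rounding level
  for (p in list(mid_params(), example_params("I")[, -1])) {
    g_pr <- growth_rate(p, method = "printed", classify = FALSE)$mu
    g_cf <- growth_rate(p, method = "coefficients", classify = FALSE)$mu
    expect_lt(abs(g_pr - g_cf) / abs(g_cf), 0.02)
  }
})

test_that("nonviable log domain yields a -Inf sentinel, not a clipped rate", {
  expect_identical(mu_from_coefficients(1, 2, 1.5, 1), -Inf)
  expect_identical(mu_from_coefficients(1, 2, 0.5, 0.2), -Inf)  # C/sqrt(rho)>1
  p4 <- example_params("IV")[, -1]
  g <- growth_rate(p4, method = "coefficients", classify = FALSE)
  expect_identical(g$mu, -Inf)
})

test_that("rho optimiser matches a brute-force grid scan", {
  # worked coefficient example: interior maximum
  opt <- optimize_rho_coef(1, 2, 0.1)
  grid <- seq(1e-3, 1, length.out = 1e6)
  mu <- mu_from_coefficients(1, 2, 0.1, grid)
  expect_lt(abs(opt$rho_star - grid[which.max(mu)]), 1e-6)
  expect_equal(opt$mu_star, max(mu), tolerance = 1e-10)
  # virus-free: monotone, optimum at full coverage
  expect_equal(optimize_rho(param_set(c_beta = 0))$rho_star, 1)
})

test_that("rising virus load pushes the optimal receptor efficiency down", {
  p <- example_params("II")[, -1]
  ratios <- 10^seq(-2, 2, length.out = 9)
  stars <- vapply(ratios, function(r) {
    optimize_rho(dplyr::mutate(p, c_beta = r * c_eta),
                 rho_min = 1e-3)$rho_star
  }, numeric(1))
  expect_equal(stars[1], 1)                      # scarce viruses: rho* = 1
  expect_true(all(diff(stars) <= 1e-8))          # monotone non-increasing
  expect_lt(stars[length(stars)], 1)             # abundant viruses: interior
})

test_that("regime classification reproduces the four canonical corners", {
  expect_identical(regime_from_coefficients(1, 1e-3, 1e-3), "I")
  expect_identical(regime_from_coefficients(1, 1.3, 0.52), "II")
  expect_identical(regime_from_coefficients(1, 0.951, 0.6495), "III")
  expect_identical(regime_from_coefficients(1, 10, 1.5), "IV")
  # labels are stable under rho-grid refinement
  sets <- derive_quantities(sample_parameters(50, seed = 19))
  r1 <- regime_from_coefficients(sets$coef_A, sets$coef_B, sets$coef_C,
                                 n_grid = 1000L)
  r2 <- regime_from_coefficients(sets$coef_A, sets$coef_B, sets$coef_C,
                                 n_grid = 10000L)
  expect_identical(r1, r2)
})

test_that("sensitivity reports flag invalid grid rows instead of failing", {
  tab <- sensitivity_report(mid_params(), "rho", c(0.2, 0.8, 1.5))
  expect_identical(tab$valid, c(TRUE, TRUE, FALSE))
  expect_true(is.na(tab$mu[3]))
  expect_error(sensitivity_report(mid_params(), "nope", 1), "target")
})
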