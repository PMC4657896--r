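test_that("Einstein-Stokes diffusivity matches hand computation and scaling", {
  kb <- 1.380649e-23
  expect_equal(einstein_stokes_diffusivity(1e-9, 293, 1e-3),
               kb * 293 / (6 * pi * 1e-3 * 1e-9), tolerance = 1e-14)
  # a 1 nm molecule in 20 C water sits inside the nutrient bracket
  k_nu <- einstein_stokes_diffusivity(1e-9, 293, 1e-3)
  expect_gt(k_nu, 1e-10)
  expect_lt(k_nu, 1e-9)
  # a 50 nm virion: ~4.3e-12 m^2/s
  expect_equal(einstein_stokes_diffusivity(5e-8, 293, 1e-3), k_nu / 50,
               tolerance = 1e-12)
  # proportionalities
  expect_equal(einstein_stokes_diffusivity(1e-9, 2 * 293, 1e-3), 2 * k_nu)
  expect_equal(einstein_stokes_diffusivity(2e-9, 293, 1e-3), k_nu / 2)
  expect_error(einstein_stokes_diffusivity(-1e-9, 293, 1e-3), "positive")
  expect_error(einstein_stokes_diffusivity(1e-9, 0, 1e-3), "positive")
})

test_that("validation separates hard physics errors from range warnings", {
  expect_no_hard_errors(mid_params())
  # rho outside (0, 1] is a hard error
  v <- validate_params(dplyr::mutate(mid_params(), rho = 1.2), warn = FALSE)
  expect_true(any(v$severity == "error" & v$parameter == "rho"))
  expect_error(param_set(rho = 1.2), "rho")
  # dense hosts: dining sphere smaller than the host itself
  v <- validate_params(
    dplyr::mutate(mid_params(), c_eta = 1e18, a_eta = 1e-4),
    warn = FALSE
  )
  expect_true(any(grepl("dining sphere", v$message)))
  # out-of-bracket values warn but are not errors
  p <- dplyr::mutate(mid_params(), c_nu = 1e20)
  expect_warning(v <- validate_params(p), "outside observed range")
  expect_false(any(v$severity == "error"))
  # zero virus concentration is a meaningful limit, not an error
  v <- validate_params(dplyr::mutate(mid_params(), c_beta = 0), warn = FALSE)
  expect_false(any(v$severity == "error"))
})

test_that("parameter sampling is reproducible, valid, and log-uniform in range", {
  s1 <- sample_parameters(100, seed = 1)
  s2 <- sample_parameters(100, seed = 1)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 100L)
  for (i in seq_len(nrow(s1))) expect_no_hard_errors(s1[i, ])
  r <- default_ranges()
  for (p in c("a_eta", "c_eta", "c_nu", "q", "rho")) {
    expect_true(all(s1[[p]] >= r$low[r$parameter == p]))
    expect_true(all(s1[[p]] <= r$high[r$parameter == p]))
  }
  # dining sphere constraint enforced by rejection
  expect_true(all((5 / 18) * s1$c_eta^(-1 / 3) > s1$a_eta))
  expect_error(sample_parameters(0, seed = 1), "positive count")
  # different seeds differ
  expect_false(identical(sample_parameters(5, 1), sample_parameters(5, 2)))
})

test_that("receptor efficiency from coverage is a saturating Monod-like curve", {
  f <- seq(0, 1, length.out = 101)
  rho <- receptor_efficiency_from_coverage(f, 1e-9, 1e-6)
  expect_equal(rho[1], 0)
  expect_equal(rho[101], 1)
  expect_true(all(diff(rho) > 0))           # monotone increasing
  expect_true(all(diff(diff(rho)) < 1e-12)) # concave
  # half-saturation at small coverage: steep then saturating
  half <- f[which.min(abs(rho - 0.5))]
  expect_lt(half, 0.05)
  expect_error(receptor_efficiency_from_coverage(1.5, 1e-9, 1e-6), "0, 1")
})

test_that("parameter CSV round trip preserves 12 significant digits", {
  s <- sample_parameters(20, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_params_csv(s, path)
  # headers carry unit strings
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "a_eta \\[m\\]")
  expect_match(hdr, "c_nu \\[fg m\\^-3\\]")
  back <- read_params_csv(path)
  for (col in c("a_eta", "c_nu", "q", "rho", "kappa_beta")) {
    expect_equal(back[[col]], s[[col]], tolerance = 1e-12)
  }
})

test_that("config files parse with CLI-style overrides taking precedence", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("a_eta: 2.0e-5", "q: 500", "rho: 0.8"), path)
  p <- read_params_config(path)
  expect_equal(p$a_eta, 2e-5)
  expect_equal(p$q, 500)
  p2 <- read_params_config(path, overrides = list(rho = 0.3))
  expect_equal(p2$rho, 0.3)
  expect_error(read_params_config(path, overrides = list(bogus = 1)),
               "unknown config fields")
})

test_that("kappa_beta defaults to the Einstein-Stokes radius ratio", {
  p <- param_set(kappa_nu = 4e-10, a_nu = 1e-10, a_beta = 5e-8)
  expect_equal(p$kappa_beta, 4e-10 * 1e-10 / 5e-8)
  # a direct value wins but triggers a consistency warning
  expect_warning(
    p2 <- param_set(kappa_nu = 4e-10, a_nu = 1e-10, a_beta = 5e-8,
                    kappa_beta = 5e-12),
    "differs from radius-derived"
  )
  expect_equal(p2$kappa_beta, 5e-12)
})
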