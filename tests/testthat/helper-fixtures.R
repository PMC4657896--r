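# Shared fixtures: all parameter sets lie inside the observed marine ranges.

# Geometric-midpoint baseline (rho = 0.5).
mid_params <- function() param_set()

# Three parameter sets used for walker-vs-quadrature replication-probability
# comparisons. Viral pressure is mild by construction (expected invasions of
# order one per 1e4 trials): there the two-term invasion law's absolute error
# against a true reflected walk is below Monte-Carlo resolution, so the
# comparison tests the machinery rather than the law's small-time truncation.
# `dt_refine` oversamples the default step so tau_r spans >= ~50 steps.
mc_bracket_sets <- function() {
  tibble::tibble(
    params = list(
      param_set(a_eta = 2e-5, c_eta = 1e9, c_nu = 1e14, c_beta = 1e9,
                q = 46, rho = 0.5),
      param_set(a_eta = 1e-5, c_eta = 3.16e8, c_nu = 1e13, c_beta = 3.16e9,
                q = 83, rho = 0.5),
      param_set(a_eta = 1e-5, c_eta = 1e9, c_nu = 1e13, c_beta = 3e9,
                q = 8.7, rho = 1)
    ),
    dt_refine = c(32, 16, 8)
  )
}

expect_no_hard_errors <- function(params) {
  v <- validate_params(params, warn = FALSE)
  expect_identical(nrow(v[v$severity == "error", ]), 0L)
}
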