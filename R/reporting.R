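#' Bundled example parameter sets, one per viral-pressure regime
#'
#' Four parameter sets, each inside the observed marine brackets of
#' [default_ranges()], constructed so that their growth-rate coefficients
#' land in the four regimes of [classify_regime()]:
#' \describe{
#'   \item{I}{Scarce viruses (\eqn{c_\beta \ll c_\eta}): growth is virus-free
#'     to within a fraction of a percent and \eqn{\rho^* = 1}.}
#'   \item{II}{Locally virus-rich, crowded water (\eqn{c_\beta \approx 23
#'     c_\eta}, \eqn{B = 3A}): an interior optimum \eqn{\rho^* \approx 0.47},
#'     with positive growth at the fixture's \eqn{\rho}.}
#'   \item{III}{Aggregated, large hosts (\eqn{B < A} but \eqn{C = O(1)}):
#'     a marginal interior optimum driven by host crowding.}
#'   \item{IV}{Heavy viral load on large, slow hosts: no \eqn{\rho} gives
#'     positive growth; the lineage is grazed down to a seed population.}
#' }
#' Note that regimes II-IV occupy corners where the small-time validity flag
#' of [derive_quantities()] can be off: the closed-form coefficients still
#' define the regime, but the compositional (exact-quadrature) growth rate is
#' the more faithful number there.
#'
#' @param regime `"I"`, `"II"`, `"III"`, `"IV"`, or `"all"`.
#' @return A tibble of parameter sets with a leading `regime` column.
#' @examples
#' classify_regime(example_params("II"))$regime
#' @export
example_params <- function(regime = c("all", "I", "II", "III", "IV")) {
  regime <- match.arg(regime)
  sets <- dplyr::bind_rows(
    dplyr::mutate(param_set(a_eta = 1e-5, a_nu = 1e-10, a_beta = 5e-8,
                            c_eta = 1e9, c_nu = 1e12, c_beta = 1e7,
                            q = 316, rho = 1,
                            kappa_nu = 3.16e-10), regime = "I"),
    dplyr::mutate(param_set(a_eta = 8.7e-5, a_nu = 1e-10, a_beta = 3.16e-8,
                            c_eta = 2e10, c_nu = 1e12, c_beta = 4.64e11,
                            q = 430, rho = 0.46,
                            kappa_nu = 3.16e-10), regime = "II"),
    dplyr::mutate(param_set(a_eta = 8e-5, a_nu = 1e-10, a_beta = 5e-8,
                            c_eta = 5e9, c_nu = 1e11, c_beta = 3.67e10,
                            q = 3.9e4, rho = 0.85,
                            kappa_nu = 3.16e-10), regime = "III"),
    dplyr::mutate(param_set(a_eta = 8e-5, a_nu = 5e-10, a_beta = 2e-8,
                            c_eta = 3e9, c_nu = 1e10, c_beta = 1e11,
                            q = 1e6, rho = 0.5,
                            kappa_nu = 3.16e-10), regime = "IV")
  )
  sets <- dplyr::relocate(sets, "regime")
  if (regime == "all") sets else sets[sets$regime == regime, ]
}

#' Growth-rate curves over receptor efficiency
#'
#' Evaluates \eqn{\mu(\rho)} (coefficient form) on a grid for each row of
#' `params`, annotates each curve with its regime and optimum, and
#' optionally writes `mu_curve.csv` and `mu_curve.png` to `out_dir`.
#'
#' @param params Data frame of parameter sets; a `label` column, if present,
#'   names the curves.
#' @param rho_grid Receptor-efficiency grid in (0, 1\].
#' @param out_dir Output directory, or `NULL` for no files.
#' @return A tibble with columns `label`, `rho`, `mu`, `regime`, `rho_star`,
#'   `mu_star`.
#' @examples
#' curves <- cmd_mu_curve(example_params("I"), rho_grid = seq(0.1, 1, 0.1))
#' @export
cmd_mu_curve <- function(params, rho_grid = seq(0.001, 1, length.out = 400),
                         out_dir = NULL) {
  if (length(rho_grid) == 0) stop("empty rho grid", call. = FALSE)
  if (any(rho_grid <= 0 | rho_grid > 1)) {
    stop("`rho_grid` must lie in (0, 1]", call. = FALSE)
  }
  dq <- with_derived(params)
  dq <- optimize_rho(dq)
  dq$regime <- regime_from_coefficients(dq$coef_A, dq$coef_B, dq$coef_C)
  labels <- if ("label" %in% names(params)) params$label else
    if ("regime" %in% names(params)) paste("regime", params$regime) else
      paste0("set ", seq_len(nrow(params)))
  curves <- purrr::map2(seq_len(nrow(dq)), labels, function(i, lab) {
    tibble::tibble(
      label = lab, rho = rho_grid,
      mu = mu_from_coefficients(dq$coef_A[i], dq$coef_B[i], dq$coef_C[i],
                                rho_grid),
      regime = dq$regime[i], rho_star = dq$rho_star[i],
      mu_star = dq$mu_star[i]
    )
  })
  out <- dplyr::bind_rows(curves)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out, file.path(out_dir, "mu_curve.csv"))
    ggplot2::ggsave(file.path(out_dir, "mu_curve.png"), plot_mu_curve(out),
                    width = 7, height = 5, dpi = 150)
  }
  out
}

#' @rdname cmd_mu_curve
#' @param curves Output of `cmd_mu_curve()`.
#' @export
plot_mu_curve <- function(curves) {
  finite <- curves[is.finite(curves$mu), ]
  opts <- dplyr::distinct(finite, .data$label, .data$rho_star, .data$mu_star)
  ggplot2::ggplot(finite, ggplot2::aes(x = .data$rho, y = .data$mu,
                                       colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = opts[is.finite(opts$mu_star), ],
                        ggplot2::aes(x = .data$rho_star, y = .data$mu_star),
                        shape = 8, size = 3) +
    ggplot2::labs(x = expression(rho~"(receptor efficiency)"),
                  y = expression(mu~(s^-1)), colour = NULL,
                  title = "Lineage growth rate vs receptor efficiency") +
    ggplot2::theme_minimal()
}

#' Regime map over the growth-rate coefficient plane
#'
#' Classifies the regime on a logarithmic grid of the coefficient ratio
#' \eqn{B/A} and the invasion coefficient \eqn{C} (at `A = 1` s^-1; labels
#' depend only on \eqn{B/A} and \eqn{C}). Also reports, per \eqn{B/A} row,
#' the width in \eqn{\log_{10} C} of the band where an interior optimum
#' exists with positive growth (regimes II/III) — the narrow corridor where
#' viruses shape receptor allocation without destroying the lineage.
#'
#' @param b_over_a Grid of \eqn{B/A} values.
#' @param c_values Grid of \eqn{C} values.
#' @param out_dir Output directory, or `NULL`.
#' @return A tibble `(b_over_a, c_value, regime)` with attribute
#'   `band_width` (tibble of `b_over_a`, `band_width_log10C`).
#' @export
cmd_regime_map <- function(b_over_a = 10^seq(-3, 2, length.out = 41),
                           c_values = 10^seq(-4, 1, length.out = 41),
                           out_dir = NULL) {
  if (length(b_over_a) == 0 || length(c_values) == 0) {
    stop("empty grid", call. = FALSE)
  }
  grid <- tidyr::expand_grid(b_over_a = b_over_a, c_value = c_values)
  grid$regime <- regime_from_coefficients(1, grid$b_over_a, grid$c_value,
                                          n_grid = 400L)
  band <- grid |>
    dplyr::filter(.data$regime %in% c("II", "III")) |>
    dplyr::group_by(.data$b_over_a) |>
    dplyr::summarise(band_width_log10C = diff(range(log10(.data$c_value))),
                     .groups = "drop")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(grid, file.path(out_dir, "regime_map.csv"))
    ggplot2::ggsave(file.path(out_dir, "regime_map.png"),
                    plot_regime_map(grid), width = 7, height = 5, dpi = 150)
  }
  attr(grid, "band_width") <- band
  grid
}

#' @rdname cmd_regime_map
#' @param grid Output of `cmd_regime_map()`.
#' @export
plot_regime_map <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$b_over_a, y = .data$c_value,
                                     fill = .data$regime)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "B/A", y = "C", fill = "regime",
                  title = "Viral-pressure regimes") +
    ggplot2::theme_minimal()
}

#' Validate the walk simulator against the analytic invasion law
#'
#' Runs the Monte-Carlo vs closed-form comparison suite: (i) two-term
#' mixture vs the radial-walk empirical CDF inside its small-time window;
#' (ii) the unreflected (\eqn{b \to \infty}) limit vs the single-term Levy
#' CDF — the clean case where the analytic law is exact; (iii) a dt-halving
#' self-convergence check on the median first-passage time.
#'
#' @param seed Integer seed.
#' @param n_walkers Walkers per check.
#' @param out_dir Output directory, or `NULL`.
#' @return A tibble `(check, statistic, tolerance, pass)` with attribute
#'   `pass_all`.
#' @export
cmd_validate_fpt <- function(seed = 1, n_walkers = 4000, out_dir = NULL) {
  a <- 1e-6; b <- 5e-6; kr <- 1e-13
  # two-term mixture inside its small-time window, started in the outer bulk
  gamma <- 0.9 * b
  t_win <- 0.1 * (b - a)^2 / kr
  cfg <- walk_config(a_eta = a, b = b, kappa_radial = kr, t_max = t_win,
                     n_walkers = n_walkers, seed = seed)
  ens <- simulate_radial_fpt(cfg, gamma)
  d_mix <- walk_cdf_distance(ens)

  # unreflected limit: reflecting shell pushed out of reach, closer start so
  # that most walkers are absorbed; the single-term Levy law is exact here
  gamma_near <- 2.5e-6
  t_far <- 0.25 * (b - a)^2 / kr
  b_far <- a + 40 * sqrt(kr * t_far)
  cfg_far <- walk_config(a_eta = a, b = b_far, kappa_radial = kr,
                         t_max = t_far, n_walkers = n_walkers,
                         seed = seed + 1, dt = cfg$dt)
  ens_far <- simulate_radial_fpt(cfg_far, gamma_near)
  d_single <- walk_cdf_distance(ens_far, single_term = TRUE)

  # dt-halving self-convergence of the median first-passage time, coupled
  # on common Brownian paths so the statistic isolates discretisation error
  d_conv <- fpt_convergence_check(a, b_far, kr, gamma_near, t_max = 10,
                                  n_walkers = 3000, dt = cfg$dt / 2,
                                  seed = seed + 2)

  out <- tibble::tibble(
    check = c("two_term_mixture_sup_distance",
              "single_term_limit_sup_distance",
              "dt_halving_median_change"),
    statistic = c(d_mix, d_single, d_conv),
    tolerance = c(0.02, 0.015, 0.02)
  )
  out$pass <- out$statistic < out$tolerance
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out, file.path(out_dir, "validate_fpt.csv"))
  }
  attr(out, "pass_all") <- all(out$pass)
  out
}

#' Total replication probability along parameter grids
#'
#' Scans \eqn{P_r = p_r^{n_\beta}} along a grid of one parameter, reporting
#' both the first-principles path (exact quadrature \eqn{p_r}) and the
#' two-digit as-printed closed form, clearly labelled.
#'
#' @param params A single-row parameter data frame (the baseline).
#' @param target Parameter to vary.
#' @param grid Values for `target`.
#' @param out_dir Output directory, or `NULL`.
#' @return A tibble `(parameter, value, P_r_exact, P_r_printed)`.
#' @export
cmd_replication_prob <- function(params, target, grid, out_dir = NULL) {
  stopifnot(is.data.frame(params), nrow(params) == 1)
  rows <- purrr::map(grid, function(v) {
    p <- params
    p[[target]] <- v
    ex <- total_replication_prob(p, method = "exact")
    pr <- total_replication_prob(p, method = "printed")
    tibble::tibble(parameter = target, value = v,
                   P_r_exact = ex$P_r, P_r_printed = pr$P_r)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out, file.path(out_dir,
                                    paste0("replication_prob_", target,
                                           ".csv")))
    ggplot2::ggsave(file.path(out_dir,
                              paste0("replication_prob_", target, ".png")),
                    plot_replication_prob(out), width = 7, height = 5,
                    dpi = 150)
  }
  out
}

#' @rdname cmd_replication_prob
#' @param scan Output of `cmd_replication_prob()`.
#' @export
plot_replication_prob <- function(scan) {
  long <- tidyr::pivot_longer(scan, c("P_r_exact", "P_r_printed"),
                              names_to = "path", values_to = "P_r")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$P_r,
                                     colour = .data$path)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = unique(scan$parameter), y = expression(P[r]),
                  colour = NULL,
                  title = "Total replication probability") +
    ggplot2::theme_minimal()
}

#' Run a lineage-simulation strategy race and write its tables
#'
#' Thin wrapper over [compare_strategies()] that writes the ranking table
#' and per-generation trajectories of the winning strategy.
#'
#' @param params A single-row parameter data frame.
#' @param rho_values Receptor efficiencies to race.
#' @param seed Integer seed.
#' @param out_dir Output directory, or `NULL`.
#' @param ... Passed to [simulate_lineages()].
#' @return The ranking tibble of [compare_strategies()].
#' @export
cmd_lineage_sim <- function(params, rho_values, seed = 1, out_dir = NULL,
                            ...) {
  ranking <- compare_strategies(params, rho_values, seed = seed, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(ranking, file.path(out_dir, "strategy_ranking.csv"))
    best <- params
    best$rho <- ranking$rho[1]
    traj <- tidy(simulate_lineages(best, seed = seed, ...))
    readr::write_csv(traj, file.path(out_dir, "lineage_trajectories.csv"))
  }
  ranking
}

#' Sample parameter sets and write them as CSV
#'
#' @param n Number of sets.
#' @param seed Integer seed.
#' @param out_dir Output directory, or `NULL`.
#' @return The sampled parameter tibble.
#' @export
cmd_sample_params <- function(n, seed, out_dir = NULL) {
  out <- sample_parameters(n, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_params_csv(out, file.path(out_dir, "parameter_samples.csv"))
  }
  out
}
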