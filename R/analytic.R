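#' Derived physical scales and growth-rate coefficients
#'
#' Augments a table of parameter sets with every derived quantity of the
#' model, computed from the definitional formulas at full precision (the
#' two-digit constants often quoted for them are never used internally):
#'
#' \describe{
#'   \item{uptake_rate}{Diffusion-limited nutrient uptake
#'     \eqn{I = 4\pi\rho\,a_\eta\kappa_\nu c_\nu}, fg s^-1.}
#'   \item{tau_r}{Replication timescale \eqn{\tau_r = q/I}, s.}
#'   \item{b}{Dining-sphere radius \eqn{b = (5/18)\,c_\eta^{-1/3}}, m — half
#'     the mean nearest-neighbour host spacing.}
#'   \item{kappa_radial}{Projected radial viral diffusivity
#'     \eqn{\varkappa_\beta = (1-2/\pi)^2 \kappa_\beta}, m^2 s^-1.}
#'   \item{n_beta}{Expected viruses engaging the host,
#'     \eqn{n_\beta = (4\pi/3)\rho\,c_\beta b^3} (receptor thinning folded in
#'     as the factor \eqn{\rho}).}
#'   \item{coef_A}{Virus-free growth coefficient
#'     \eqn{A = 4\pi \ln 2\, \kappa_\nu c_\nu a_\eta / q}, s^-1.}
#'   \item{coef_B}{Viral-pressure coefficient
#'     \eqn{B = (0.08977/\ln 2)\, A\, c_\beta/c_\eta}, s^-1.}
#'   \item{coef_C}{Dimensionless invasion coefficient entering the logarithm
#'     of \eqn{\mu = A\rho + B\rho^2 \ln(1 - C\rho^{-1/2})}.}
#'   \item{small_time_valid}{Whether the small-time validity condition
#'     \eqn{(b-a_\eta)/\sqrt{\varkappa_\beta\tau_r} \ge 2} holds.}
#' }
#'
#' @param params Data frame of parameter sets (see [param_set()]).
#' @param validate Validate rows first (hard violations raise an error).
#' @return `params` with the derived columns appended.
#' @examples
#' derive_quantities(param_set())
#' @export
derive_quantities <- function(params, validate = TRUE) {
  stopifnot(is.data.frame(params))
  if (validate) {
    bad <- validate_params(params, warn = FALSE)
    bad <- bad[bad$severity == "error", , drop = FALSE]
    if (nrow(bad) > 0) {
      stop("invalid parameter set:\n  ",
           paste(bad$message, collapse = "\n  "), call. = FALSE)
    }
  }
  dplyr::mutate(
    tibble::as_tibble(params),
    uptake_rate = 4 * pi * .data$rho * .data$a_eta * .data$kappa_nu * .data$c_nu,
    tau_r = .data$q / .data$uptake_rate,
    b = (5 / 18) * .data$c_eta^(-1 / 3),
    kappa_radial = colim_constants$radial_projection * .data$kappa_beta,
    n_beta = (4 * pi / 3) * .data$rho * .data$c_beta * .data$b^3,
    coef_A = 4 * pi * log(2) * .data$kappa_nu * .data$c_nu * .data$a_eta / .data$q,
    coef_B = colim_constants$b_over_a_prefactor * .data$coef_A *
      .data$c_beta / .data$c_eta,
    coef_C = colim_constants$c_coef_prefactor * .data$a_eta^(3 / 2) *
      sqrt((.data$kappa_beta / .data$kappa_nu) * (.data$q / .data$c_nu)) /
      (.data$b^3 - .data$a_eta^3),
    small_time_valid = (.data$b - .data$a_eta) /
      sqrt(.data$kappa_radial * .data$tau_r) >= 2
  )
}

with_derived <- function(params) {
  if (!all(c("tau_r", "b", "kappa_radial", "n_beta", "coef_A") %in%
             names(params))) {
    params <- derive_quantities(params)
  }
  params
}

#' Replication probability for a single engaged virus
#'
#' Probability \eqn{p_r} that a host whose dining sphere contains a single
#' virus replicates before that virus reaches its surface:
#' \eqn{p_r = 1 - E_\gamma[\mathrm{CDF}(\tau_r \mid \gamma)]}, where the start
#' radius \eqn{\gamma} is uniform in shell volume (density
#' \eqn{3\gamma^2/(b^3 - a_\eta^3)}) and the invasion-time CDF is the
#' two-term Levy mixture of [fpt_law()].
#'
#' Three evaluation paths are exposed:
#' \describe{
#'   \item{`"exact"`}{Adaptive quadrature of the \eqn{\gamma}-average of the
#'     mixture CDF (default).}
#'   \item{`"approx"`}{The small-time closed form
#'     \eqn{p_r \approx 1 - K a_\eta^2 \sqrt{\varkappa_\beta \tau_r}/(b^3 -
#'     a_\eta^3)}. The default `constant` \eqn{K = 3/\sqrt{2\pi}} is the
#'     leading coefficient of the small-time series of the exact average (so
#'     the two paths agree as \eqn{\tau_r \to 0}); any other prefactor may be
#'     supplied.}
#'   \item{`"printed"`}{The two-digit form conventionally quoted,
#'     \eqn{1 - 0.93\, a_\eta^2 \sqrt{\kappa_\beta \tau_r} / ((5/18)^3
#'     c_\eta^{-1} - a_\eta^3)} (note: unprojected \eqn{\kappa_\beta}).}
#' }
#' Approximate paths are clipped to \[0, 1\]. The small-time validity flag
#' `small_time_valid` (\eqn{(b-a_\eta)/\sqrt{\varkappa_\beta\tau_r} \ge 2})
#' is attached; violation is flagged, not an error.
#'
#' @param params Data frame of parameter sets.
#' @param method `"exact"`, `"approx"` or `"printed"`.
#' @param constant Prefactor for `method = "approx"`; default
#'   `colim_constants$pr_series_constant`.
#' @return `params` with derived columns plus `p_r`.
#' @examples
#' replication_prob(param_set(), method = "exact")
#' @export
replication_prob <- function(params,
                             method = c("exact", "approx", "printed"),
                             constant = NULL) {
  method <- match.arg(method)
  dq <- with_derived(params)
  p_r <- switch(
    method,
    exact = purrr::pmap_dbl(
      list(dq$a_eta, dq$b, dq$kappa_radial, dq$tau_r),
      pr_exact_one
    ),
    approx = {
      k <- if (is.null(constant)) colim_constants$pr_series_constant else constant
      pmin(pmax(
        1 - k * dq$a_eta^2 * sqrt(dq$kappa_radial * dq$tau_r) /
          (dq$b^3 - dq$a_eta^3), 0), 1)
    },
    printed = pmin(pmax(
      1 - 0.93 * dq$a_eta^2 * sqrt(dq$kappa_beta * dq$tau_r) /
        ((5 / 18)^3 / dq$c_eta - dq$a_eta^3), 0), 1)
  )
  dq$p_r <- p_r
  dq
}

pr_exact_one <- function(a_eta, b, kappa_radial, tau_r) {
  if (tau_r <= 0) return(1)
  integrand <- function(gamma) {
    law <- fpt_law(gamma, a_eta, b, kappa_radial)
    3 * gamma^2 / (b^3 - a_eta^3) * invasion_time_cdf(law, tau_r)
  }
  val <- tryCatch(
    stats::integrate(integrand, a_eta, b, rel.tol = 1e-9,
                     abs.tol = 1e-12, subdivisions = 500L)$value,
    error = function(e) {
      stop("quadrature for p_r failed (a = ", format(a_eta), ", b = ",
           format(b), ", kappa_radial = ", format(kappa_radial),
           ", tau_r = ", format(tau_r), "): ", conditionMessage(e),
           call. = FALSE)
    }
  )
  min(max(1 - val, 0), 1)
}

#' Total replication probability over all engaged viruses
#'
#' Viral trajectories are independent, so the probability that the host
#' replicates before *any* virus invades is \eqn{P_r = p_r^{n_\beta}} with
#' \eqn{n_\beta = (4\pi/3)\rho c_\beta b^3} the expected number of viruses in
#' the dining sphere (thinned by receptor efficiency). `method` selects the
#' \eqn{p_r} path of [replication_prob()]; `"printed"` uses the two-digit
#' closed form throughout.
#'
#' @inheritParams replication_prob
#' @param method `"exact"`, `"approx"` or `"printed"`.
#' @return `params` with derived columns plus `p_r` and `P_r`.
#' @examples
#' total_replication_prob(param_set())
#' @export
total_replication_prob <- function(params,
                                   method = c("exact", "approx", "printed"),
                                   constant = NULL) {
  method <- match.arg(method)
  dq <- replication_prob(params, method = method, constant = constant)
  dq$P_r <- ifelse(dq$n_beta == 0, 1, dq$p_r^dq$n_beta)
  dq
}

#' Growth rate from the frozen-coefficient form
#'
#' Evaluates \eqn{\mu(\rho) = A\rho + B\rho^2 \ln(1 - C\rho^{-1/2})}.
#' Where the logarithm's argument is nonpositive the lineage cannot survive
#' (an engaged virus is effectively certain to invade) and \eqn{\mu = -\infty}
#' is returned as a sentinel rather than clipping — this keeps optimisation
#' over \eqn{\rho} honest about the nonviable region.
#'
#' @param A Virus-free growth coefficient, s^-1.
#' @param B Viral-pressure coefficient, s^-1.
#' @param C Dimensionless invasion coefficient.
#' @param rho Receptor efficiency values in (0, 1\].
#' @return Growth rate(s), s^-1 (possibly `-Inf`). Vectorised over all
#'   arguments.
#' @export
mu_from_coefficients <- function(A, B, C, rho) {
  arg <- 1 - C / sqrt(rho)
  ifelse(arg > 0, A * rho + B * rho^2 * log(pmax(arg, .Machine$double.xmin)),
         -Inf)
}

#' Individual-lineage growth rate under virus-nutrient co-limitation
#'
#' The expected long-run growth rate of an individual host's lineage when a
#' replication event is a doubling that happens only if none of the
#' \eqn{n_\beta} engaged viruses arrives within \eqn{\tau_r}:
#' \deqn{\mu = \frac{1}{\tau_r}\left(\ln 2 + n_\beta \ln p_r\right).}
#' The first term is the virus-free doubling rate \eqn{A\rho}; the second,
#' always nonpositive, is the viral depression of growth.
#'
#' Evaluation paths:
#' \describe{
#'   \item{`"compositional"`}{The definition above with the exact quadrature
#'     \eqn{p_r} (default).}
#'   \item{`"coefficients"`}{\eqn{\mu = A\rho + B\rho^2\ln(1 - C\rho^{-1/2})}
#'     with full-precision coefficients (the small-time \eqn{p_r} composed
#'     through the same definition).}
#'   \item{`"printed"`}{The two-significant-digit closed form
#'     \eqn{\mu = \frac{4\pi\kappa_\nu c_\nu a_\eta \rho}{q}\left(.69 +
#'     .089\rho\frac{c_\beta}{c_\eta} \ln(1 - .13[\cdots]\sqrt{a_\nu q /
#'     (a_\beta c_\nu \rho)})\right)}, using the literal printed constants.}
#' }
#' If the survival probability vanishes (log argument \eqn{\le 0}), `mu` is
#' `-Inf` and the row is Regime IV-degenerate.
#'
#' @param params Data frame of parameter sets.
#' @param method Evaluation path, see Details.
#' @param classify Add the Regime I-IV label via [classify_regime()]?
#' @param optimize Add `rho_star`/`mu_star` via [optimize_rho()]?
#' @return `params` with derived columns plus `p_r`, `P_r`, `mu`, and
#'   optionally `regime`, `rho_star`, `mu_star`.
#' @examples
#' growth_rate(param_set(c_beta = 0), classify = FALSE)
#' @export
growth_rate <- function(params,
                        method = c("compositional", "coefficients", "printed"),
                        classify = TRUE,
                        optimize = FALSE) {
  method <- match.arg(method)
  dq <- switch(
    method,
    compositional = total_replication_prob(params, method = "exact"),
    coefficients  = total_replication_prob(params, method = "approx"),
    printed       = total_replication_prob(params, method = "printed")
  )
  dq$mu <- switch(
    method,
    compositional = ,
    coefficients = {
      viral <- ifelse(dq$n_beta == 0, 0,
                      ifelse(dq$p_r > 0, dq$n_beta * log(dq$p_r), -Inf))
      (log(2) + viral) / dq$tau_r
    },
    printed = {
      b3 <- (5 / 18)^3 / dq$c_eta - dq$a_eta^3
      inner <- 1 - 0.13 * (dq$a_eta^(3 / 2) / b3) *
        sqrt(dq$a_nu * dq$q / (dq$a_beta * dq$c_nu * dq$rho))
      pre <- 4 * pi * dq$kappa_nu * dq$c_nu * dq$a_eta * dq$rho / dq$q
      ifelse(inner > 0,
             pre * (0.69 + 0.089 * dq$rho * (dq$c_beta / dq$c_eta) *
                      log(pmax(inner, .Machine$double.xmin))),
             -Inf)
    }
  )
  if (classify) {
    dq$regime <- regime_from_coefficients(dq$coef_A, dq$coef_B, dq$coef_C)
  }
  if (optimize) {
    opt <- purrr::pmap(list(dq$coef_A, dq$coef_B, dq$coef_C),
                       optimize_rho_coef)
    dq$rho_star <- purrr::map_dbl(opt, "rho_star")
    dq$mu_star <- purrr::map_dbl(opt, "mu_star")
  }
  dq
}

#' Optimal receptor efficiency
#'
#' Maximises \eqn{\mu(\rho) = A\rho + B\rho^2\ln(1 - C\rho^{-1/2})} over
#' \eqn{\rho \in (\rho_{min}, 1]} for each parameter set: a coarse grid over
#' the viable region (\eqn{\rho > C^2}, where the log argument is positive)
#' locates the basin, bounded scalar maximisation refines it to `tol`, and
#' ties are broken toward larger \eqn{\rho}. When no viable \eqn{\rho}
#' exists (\eqn{C \ge 1}) the optimum is reported as `NA` with
#' `mu_star = -Inf` (Regime IV).
#'
#' @param params Data frame of parameter sets.
#' @param rho_min Lower end of the search interval (default 1e-3).
#' @param tol Absolute tolerance in `rho`.
#' @param method `"coefficients"` (default) maximises the closed form
#'   \eqn{A\rho + B\rho^2\ln(1-C\rho^{-1/2})}; `"compositional"` maximises
#'   the exact-quadrature growth rate, which can place the optimum at a
#'   lower \eqn{\rho} when long replication timescales stretch the
#'   small-time approximation underlying the coefficients.
#' @return `params` with derived columns plus `rho_star` and `mu_star`.
#' @examples
#' optimize_rho(param_set(c_beta = 1e7))
#' @export
optimize_rho <- function(params, rho_min = 1e-3, tol = 1e-6,
                         method = c("coefficients", "compositional")) {
  method <- match.arg(method)
  dq <- with_derived(params)
  opt <- if (method == "coefficients") {
    purrr::pmap(list(dq$coef_A, dq$coef_B, dq$coef_C),
                optimize_rho_coef, rho_min = rho_min, tol = tol)
  } else {
    purrr::map(seq_len(nrow(dq)), function(i) {
      f <- function(rho) {
        pp <- dq[i, PARAM_COLS]
        pp$rho <- rho
        growth_rate(pp, method = "compositional", classify = FALSE)$mu
      }
      grid <- seq(rho_min, 1, length.out = 33L)
      vals <- vapply(grid, f, numeric(1))
      k <- which.max(vals)
      best <- stats::optimize(f, lower = grid[max(k - 1L, 1L)],
                              upper = grid[min(k + 1L, 33L)],
                              maximum = TRUE, tol = tol)
      if (f(1) >= best$objective) {
        list(rho_star = 1, mu_star = f(1))
      } else {
        list(rho_star = best$maximum, mu_star = best$objective)
      }
    })
  }
  dq$rho_star <- purrr::map_dbl(opt, "rho_star")
  dq$mu_star <- purrr::map_dbl(opt, "mu_star")
  dq
}

#' @rdname optimize_rho
#' @param A,B,C Growth-rate coefficients (see [derive_quantities()]).
#' @export
optimize_rho_coef <- function(A, B, C, rho_min = 1e-3, tol = 1e-6) {
  lo <- max(rho_min, C^2 * (1 + 1e-9))
  if (lo >= 1 || !is.finite(mu_from_coefficients(A, B, C, 1))) {
    return(list(rho_star = NA_real_, mu_star = -Inf))
  }
  f <- function(rho) mu_from_coefficients(A, B, C, rho)
  grid <- seq(lo, 1, length.out = 512L)
  vals <- f(grid)
  i <- which.max(vals)
  lower <- grid[max(i - 1L, 1L)]
  upper <- grid[min(i + 1L, length(grid))]
  best <- if (upper > lower) {
    stats::optimize(f, lower = lower, upper = upper, maximum = TRUE,
                    tol = min(tol, 1e-8))
  } else {
    list(maximum = grid[i], objective = vals[i])
  }
  rho_star <- best$maximum
  mu_star <- best$objective
  # ties (and monotone cases) break toward the larger rho
  mu_one <- f(1)
  if (mu_one >= mu_star - 1e-12 * max(abs(mu_star), abs(mu_one), A)) {
    rho_star <- 1
    mu_star <- mu_one
  }
  list(rho_star = rho_star, mu_star = mu_star)
}

#' Classify the viral-pressure regime
#'
#' Assigns each parameter set to one of the four qualitative regimes of the
#' growth-rate curve \eqn{\mu(\rho)} on \eqn{(\rho_{min}, 1]}:
#' \describe{
#'   \item{I}{Viruses negligible: the optimum sits at \eqn{\rho = 1} with
#'     positive growth (\eqn{\mu \approx A\rho}).}
#'   \item{II}{Virus-abundance-driven interior optimum: \eqn{\rho^* < 1}
#'     with \eqn{B \ge A} (locally many viruses per host).}
#'   \item{III}{Host-aggregation-driven interior optimum: \eqn{\rho^* < 1}
#'     with \eqn{B < A} but \eqn{C = O(1)} or larger.}
#'   \item{IV}{Grazed: \eqn{\mu \le 0} on at least `negative_fraction` of the
#'     \eqn{\rho} grid, or no \eqn{\rho} yields positive growth — the lineage
#'     is drawn down to a seed population.}
#' }
#' The thresholds are package choices (documented, configurable): the
#' interior-optimum test itself operationalises "C not particularly
#' large/small", and `negative_fraction = 0.95` operationalises "negative for
#' nearly all \eqn{\rho}".
#'
#' @param params Data frame of parameter sets.
#' @param n_grid Number of uniform \eqn{\rho} grid points.
#' @param rho_min Lower end of the grid.
#' @param negative_fraction Fraction of nonpositive grid values that defines
#'   Regime IV.
#' @return `params` with derived columns plus `regime`.
#' @examples
#' classify_regime(param_set())
#' @export
classify_regime <- function(params, n_grid = 1000L, rho_min = 1e-3,
                            negative_fraction = 0.95) {
  dq <- with_derived(params)
  dq$regime <- regime_from_coefficients(
    dq$coef_A, dq$coef_B, dq$coef_C,
    n_grid = n_grid, rho_min = rho_min,
    negative_fraction = negative_fraction
  )
  dq
}

#' @rdname classify_regime
#' @param A,B,C Growth-rate coefficients, vectorised.
#' @export
regime_from_coefficients <- function(A, B, C, n_grid = 1000L, rho_min = 1e-3,
                                     negative_fraction = 0.95) {
  n <- max(length(A), length(B), length(C))
  A <- rep_len(A, n); B <- rep_len(B, n); C <- rep_len(C, n)
  rho <- seq(rho_min, 1, length.out = n_grid)
  vapply(seq_len(n), function(i) {
    mu <- mu_from_coefficients(A[i], B[i], C[i], rho)
    if (mean(mu <= 0) >= negative_fraction) return("IV")
    opt <- optimize_rho_coef(A[i], B[i], C[i], rho_min = rho_min)
    if (!is.finite(opt$mu_star) || opt$mu_star <= 0) return("IV")
    if (opt$rho_star < 1 - 1e-6) {
      if (B[i] >= A[i]) "II" else "III"
    } else {
      "I"
    }
  }, character(1))
}

#' Sensitivity of the model along one parameter
#'
#' Recomputes the growth rate, replication probabilities and regime along a
#' grid of values for a single parameter, holding the rest of `params`
#' fixed. Rows whose value violates a hard physical invariant are flagged
#' invalid and left `NA` rather than aborting the scan.
#'
#' @param params A single-row data frame of parameter sets (the baseline).
#' @param target Name of the parameter to vary (a [param_set()] column).
#' @param grid Numeric vector of values for `target`.
#' @param method Growth-rate path passed to [growth_rate()].
#' @return A tibble with columns `parameter`, `value`, `mu`, `p_r`, `P_r`,
#'   `regime`, `valid`.
#' @examples
#' sensitivity_report(param_set(), "c_beta", c(1e8, 1e9, 1e10))
#' @export
sensitivity_report <- function(params, target, grid,
                               method = "compositional") {
  stopifnot(is.data.frame(params), nrow(params) == 1)
  if (!target %in% PARAM_COLS) {
    stop("`target` must be one of: ", paste(PARAM_COLS, collapse = ", "),
         call. = FALSE)
  }
  rows <- purrr::map(grid, function(v) {
    p <- params
    p[[target]] <- v
    hard <- validate_params(p, warn = FALSE)
    hard <- hard[hard$severity == "error", , drop = FALSE]
    if (nrow(hard) > 0) {
      return(tibble::tibble(parameter = target, value = v,
                            mu = NA_real_, p_r = NA_real_, P_r = NA_real_,
                            regime = NA_character_, valid = FALSE))
    }
    g <- growth_rate(p, method = method)
    tibble::tibble(parameter = target, value = v, mu = g$mu,
                   p_r = g$p_r, P_r = g$P_r, regime = g$regime, valid = TRUE)
  })
  dplyr::bind_rows(rows)
}
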