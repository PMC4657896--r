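#' Configuration for a first-passage random-walk ensemble
#'
#' Describes a walk between an absorbing host surface at radius `a_eta` and a
#' reflecting dining-sphere boundary at `b`. The time step must satisfy
#' \eqn{\sqrt{\varkappa\,dt} \le (b - a_\eta)/100} so that a single step
#' cannot straddle the geometry; by default `dt` sits exactly at that bound
#' divided by `dt_refine`.
#'
#' @param a_eta Absorbing radius, m.
#' @param b Reflecting radius, m.
#' @param kappa_radial Radial (1-d projected) diffusivity, m^2 s^-1. For
#'   `mode = "full-3d"` the per-axis diffusivity is
#'   `kappa_radial / (1 - 2/pi)^2` unless `kappa_3d` is given, so that the two
#'   modes describe the same physical virus.
#' @param t_max Censoring horizon, s.
#' @param n_walkers Ensemble size (>= 1).
#' @param seed Integer seed.
#' @param dt Time step, s; default `(b - a_eta)^2 / (100^2 dt_refine^2) /
#'   kappa_radial`.
#' @param dt_refine Refinement factor applied to the default `dt` (used by
#'   convergence checks).
#' @param drift Radial drift, m s^-1 (negative = toward the host); default 0.
#' @param mode `"radial-1d"` or `"full-3d"`.
#' @param kappa_3d Per-axis 3-d diffusivity, m^2 s^-1 (optional).
#' @return A `walk_config` list.
#' @seealso [simulate_radial_fpt()], [simulate_3d_fpt()]
#' @export
walk_config <- function(a_eta, b, kappa_radial, t_max, n_walkers, seed,
                        dt = NULL, dt_refine = 1, drift = 0,
                        mode = c("radial-1d", "full-3d"), kappa_3d = NULL) {
  mode <- match.arg(mode)
  stopifnot(a_eta > 0, b > a_eta, kappa_radial > 0, t_max > 0, n_walkers >= 1)
  kappa_step <- if (mode == "full-3d") {
    if (is.null(kappa_3d)) kappa_radial / colim_constants$radial_projection
    else kappa_3d
  } else {
    kappa_radial
  }
  if (is.null(dt)) {
    dt <- ((b - a_eta) / (100 * dt_refine))^2 / kappa_step
  }
  if (sqrt(kappa_step * dt) > (b - a_eta) / 100 * (1 + 1e-12)) {
    stop("dt too coarse: need sqrt(kappa * dt) <= (b - a_eta)/100",
         call. = FALSE)
  }
  structure(
    list(a_eta = a_eta, b = b, kappa_radial = kappa_radial,
         kappa_3d = if (mode == "full-3d") kappa_step else NULL,
         dt = dt, t_max = t_max, n_walkers = as.integer(n_walkers),
         seed = as.integer(seed), drift = drift, mode = mode),
    class = "walk_config"
  )
}

# One L'Ecuyer-CMRG substream per walker, resumable across time blocks, so
# walker k's increments do not depend on n_walkers or on other walkers.
make_streams <- function(seed, n) {
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  s <- get(".Random.seed", envir = globalenv())
  states <- matrix(0L, nrow = 7L, ncol = n)
  for (k in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    states[, k] <- s
  }
  states
}

# draw n N(0,1) deviates from walker k's substream, advancing its state
stream_rnorm <- function(states, k, n) {
  assign(".Random.seed", states[, k], envir = globalenv())
  x <- stats::rnorm(n)
  list(x = x, state = get(".Random.seed", envir = globalenv()))
}

new_walk_ensemble <- function(times, censored, gamma, config) {
  structure(
    list(times = times, censored = censored, gamma = gamma, config = config),
    class = "colim_walk"
  )
}

#' Simulate radial first-passage times
#'
#' Euler-Maruyama simulation of the projected 1-d radial walk of
#' [fpt_law()]: Gaussian increments of variance `kappa_radial * dt`
#' (variance-rate convention, matching the analytic Levy parameterisation),
#' absorption on the first step crossing below `a_eta` (time recorded at the
#' crossing step), mirror reflection above `b`, censoring at `t_max`.
#' Deterministic given `(config, gamma)`.
#'
#' @param config A [walk_config()] with `mode = "radial-1d"`.
#' @param gamma Start radius, m; scalar or one value per walker, in
#'   `[a_eta, b]`.
#' @return A `colim_walk` ensemble; see [tidy.colim_walk()],
#'   [glance.colim_walk()], [autoplot.colim_walk()].
#' @examples
#' cfg <- walk_config(a_eta = 1e-6, b = 5e-6, kappa_radial = 1e-13,
#'                    t_max = 10, n_walkers = 100, seed = 1)
#' ens <- simulate_radial_fpt(cfg, gamma = 3e-6)
#' glance(ens)
#' @export
simulate_radial_fpt <- function(config, gamma) {
  stopifnot(inherits(config, "walk_config"), config$mode == "radial-1d")
  n <- config$n_walkers
  gamma <- rep_len(gamma, n)
  if (any(gamma < config$a_eta) || any(gamma > config$b)) {
    stop("`gamma` must lie in [a_eta, b]", call. = FALSE)
  }
  withr::local_preserve_seed()
  a <- config$a_eta; b <- config$b; dt <- config$dt
  sd_step <- sqrt(config$kappa_radial * dt)
  drift_step <- config$drift * dt
  n_steps <- ceiling(config$t_max / dt)
  fpt <- rep(NA_real_, n)
  fpt[gamma <= a] <- 0
  alive <- which(is.na(fpt))
  pos <- gamma
  states <- make_streams(config$seed, n)
  block <- 256L
  done <- 0L
  while (done < n_steps && length(alive) > 0) {
    steps <- min(block, n_steps - done)
    inc <- matrix(0, nrow = length(alive), ncol = steps)
    for (k in seq_along(alive)) {
      d <- stream_rnorm(states, alive[k], steps)
      inc[k, ] <- d$x
      states[, alive[k]] <- d$state
    }
    p <- pos[alive]
    live <- seq_along(alive)
    for (j in seq_len(steps)) {
      p[live] <- p[live] + drift_step + sd_step * inc[live, j]
      hit <- live[p[live] <= a]
      if (length(hit) > 0) {
        fpt[alive[hit]] <- (done + j) * dt
        live <- setdiff(live, hit)
        if (length(live) == 0) break
      }
      over <- live[p[live] > b]
      if (length(over) > 0) p[over] <- 2 * b - p[over]
    }
    pos[alive] <- p
    alive <- alive[live]
    done <- done + steps
  }
  censored <- is.na(fpt)
  fpt[censored] <- config$t_max
  new_walk_ensemble(fpt, censored, gamma, config)
}

#' Simulate 3-d Brownian first-passage times
#'
#' Full 3-d isotropic walk around the spherical absorber: per-axis Gaussian
#' increments of variance `kappa_3d * dt`, absorption on `|x| <= a_eta`,
#' radial mirror reflection at `b`. This is the reference against which the
#' quality of the 1-d radial projection (and its \eqn{(1-2/\pi)^2}
#' diffusivity factor) is quantified.
#'
#' @param config A [walk_config()] with `mode = "full-3d"`.
#' @param start Start position: a length-3 vector, an `n_walkers` x 3 matrix,
#'   or a scalar start radius (placed on the x-axis).
#' @return A `colim_walk` ensemble (the `gamma` field holds start radii).
#' @export
simulate_3d_fpt <- function(config, start) {
  stopifnot(inherits(config, "walk_config"), config$mode == "full-3d")
  n <- config$n_walkers
  if (is.matrix(start)) {
    stopifnot(ncol(start) == 3)
    pos <- matrix(rep_len(t(start), 3 * n), ncol = 3, byrow = TRUE)
  } else if (length(start) == 3) {
    pos <- matrix(rep(start, each = n), ncol = 3)
  } else {
    pos <- cbind(rep_len(start, n), 0, 0)
  }
  r0 <- sqrt(rowSums(pos^2))
  if (any(r0 < config$a_eta - 1e-12 * config$a_eta) || any(r0 > config$b)) {
    stop("|start| must lie in [a_eta, b]", call. = FALSE)
  }
  withr::local_preserve_seed()
  a <- config$a_eta; b <- config$b; dt <- config$dt
  sd_step <- sqrt(config$kappa_3d * dt)
  n_steps <- ceiling(config$t_max / dt)
  fpt <- rep(NA_real_, n)
  fpt[r0 <= a] <- 0
  alive <- which(is.na(fpt))
  states <- make_streams(config$seed, n)
  block <- 128L
  done <- 0L
  while (done < n_steps && length(alive) > 0) {
    steps <- min(block, n_steps - done)
    inc <- array(0, dim = c(length(alive), steps, 3L))
    for (k in seq_along(alive)) {
      d <- stream_rnorm(states, alive[k], 3L * steps)
      inc[k, , ] <- d$x
      states[, alive[k]] <- d$state
    }
    p <- pos[alive, , drop = FALSE]
    live <- seq_along(alive)
    for (j in seq_len(steps)) {
      p[live, ] <- p[live, , drop = FALSE] + sd_step * inc[live, j, ]
      r <- sqrt(rowSums(p[live, , drop = FALSE]^2))
      hit <- which(r <= a)
      if (length(hit) > 0) {
        fpt[alive[live[hit]]] <- (done + j) * dt
        live <- live[-hit]
        if (length(live) == 0) break
        r <- r[-hit]
      }
      over <- which(r > b)
      if (length(over) > 0) {
        idx <- live[over]
        p[idx, ] <- p[idx, , drop = FALSE] * ((2 * b - r[over]) / r[over])
      }
    }
    pos[alive, ] <- p
    alive <- alive[live]
    done <- done + steps
  }
  censored <- is.na(fpt)
  fpt[censored] <- config$t_max
  new_walk_ensemble(fpt, censored, r0, config)
}

#' Coupled dt-halving convergence check
#'
#' Quantifies the Euler discretisation error of the walk: the same Brownian
#' paths are sampled at step `dt` and `dt/2` (the coarse increments are
#' pairwise sums of the fine ones, so the comparison is common-random-number
#' coupled and the difference is almost purely discretisation), and the
#' relative change in the median first-passage time is returned.
#'
#' @param a_eta,b,kappa_radial,gamma Walk geometry as in [fpt_law()].
#' @param t_max Horizon, s.
#' @param n_walkers Paths.
#' @param dt Coarse step, s.
#' @param seed Integer seed.
#' @return Relative change in median FPT between the two resolutions.
#' @export
fpt_convergence_check <- function(a_eta, b, kappa_radial, gamma, t_max,
                                  n_walkers, dt, seed) {
  m <- ceiling(t_max / dt)
  sd_fine <- sqrt(kappa_radial * dt / 2)
  inc <- withr::with_seed(as.integer(seed),
                          matrix(stats::rnorm(n_walkers * 2 * m, sd = sd_fine),
                                 nrow = n_walkers))
  run <- function(steps_mat, step_dt) {
    pos <- rep(gamma, n_walkers)
    fpt <- rep(NA_real_, n_walkers)
    alive <- seq_len(n_walkers)
    for (j in seq_len(ncol(steps_mat))) {
      pos[alive] <- pos[alive] + steps_mat[alive, j]
      hit <- alive[pos[alive] <= a_eta]
      if (length(hit) > 0) {
        fpt[hit] <- j * step_dt
        alive <- setdiff(alive, hit)
        if (length(alive) == 0) break
      }
      over <- alive[pos[alive] > b]
      if (length(over) > 0) pos[over] <- 2 * b - pos[over]
    }
    fpt
  }
  fine <- run(inc, dt / 2)
  coarse_inc <- inc[, seq(1, 2 * m, by = 2), drop = FALSE] +
    inc[, seq(2, 2 * m, by = 2), drop = FALSE]
  coarse <- run(coarse_inc, dt)
  med_f <- stats::median(fine, na.rm = TRUE)
  med_c <- stats::median(coarse, na.rm = TRUE)
  abs(med_f - med_c) / med_c
}

#' Monte-Carlo estimate of the replication probability
#'
#' Estimates \eqn{p_r} by direct simulation: start radii are drawn uniformly
#' in dining-sphere shell volume, each virus performs the projected radial
#' walk, and a trial counts as replication when no absorption occurs before
#' \eqn{\tau_r}. Reports the exact (Clopper-Pearson) 95% binomial interval.
#'
#' @param params Data frame of parameter sets.
#' @param n_trials Walkers per parameter set.
#' @param seed Integer seed.
#' @param dt_refine Time-step refinement factor (see [walk_config()]).
#' @return `params` with derived columns plus `p_r_mc`, `p_r_mc_lo`,
#'   `p_r_mc_hi`, `n_trials`.
#' @export
estimate_pr_mc <- function(params, n_trials = 10000, seed = 1,
                           dt_refine = 1) {
  dq <- with_derived(params)
  res <- purrr::pmap(
    list(dq$a_eta, dq$b, dq$kappa_radial, dq$tau_r, seq_len(nrow(dq))),
    function(a, b, kr, tau_r, i) {
      gamma <- withr::with_seed(as.integer(seed) + i,
                                sample_start_radius(n_trials, a, b))
      cfg <- walk_config(a_eta = a, b = b, kappa_radial = kr,
                         t_max = tau_r, n_walkers = n_trials,
                         seed = as.integer(seed) + 7919L * i,
                         dt_refine = dt_refine)
      ens <- simulate_radial_fpt(cfg, gamma)
      k <- sum(ens$censored)  # no invasion before tau_r => replication
      ci <- stats::binom.test(k, n_trials)$conf.int
      tibble::tibble(p_r_mc = k / n_trials, p_r_mc_lo = ci[1],
                     p_r_mc_hi = ci[2], n_trials = n_trials)
    }
  )
  dplyr::bind_cols(dq, dplyr::bind_rows(res))
}

#' Sup-distance between an ensemble's empirical CDF and an analytic law
#'
#' Kolmogorov-Smirnov-style statistic
#' \eqn{\sup_{t \le \tau_{max}} |\hat F(t) - F(t)|} between the empirical
#' first-passage CDF (censored walkers count as not-yet-arrived, which is
#' exact for \eqn{t < t_{max}}) and either the two-term mixture CDF of the
#' ensemble's geometry or, with `single_term = TRUE`, the one-term Levy CDF
#' \eqn{\mathrm{erfc}((\gamma - a)/\sqrt{2\varkappa\tau})} — the unreflected
#' (\eqn{b \to \infty}) limit where the analytic law is exact.
#'
#' @param ensemble A `colim_walk` from [simulate_radial_fpt()].
#' @param tau_max Restrict the comparison to `t <= tau_max` (default: the
#'   ensemble's censoring horizon).
#' @param single_term Compare against the single-term Levy CDF.
#' @return The sup-distance (a single number).
#' @export
walk_cdf_distance <- function(ensemble, tau_max = NULL, single_term = FALSE) {
  stopifnot(inherits(ensemble, "colim_walk"))
  cfg <- ensemble$config
  if (is.null(tau_max)) tau_max <- cfg$t_max
  gamma <- ensemble$gamma
  if (length(unique(gamma)) != 1) {
    stop("analytic comparison needs a common start radius", call. = FALSE)
  }
  gamma <- gamma[1]
  analytic <- function(t) {
    if (single_term) {
      levy_cdf(t, (gamma - cfg$a_eta)^2 / cfg$kappa_radial)
    } else {
      invasion_time_cdf(fpt_law(gamma, cfg$a_eta, cfg$b, cfg$kappa_radial), t)
    }
  }
  n <- length(ensemble$times)
  t_obs <- sort(ensemble$times[!ensemble$censored & ensemble$times <= tau_max])
  if (length(t_obs) == 0) return(analytic(tau_max))
  emp_hi <- seq_along(t_obs) / n
  emp_lo <- c(0, utils::head(emp_hi, -1))
  f <- analytic(t_obs)
  max(abs(emp_hi - f), abs(emp_lo - f),
      abs(length(t_obs) / n - analytic(tau_max)))
}

#' @rdname tidy.colim_walk
#' @export
tidy.colim_walk <- function(x, ...) {
  tibble::tibble(
    walker_id = seq_along(x$times),
    fpt_seconds = x$times,
    censored = x$censored,
    start_radius = x$gamma
  )
}

#' Tidy and summarise walk ensembles
#'
#' `tidy()` returns one row per walker (`walker_id`, `fpt_seconds`,
#' `censored`, `start_radius`); `glance()` returns a one-row summary with
#' quartiles of the uncensored first-passage times and the censored fraction.
#'
#' @param x A `colim_walk` ensemble.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.colim_walk <- function(x, ...) {
  obs <- x$times[!x$censored]
  qs <- if (length(obs) > 0) {
    stats::quantile(obs, c(0.25, 0.5, 0.75), names = FALSE)
  } else {
    rep(NA_real_, 3)
  }
  tibble::tibble(
    n_walkers = length(x$times),
    censored_fraction = mean(x$censored),
    fpt_q25 = qs[1], fpt_median = qs[2], fpt_q75 = qs[3],
    dt = x$config$dt, t_max = x$config$t_max, seed = x$config$seed
  )
}

#' Plot a walk ensemble against its analytic first-passage law
#'
#' Empirical first-passage CDF (censoring handled as not-yet-arrived) with
#' the analytic two-term Levy mixture overlaid, on a log time axis.
#'
#' @param object A `colim_walk` ensemble with a common start radius.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.colim_walk <- function(object, ...) {
  cfg <- object$config
  gamma <- object$gamma[1]
  t_obs <- sort(object$times[!object$censored & object$times > 0])
  emp <- tibble::tibble(t = t_obs, F = seq_along(t_obs) / length(object$times))
  t_lo <- if (length(t_obs) > 0) max(min(t_obs), cfg$dt) else cfg$dt
  grid <- exp(seq(log(t_lo), log(cfg$t_max), length.out = 200))
  law <- fpt_law(gamma, cfg$a_eta, cfg$b, cfg$kappa_radial)
  ana <- tibble::tibble(t = grid, F = invasion_time_cdf(law, grid))
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$t, y = .data$F)) +
    ggplot2::geom_step(ggplot2::aes(colour = "empirical")) +
    ggplot2::geom_line(data = ana, ggplot2::aes(colour = "analytic"),
                       linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "first-passage time (s)", y = "CDF", colour = NULL,
                  title = "Viral invasion-time law: walk vs closed form") +
    ggplot2::theme_minimal()
}

#' @export
print.colim_walk <- function(x, ...) {
  g <- glance(x)
  cat("<colim_walk>", g$n_walkers, "walkers,",
      sprintf("%.1f%% censored,", 100 * g$censored_fraction),
      "median FPT", format(g$fpt_median, digits = 3), "s\n")
  invisible(x)
}
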