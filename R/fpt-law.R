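#' Levy first-passage density
#'
#' Density of the one-sided Levy (stable-1/2) law
#' \eqn{L(h; g^2) = \sqrt{g^2/(2\pi h^3)}\, e^{-g^2/(2h)}}, the hitting-time
#' law of a driftless 1-d Brownian motion started a scaled distance
#' \eqn{g = d/\sqrt{\varkappa}} from an absorbing point (variance-rate
#' convention: the walk has variance \eqn{\varkappa t}).
#'
#' @param h Time, s (> 0). Vectorised.
#' @param g_squared Scale parameter \eqn{g^2 = d^2/\varkappa}, s (> 0).
#' @return Density value(s), s^-1.
#' @examples
#' levy_density(1, 1)  # (2*pi)^(-1/2) * exp(-1/2)
#' @export
levy_density <- function(h, g_squared) {
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("`h` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(g_squared)) || any(g_squared <= 0)) {
    stop("`g_squared` must be strictly positive", call. = FALSE)
  }
  sqrt(g_squared / (2 * pi * h^3)) * exp(-g_squared / (2 * h))
}

#' Levy first-passage CDF
#'
#' \eqn{P(\tau \le h) = \mathrm{erfc}\!\left(\sqrt{g^2/(2h)}\right)}, the
#' complementary-error-function CDF matching [levy_density()].
#'
#' @inheritParams levy_density
#' @return Probability value(s).
#' @export
levy_cdf <- function(h, g_squared) {
  if (any(!is.finite(g_squared)) || any(g_squared <= 0)) {
    stop("`g_squared` must be strictly positive", call. = FALSE)
  }
  h <- as.numeric(h)
  z <- sqrt(g_squared / (2 * pmax(h, .Machine$double.xmin)))
  out <- erfc(z)
  out[h <= 0] <- 0
  out
}

# complementary error function via the normal CDF
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' First-passage law for viral invasion
#'
#' The invasion-time law for a virus performing a projected 1-d radial walk
#' between the absorbing host surface at radius `a_eta` and the reflecting
#' dining-sphere boundary at radius `b`, started at radius `gamma`. The law is
#' the equal-weight two-term Levy mixture with path lengths
#' \eqn{\gamma - a} (direct) and \eqn{2b - a - \gamma} (to the reflecting
#' boundary and back):
#' \deqn{P(\tau_i \mid \gamma) = \tfrac12\left[L(\tau; (\gamma-a)^2/\varkappa_\beta)
#'   + L(\tau; (2b-a-\gamma)^2/\varkappa_\beta)\right].}
#'
#' @param gamma Start radius, m, with `a_eta <= gamma <= b`. Vectorised.
#' @param a_eta Absorbing (host surface) radius, m.
#' @param b Reflecting (dining sphere) radius, m.
#' @param kappa_radial Projected radial diffusivity \eqn{\varkappa_\beta},
#'   m^2 s^-1.
#' @return An object of class `fpt_law` (a list with the fields above).
#' @seealso [invasion_time_density()], [invasion_time_cdf()],
#'   [sample_invasion_times()]
#' @export
fpt_law <- function(gamma, a_eta, b, kappa_radial) {
  if (a_eta <= 0 || b <= a_eta || kappa_radial <= 0) {
    stop("need 0 < a_eta < b and kappa_radial > 0", call. = FALSE)
  }
  if (any(gamma < a_eta) || any(gamma > b)) {
    stop("`gamma` must lie in [a_eta, b]", call. = FALSE)
  }
  structure(
    list(gamma = gamma, a_eta = a_eta, b = b, kappa_radial = kappa_radial),
    class = "fpt_law"
  )
}

#' @export
print.fpt_law <- function(x, ...) {
  cat("<fpt_law> absorbing a =", format(x$a_eta), "m, reflecting b =",
      format(x$b), "m, kappa_radial =", format(x$kappa_radial),
      "m^2/s, start gamma =",
      paste(utils::head(format(x$gamma), 3), collapse = ", "),
      if (length(x$gamma) > 3) "..." else "", "\n")
  invisible(x)
}

law_scales <- function(law) {
  list(
    g2_direct    = (law$gamma - law$a_eta)^2 / law$kappa_radial,
    g2_reflected = (2 * law$b - law$a_eta - law$gamma)^2 / law$kappa_radial
  )
}

#' Invasion-time density
#'
#' Density of the two-term Levy mixture of [fpt_law()] at times `tau`.
#' A degenerate start on the absorber (`gamma == a_eta`) is a point mass at
#' zero: the density is returned as `Inf` at `tau = 0` and 0 elsewhere, with
#' the CDF convention handled by [invasion_time_cdf()].
#'
#' @param law An [fpt_law()].
#' @param tau Times, s (> 0). Vectorised; `law$gamma` must be scalar or match.
#' @return Density value(s), s^-1.
#' @export
invasion_time_density <- function(law, tau) {
  stopifnot(inherits(law, "fpt_law"))
  if (any(tau <= 0)) stop("`tau` must be strictly positive", call. = FALSE)
  s <- law_scales(law)
  n <- max(length(tau), length(s$g2_direct))
  tau <- rep_len(as.numeric(tau), n)
  g2d <- rep_len(s$g2_direct, n)
  g2r <- rep_len(s$g2_reflected, n)
  d_direct <- ifelse(g2d == 0, 0,
                     sqrt(pmax(g2d, .Machine$double.xmin) /
                            (2 * pi * tau^3)) * exp(-g2d / (2 * tau)))
  d_refl <- sqrt(g2r / (2 * pi * tau^3)) * exp(-g2r / (2 * tau))
  0.5 * (d_direct + d_refl)
}

#' Invasion-time CDF
#'
#' \eqn{\tfrac12[\mathrm{erfc}((\gamma-a)/\sqrt{2\varkappa_\beta\tau}) +
#' \mathrm{erfc}((2b-a-\gamma)/\sqrt{2\varkappa_\beta\tau})]}. For the
#' degenerate start `gamma == a_eta` the direct component is an immediate
#' hit, so its term is 1 for every `tau > 0`.
#'
#' @inheritParams invasion_time_density
#' @return Probability value(s), nondecreasing in `tau`.
#' @export
invasion_time_cdf <- function(law, tau) {
  stopifnot(inherits(law, "fpt_law"))
  if (any(tau < 0)) stop("`tau` must be nonnegative", call. = FALSE)
  n <- max(length(tau), length(law$gamma))
  tau <- rep_len(as.numeric(tau), n)
  d1 <- rep_len(law$gamma - law$a_eta, n)
  d2 <- rep_len(2 * law$b - law$a_eta - law$gamma, n)
  sig <- sqrt(2 * law$kappa_radial * pmax(tau, .Machine$double.xmin))
  c1 <- ifelse(d1 == 0, as.numeric(tau > 0),
               ifelse(tau > 0, erfc(d1 / sig), 0))
  c2 <- ifelse(tau > 0, erfc(d2 / sig), 0)
  0.5 * (c1 + c2)
}

#' Sample start radii uniformly in the dining-sphere shell
#'
#' Draws radii with density \eqn{3\gamma^2/(b^3 - a^3)} on \eqn{[a, b]}
#' (uniform in shell volume) by inverse transform.
#'
#' @param n Number of draws.
#' @param a_eta Inner radius, m.
#' @param b Outer radius, m.
#' @return Numeric vector of radii.
#' @export
sample_start_radius <- function(n, a_eta, b) {
  u <- stats::runif(n)
  (a_eta^3 + u * (b^3 - a_eta^3))^(1 / 3)
}

#' Sample invasion times exactly from the two-term mixture
#'
#' Uses the closed-form inverse of the Levy law: if \eqn{Z \sim N(0,1)} then
#' \eqn{g^2/Z^2} is Levy with scale \eqn{g^2}. The mixture component (direct
#' vs reflected path) is chosen with probability 1/2 each, matching
#' [invasion_time_cdf()] exactly.
#'
#' @param law An [fpt_law()] whose `gamma` is scalar or length `n`.
#' @param n Number of samples (defaults to `length(law$gamma)`).
#' @return Numeric vector of invasion times, s.
#' @export
sample_invasion_times <- function(law, n = length(law$gamma)) {
  stopifnot(inherits(law, "fpt_law"))
  gamma <- rep_len(law$gamma, n)
  d1 <- gamma - law$a_eta
  d2 <- 2 * law$b - law$a_eta - gamma
  d <- ifelse(stats::runif(n) < 0.5, d1, d2)
  z <- stats::rnorm(n)
  (d * d) / (law$kappa_radial * z * z)
}
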