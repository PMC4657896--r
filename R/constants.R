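#' Physical and model constants
#'
#' Full-precision values of the constants that appear (rounded to two
#' significant digits) in the model's closed forms. All internal computation
#' uses these full-precision values; the two-digit "as printed" figures are
#' confined to the `method = "printed"` evaluation paths.
#'
#' @format A named list:
#' \describe{
#'   \item{k_boltzmann}{Boltzmann constant, J K^-1 (2019 SI exact value).}
#'   \item{radial_projection}{\eqn{(1 - 2/\pi)^2 \approx 0.13205}: factor
#'     mapping the 3-d viral diffusivity onto the projected 1-d radial walk.}
#'   \item{spacing_prefactor}{\eqn{\Gamma(4/3)\,(3/(4\pi))^{1/3} \approx
#'     0.55396}: mean nearest-neighbour distance prefactor for a 3-d Poisson
#'     point process (often quoted as 5/9); half of it sets the dining-sphere
#'     radius \eqn{b = (5/18)\,c_\eta^{-1/3}}.}
#'   \item{dining_prefactor}{\eqn{(4\pi/3)(5/18)^3 \approx 0.08977}: expected
#'     viruses per dining sphere per unit \eqn{\rho\,c_\beta/c_\eta}.}
#'   \item{b_over_a_prefactor}{\code{dining_prefactor / ln 2} \eqn{\approx
#'     0.12951}: ratio of the growth-rate coefficients \eqn{B/A} per unit
#'     \eqn{c_\beta/c_\eta}.}
#'   \item{pr_series_constant}{\eqn{3/\sqrt{2\pi} \approx 1.19683}: leading
#'     coefficient of the small-time series of the replication probability,
#'     multiplying \eqn{a_\eta^2\sqrt{\varkappa_\beta\tau_r}/(b^3-a_\eta^3)}.}
#'   \item{c_coef_prefactor}{\eqn{3(1-2/\pi)/(2\pi\sqrt{2}) \approx 0.12268}:
#'     full-precision prefactor of the dimensionless coefficient C.}
#' }
#' @export
colim_constants <- list(
  k_boltzmann       = 1.380649e-23,
  radial_projection = (1 - 2 / pi)^2,
  spacing_prefactor = gamma(4 / 3) * (3 / (4 * pi))^(1 / 3),
  dining_prefactor  = (4 * pi / 3) * (5 / 18)^3,
  b_over_a_prefactor = (4 * pi / 3) * (5 / 18)^3 / log(2),
  pr_series_constant = 3 / sqrt(2 * pi),
  c_coef_prefactor  = (3 / sqrt(2 * pi)) * sqrt((1 - 2 / pi)^2 / (4 * pi))
)

#' Tabulate model constants against their two-digit printed forms
#'
#' Convenience view of [colim_constants]: each derived constant with its
#' full-precision value and the rounded form conventionally quoted for it.
#'
#' @return A tibble with columns `constant`, `value`, `printed`.
#' @examples
#' model_constants()
#' @export
model_constants <- function() {
  tibble::tibble(
    constant = c(
      "radial_projection", "spacing_prefactor", "dining_prefactor",
      "ln2", "b_over_a_prefactor", "pr_series_constant", "c_coef_prefactor"
    ),
    value = c(
      colim_constants$radial_projection,
      colim_constants$spacing_prefactor,
      colim_constants$dining_prefactor,
      log(2),
      colim_constants$b_over_a_prefactor,
      colim_constants$pr_series_constant,
      colim_constants$c_coef_prefactor
    ),
    printed = c(0.13, 0.554, 0.089, 0.69, 0.13, NA, NA)
  )
}
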