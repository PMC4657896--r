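#' Construct a parameter set
#'
#' Builds a one-row tibble holding the full physical state of the model: a
#' spherical nonmotile host of radius `a_eta` taking up a single limiting
#' nutrient (concentration `c_nu`, molecule radius `a_nu`) through surface
#' receptors of efficiency `rho`, surrounded by lytic viruses (concentration
#' `c_beta`, virion radius `a_beta`) that enter through the same receptors.
#' Units are strict SI with nutrient mass in femtograms.
#'
#' Diffusivities may be given directly or derived: if `kappa_nu` is missing it
#' is computed from `temperature` and `viscosity` by the Einstein-Stokes
#' relation; if `kappa_beta` is missing it is taken as
#' `kappa_nu * a_nu / a_beta` (the Einstein-Stokes ratio of the radii). If a
#' direct `kappa_beta` is supplied it wins; a consistency warning is emitted
#' when it disagrees with the radius-derived value by more than 1%.
#'
#' @param a_eta Host equivalent-spherical radius, m.
#' @param a_nu Nutrient molecule radius, m.
#' @param a_beta Virus (virion) radius, m.
#' @param c_eta Local host concentration, m^-3. "Local" means within an
#'   O(mm) neighbourhood of the focal cell, so aggregation raises it.
#' @param c_nu Nutrient concentration, fg m^-3.
#' @param c_beta Virus concentration, m^-3.
#' @param q Host nutrient quota: nutrient mass to take up before dividing, fg.
#' @param rho Receptor efficiency, the cell's uptake rate relative to a
#'   perfect absorber of the same size; dimensionless in (0, 1].
#' @param kappa_nu Nutrient diffusivity, m^2 s^-1 (optional, see Details).
#' @param kappa_beta Virus diffusivity, m^2 s^-1 (optional, see Details).
#' @param temperature Temperature, K (optional; Einstein-Stokes only).
#' @param viscosity Dynamic viscosity, Pa s (optional; Einstein-Stokes only).
#' @param validate If `TRUE` (default) hard physics violations raise an error
#'   (see [validate_params()]); range warnings are not emitted here.
#'
#' @return A one-row tibble with the parameter columns above.
#' @examples
#' param_set(a_eta = 1e-5, c_nu = 1e12, c_beta = 3e9, c_eta = 3e8, q = 300)
#' @seealso [validate_params()], [sample_parameters()], [derive_quantities()]
#' @export
param_set <- function(a_eta = 1e-5,
                      a_nu = 1e-10,
                      a_beta = 3.16e-8,
                      c_eta = 3.16e8,
                      c_nu = 1e12,
                      c_beta = 3.16e9,
                      q = 316,
                      rho = 0.5,
                      kappa_nu = 3.16e-10,
                      kappa_beta = NULL,
                      temperature = NA_real_,
                      viscosity = NA_real_,
                      validate = TRUE) {
  if (is.null(kappa_nu)) {
    if (is.na(temperature) || is.na(viscosity)) {
      stop("supply `kappa_nu` or both `temperature` and `viscosity`",
           call. = FALSE)
    }
    kappa_nu <- einstein_stokes_diffusivity(a_nu, temperature, viscosity)
  }
  if (is.null(kappa_beta)) {
    kappa_beta <- kappa_nu * a_nu / a_beta
  } else {
    implied <- kappa_nu * a_nu / a_beta
    off <- abs(kappa_beta - implied) / implied
    if (any(off > 0.01)) {
      warning(sprintf(
        paste0("direct kappa_beta (%.3g) differs from radius-derived ",
               "kappa_nu*a_nu/a_beta (%.3g) by %.1f%%; direct value used"),
        kappa_beta[which.max(off)], implied[which.max(off)], 100 * max(off)
      ), call. = FALSE)
    }
  }
  params <- tibble::tibble(
    a_eta = a_eta, a_nu = a_nu, a_beta = a_beta,
    c_eta = c_eta, c_nu = c_nu, c_beta = c_beta,
    q = q, rho = rho,
    kappa_nu = kappa_nu, kappa_beta = kappa_beta,
    temperature = temperature, viscosity = viscosity
  )
  if (validate) {
    bad <- validate_params(params, warn = FALSE)
    bad <- bad[bad$severity == "error", , drop = FALSE]
    if (nrow(bad) > 0) {
      stop("invalid parameter set:\n  ",
           paste(bad$message, collapse = "\n  "), call. = FALSE)
    }
  }
  params
}

PARAM_COLS <- c("a_eta", "a_nu", "a_beta", "c_eta", "c_nu", "c_beta",
                "q", "rho", "kappa_nu", "kappa_beta")

PARAM_UNITS <- c(
  a_eta = "m", a_nu = "m", a_beta = "m",
  c_eta = "m^-3", c_nu = "fg m^-3", c_beta = "m^-3",
  q = "fg", rho = "-", kappa_nu = "m^2 s^-1", kappa_beta = "m^2 s^-1",
  temperature = "K", viscosity = "Pa s"
)

#' Observed marine parameter ranges
#'
#' The "typical range" brackets compiled from marine observations for each
#' model parameter. The viral diffusivity row is stored as the *radial*
#' (projected 1-d) diffusivity bracket, matching how it is conventionally
#' tabulated; [validate_params()] applies the \eqn{(1-2/\pi)^2} projection
#' factor before checking `kappa_beta` against it.
#'
#' Values outside these brackets are physically possible (the model applies
#' beyond marine systems) and trigger warnings, not errors.
#'
#' @return A tibble with columns `parameter`, `low`, `high`, `unit`, `note`.
#' @examples
#' default_ranges()
#' @export
default_ranges <- function() {
  tibble::tribble(
    ~parameter,           ~low,   ~high,  ~unit,       ~note,
    "a_eta",              1e-6,   1e-4,   "m",         "host equivalent-spherical radius",
    "a_nu",               1e-11,  1e-9,   "m",         "nutrient molecule radius",
    "a_beta",             1e-8,   1e-7,   "m",         "virion radius",
    "c_eta",              1e6,    1e11,   "m^-3",      "local host concentration",
    "c_nu",               1e10,   1e14,   "fg m^-3",   "nutrient concentration",
    "c_beta",             1e7,    1e12,   "m^-3",      "virus concentration",
    "q",                  0.1,    1e6,    "fg",        "host nutrient quota",
    "rho",                0.1,    1,      "-",         "receptor efficiency",
    "kappa_nu",           1e-10,  1e-9,   "m^2 s^-1",  "nutrient diffusivity",
    "kappa_beta_radial",  1e-13,  1e-12,  "m^2 s^-1",  "projected radial viral diffusivity (~0.13 kappa_beta)"
  )
}

#' Einstein-Stokes diffusivity of a sphere
#'
#' \eqn{\kappa = k_B T / (6 \pi \nu a)} for a sphere of radius `a` in a fluid
#' of dynamic viscosity `nu` at absolute temperature `T`.
#'
#' @param radius Particle radius, m.
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return Diffusivity, m^2 s^-1. Vectorised over all arguments.
#' @examples
#' einstein_stokes_diffusivity(1e-9, 293, 1e-3)  # ~2.1e-10 m^2/s
#' @export
einstein_stokes_diffusivity <- function(radius, temperature, viscosity) {
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("`radius` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("`temperature` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(viscosity)) || any(viscosity <= 0)) {
    stop("`viscosity` must be strictly positive", call. = FALSE)
  }
  colim_constants$k_boltzmann * temperature / (6 * pi * viscosity * radius)
}

#' Validate a table of parameter sets
#'
#' Checks each row of `params` against the model's hard physical invariants
#' and against the observed ranges of [default_ranges()]. Hard violations
#' (non-positive quantities, `rho` outside (0, 1], size ordering
#' `a_eta > a_beta > a_nu`, or a dining sphere `b = (5/18) c_eta^{-1/3}` not
#' exceeding the host radius) are reported with severity `"error"`;
#' out-of-range values are severity `"warning"` because the model applies
#' beyond the marine brackets.
#'
#' @param params A data frame of parameter sets (as from [param_set()] or
#'   [sample_parameters()]).
#' @param ranges Range table, defaults to [default_ranges()].
#' @param warn If `TRUE`, emit R warnings for range violations.
#' @return A tibble of violations with columns `row`, `parameter`, `value`,
#'   `bound`, `severity`, `message`; zero rows when all invariants hold.
#' @export
validate_params <- function(params, ranges = default_ranges(), warn = TRUE) {
  stopifnot(is.data.frame(params))
  missing_cols <- setdiff(PARAM_COLS, names(params))
  if (length(missing_cols) > 0) {
    stop("missing parameter columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  add <- function(row, parameter, value, bound, severity, message) {
    out[[length(out) + 1]] <<- tibble::tibble(
      row = row, parameter = parameter, value = value,
      bound = bound, severity = severity, message = message
    )
  }
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    for (f in PARAM_COLS) {
      v <- p[[f]]
      # c_beta = 0 (virus-free water) is a meaningful limit; all else > 0
      bad_val <- if (f == "c_beta") !is.finite(v) || v < 0 else
        !is.finite(v) || v <= 0
      if (bad_val) {
        add(i, f, v, 0, "error",
            sprintf("row %d: %s = %g must be %s", i, f, v,
                    if (f == "c_beta") "nonnegative" else "strictly positive"))
      }
    }
    if (is.finite(p$rho) && p$rho > 1) {
      add(i, "rho", p$rho, 1, "error",
          sprintf("row %d: rho = %g exceeds 1", i, p$rho))
    }
    ok_pos <- all(vapply(PARAM_COLS, function(f) {
      isTRUE(is.finite(p[[f]]) &&
               (p[[f]] > 0 || (f == "c_beta" && p[[f]] == 0)))
    }, logical(1)))
    if (ok_pos) {
      if (!(p$a_eta > p$a_beta && p$a_beta > p$a_nu)) {
        add(i, "a_eta", p$a_eta, NA_real_, "error",
            sprintf("row %d: size ordering a_eta > a_beta > a_nu violated", i))
      }
      b <- (5 / 18) * p$c_eta^(-1 / 3)
      if (b <= p$a_eta) {
        add(i, "c_eta", p$c_eta, NA_real_, "error",
            sprintf(paste0("row %d: dining sphere smaller than host ",
                           "(b = %.3g m <= a_eta = %.3g m)"), i, b, p$a_eta))
      }
      for (j in seq_len(nrow(ranges))) {
        par <- ranges$parameter[j]
        v <- if (par == "kappa_beta_radial") {
          colim_constants$radial_projection * p$kappa_beta
        } else {
          p[[par]]
        }
        if (is.null(v) || !is.finite(v)) next
        if (v < ranges$low[j] || v > ranges$high[j]) {
          add(i, par, v, if (v < ranges$low[j]) ranges$low[j] else ranges$high[j],
              "warning",
              sprintf("row %d: %s = %.3g outside observed range [%.3g, %.3g] %s",
                      i, par, v, ranges$low[j], ranges$high[j], ranges$unit[j]))
        }
      }
    }
  }
  res <- if (length(out) == 0) {
    tibble::tibble(row = integer(), parameter = character(), value = numeric(),
                   bound = numeric(), severity = character(),
                   message = character())
  } else {
    dplyr::bind_rows(out)
  }
  if (warn && any(res$severity == "warning")) {
    warning(paste(res$message[res$severity == "warning"], collapse = "\n"),
            call. = FALSE)
  }
  res
}

#' Sample parameter sets within observed ranges
#'
#' Draws `n` parameter sets log-uniformly within each range of `ranges`
#' (every bracket spans at least an order of magnitude, so log-uniform is the
#' natural reference measure). `kappa_beta` is drawn through the tabulated
#' radial bracket and de-projected by \eqn{(1-2/\pi)^{-2}}. Rows violating the
#' dining-sphere constraint `b > a_eta` are rejection-resampled.
#'
#' @param n Number of parameter sets (>= 1).
#' @param seed Integer seed; output is bit-identical across runs for a seed.
#' @param ranges Range table, defaults to [default_ranges()].
#' @param max_tries Rejection-sampling cap per batch.
#' @return A tibble of `n` valid parameter sets.
#' @examples
#' sample_parameters(3, seed = 1)
#' @export
sample_parameters <- function(n, seed, ranges = default_ranges(),
                              max_tries = 1000) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(is.numeric(seed), length(seed) == 1)
  rng <- function(par, k) {
    r <- ranges[ranges$parameter == par, ]
    exp(stats::runif(k, log(r$low), log(r$high)))
  }
  withr::with_seed(as.integer(seed), {
    draw <- function(k) {
      tibble::tibble(
        a_eta = rng("a_eta", k),
        a_nu = rng("a_nu", k),
        a_beta = rng("a_beta", k),
        c_eta = rng("c_eta", k),
        c_nu = rng("c_nu", k),
        c_beta = rng("c_beta", k),
        q = rng("q", k),
        rho = rng("rho", k),
        kappa_nu = rng("kappa_nu", k),
        kappa_beta = rng("kappa_beta_radial", k) /
          colim_constants$radial_projection,
        temperature = NA_real_, viscosity = NA_real_
      )
    }
    out <- draw(n)
    tries <- 0
    repeat {
      b <- (5 / 18) * out$c_eta^(-1 / 3)
      bad <- which(b <= out$a_eta | out$a_eta <= out$a_beta |
                     out$a_beta <= out$a_nu)
      if (length(bad) == 0) break
      tries <- tries + 1
      if (tries > max_tries) {
        stop("rejection sampling failed to satisfy b > a_eta within ",
             max_tries, " attempts", call. = FALSE)
      }
      out[bad, names(draw(1))] <- draw(length(bad))
    }
    out
  })
}

#' Receptor efficiency from surface receptor coverage
#'
#' Maps the fraction of the cell surface covered by receptors to the receptor
#' efficiency \eqn{\rho = I/I_{perf}} using the classical diffusive-capture
#' result for N absorbing disks of radius `receptor_radius` on a sphere of
#' radius `cell_radius`: capture is proportional to \eqn{Ns/(Ns + \pi a)},
#' which saturates steeply (Monod-like) because a sparse scatter of receptors
#' already intercepts most incoming diffusive flux. The curve is normalised by
#' its full-coverage value so that \eqn{\rho(1) = 1} exactly.
#'
#' This utility is an extrapolation from the uptake literature — the core
#' model treats `rho` itself as the primitive — and is provided for mapping
#' receptor-allocation scenarios onto `rho` values only.
#'
#' @param coverage_fraction Fraction of surface area covered, in \[0, 1\].
#' @param receptor_radius Receptor (absorbing patch) radius, m.
#' @param cell_radius Cell radius, m.
#' @return Receptor efficiency in \[0, 1\], vectorised over
#'   `coverage_fraction`.
#' @examples
#' receptor_efficiency_from_coverage(c(0, 0.01, 0.1, 1), 1e-9, 1e-6)
#' @export
receptor_efficiency_from_coverage <- function(coverage_fraction,
                                              receptor_radius,
                                              cell_radius) {
  if (any(!is.finite(coverage_fraction)) ||
      any(coverage_fraction < 0 | coverage_fraction > 1)) {
    stop("`coverage_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (receptor_radius <= 0 || cell_radius <= 0) {
    stop("radii must be strictly positive", call. = FALSE)
  }
  # N disks of radius s covering fraction f of 4*pi*a^2: N = 4 f a^2 / s^2
  bp <- function(f) {
    ns <- 4 * f * cell_radius^2 / receptor_radius
    ns / (ns + pi * cell_radius)
  }
  bp(coverage_fraction) / bp(1)
}

#' Write parameter sets to CSV
#'
#' Wide CSV, one row per parameter set; each column header carries its unit
#' (e.g. `a_eta [m]`). Values are written with 15 significant digits so a
#' round trip through [read_params_csv()] preserves them to at least 12.
#'
#' @param params Data frame of parameter sets.
#' @param path Output file path.
#' @return `params`, invisibly.
#' @export
write_params_csv <- function(params, path) {
  stopifnot(is.data.frame(params))
  out <- params[, intersect(names(PARAM_UNITS), names(params)), drop = FALSE]
  hdr <- paste0(names(out), " [", PARAM_UNITS[names(out)], "]")
  chr <- vapply(out, function(x) format(x, digits = 15, trim = TRUE),
                character(nrow(out)))
  chr <- matrix(chr, nrow = nrow(out),
                dimnames = list(NULL, names(out)))
  df <- tibble::as_tibble(chr)
  names(df) <- hdr
  readr::write_csv(df, path)
  invisible(params)
}

#' Read parameter sets from CSV
#'
#' Inverse of [write_params_csv()]: strips the unit annotation from each
#' header and returns a parameter tibble.
#'
#' @param path CSV path as written by [write_params_csv()].
#' @return A tibble of parameter sets.
#' @export
read_params_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- sub(" \\[.*\\]$", "", names(df))
  for (nm in names(df)) df[[nm]] <- as.numeric(df[[nm]])
  tibble::as_tibble(df)
}

#' Read a parameter set from a flat key/value config file
#'
#' The config is flat YAML (`field: value` per line) using the field names of
#' [param_set()]. Entries in `overrides` (e.g. parsed CLI flags) replace
#' config values.
#'
#' @param path Config file path, or `NULL` to use defaults plus overrides.
#' @param overrides Named list of field overrides.
#' @return A one-row parameter tibble via [param_set()].
#' @export
read_params_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.null(path) && (!is.list(cfg) || is.null(names(cfg)))) {
    stop("config must be flat key: value mappings", call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  allowed <- c(PARAM_COLS, "temperature", "viscosity")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- lapply(cfg, as.numeric)
  do.call(param_set, cfg)
}
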