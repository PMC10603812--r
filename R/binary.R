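# Binary cosolute-water solutions: composition bookkeeping, partial molar
# volumes from density, chi from water activity, osmotic pressure.

#' Convert molality to volume-fraction composition
#'
#' Uses constant partial molar volumes: per kg of water the solution volume is
#' `V = (1000 / M_S) * Vbar_S + m * Vbar_C` (cm^3), so the cosolute volume
#' fraction is `phi_C = m * Vbar_C / V` and the molarity is `1000 * m / V`.
#'
#' @param molality Cosolute molality, mol/kg water (vectorized, >= 0).
#' @param params A [cosolute_params()] object.
#' @return A tibble with columns `molality`, `molarity` (mol/L), `phi_C`,
#'   `phi_S` (`phi_C + phi_S = 1`).
#' @examples
#' tre <- cosolute_params("trehalose", 342.3, 209.5)
#' molality_to_composition(c(0, 0.5, 1), tre)
#' @export
molality_to_composition <- function(molality, params) {
  stopifnot(inherits(params, "cosolute_params"))
  if (any(molality < 0)) abort("molality must be >= 0.")
  n_S <- 1000 / params$M_S                     # mol water per kg water
  vol <- n_S * params$Vbar_S + molality * params$Vbar_C  # cm^3 per kg water
  phi_C <- molality * params$Vbar_C / vol
  tibble::tibble(
    molality = molality,
    molarity = 1000 * molality / vol,
    phi_C = phi_C,
    phi_S = 1 - phi_C
  )
}

#' Invert composition: molality from cosolute volume fraction
#'
#' @param phi_C Cosolute volume fraction in `[0, 1)`.
#' @param params A [cosolute_params()] object.
#' @return Molality, mol/kg water.
#' @export
composition_to_molality <- function(phi_C, params) {
  stopifnot(inherits(params, "cosolute_params"))
  if (any(phi_C < 0 | phi_C >= 1)) abort("phi_C must lie in [0, 1).")
  n_S <- 1000 / params$M_S
  phi_C * n_S * params$Vbar_S / (params$Vbar_C * (1 - phi_C))
}

#' Fit partial molar volumes from a binary-solution density series
#'
#' Converts each density to a solution volume per kg water,
#' `V(m) = (1000 + m * M_C) / rho(m)`, and fits the linear model
#' `V(m) = (1000 / M_S) * Vbar_S + m * Vbar_C` by least squares, treating
#' both partial molar volumes as concentration-independent constants.
#'
#' @param data A data frame with columns `molality` (mol/kg, including 0)
#'   and `density_g_cm3`, e.g. from [gen_density_series()] or
#'   [read_density_csv()].
#' @param M_C Cosolute molar mass, g/mol.
#' @param M_S Solvent molar mass, g/mol.
#' @return A tibble with one row per parameter (`Vbar_C`, `Vbar_S`):
#'   `estimate` (cm^3/mol), `std_error`, plus the implied `nu` as an
#'   attribute-free extra row.
#' @examples
#' truth <- ground_truth()
#' dens <- gen_density_series(truth, molalities = seq(0, 1.5, by = 0.25),
#'                            noise = FALSE)
#' fit_partial_molar_volume(dens, M_C = truth$cosolute$M_C)
#' @export
fit_partial_molar_volume <- function(data, M_C,
                                     M_S = fh_constants$M_water) {
  stopifnot(all(c("molality", "density_g_cm3") %in% names(data)))
  if (nrow(data) < 3) abort("Need at least 3 density points (including m = 0).")
  if (!any(data$molality == 0)) abort("Density series must include m = 0.")
  if (any(data$density_g_cm3 <= 0)) abort("Densities must be positive.")
  if (is.unsorted(data$molality, strictly = TRUE)) {
    data <- dplyr::arrange(data, .data$molality)
  }

  vol <- (1000 + data$molality * M_C) / data$density_g_cm3
  if (any(diff(vol) < 0)) {
    warn("Solution volume per kg water is not monotone in molality; check the density series.")
  }
  fit <- lm(vol ~ molality, data = tibble::tibble(vol = vol, molality = data$molality))
  est <- coef(fit)
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  n_S <- 1000 / M_S
  out <- tibble::tibble(
    term = c("Vbar_C", "Vbar_S"),
    estimate = c(unname(est[2]), unname(est[1]) / n_S),
    std_error = c(unname(se[2]), unname(se[1]) / n_S)
  )
  out$nu <- out$estimate[out$term == "Vbar_C"] / out$estimate[out$term == "Vbar_S"]
  out
}

#' Water activity of a Flory-Huggins binary mixture
#'
#' Solvent activity from the mean-field mixing free energy of a binary
#' lattice solution with cosolute-to-solvent size ratio `nu` and interaction
#' parameter `chi`:
#' `ln a_S = ln(1 - phi_C) + (1 - 1/nu) * phi_C + chi * phi_C^2`.
#'
#' @param phi_C Cosolute volume fraction in `[0, 1)` (vectorized).
#' @param nu Excluded-volume ratio (> 0).
#' @param chi Flory-Huggins interaction parameter.
#' @return Water activity `a_S`.
#' @examples
#' water_activity_fh(0.2, nu = 10, chi = 0.5)
#' @export
water_activity_fh <- function(phi_C, nu, chi) {
  if (any(phi_C < 0 | phi_C >= 1)) abort("phi_C must lie in [0, 1).")
  stopifnot(nu > 0)
  exp(log1p(-phi_C) + (1 - 1 / nu) * phi_C + chi * phi_C^2)
}

#' Fit the Flory-Huggins chi from a water-activity series
#'
#' With `nu` fixed from density measurements, the activity closed form leaves
#' `chi` as the slope of the residual
#' `ln a_S - ln(1 - phi_C) - (1 - 1/nu) * phi_C` against `phi_C^2`; the fit
#' is least squares through the origin, inverse-variance weighted when a
#' `sigma` column of activity standard errors is present.
#'
#' @param data A data frame with columns `molality` and `water_activity`
#'   (optionally `sigma`).
#' @param params A [cosolute_params()] object supplying `nu` and the volumes
#'   for the molality-to-composition conversion.
#' @return A one-row tibble: `term = "chi"`, `estimate`, `std_error`,
#'   `n` points used, and logical `suspect` flagging `|chi| > 10`.
#' @export
fit_chi <- function(data, params) {
  stopifnot(all(c("molality", "water_activity") %in% names(data)))
  keep <- data$molality > 0
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 3) abort("Need at least 3 points with m > 0 to fit chi.")
  if (any(d$water_activity <= 0 | d$water_activity > 1)) {
    abort("water_activity must lie in (0, 1].")
  }
  comp <- molality_to_composition(d$molality, params)
  y <- log(d$water_activity) - log1p(-comp$phi_C) - (1 - 1 / params$nu) * comp$phi_C
  x <- comp$phi_C^2
  w <- if ("sigma" %in% names(d)) 1 / pmax(d$sigma, 1e-12)^2 else rep(1, nrow(d))
  fit <- lm(y ~ x + 0, weights = w)
  est <- unname(coef(fit)[1])
  se <- sqrt(diag(suppressWarnings(vcov(fit))))[[1]]
  if (abs(est) > 10) warn(sprintf("Fitted chi = %.2f is outside the plausible range; flagged as suspect.", est))
  tibble::tibble(term = "chi", estimate = est, std_error = se,
                 n = nrow(d), suspect = abs(est) > 10)
}

#' Temperature dependence of chi by van't Hoff regression
#'
#' Fits `chi(T) = a + b / T` to per-temperature chi estimates by (optionally
#' weighted) least squares and reports the enthalpy/entropy split at the
#' reference temperature: `chi_H(T0) = b / T0`, `chi_TS(T0) = -a`, so that
#' `chi(T0) = chi_H(T0) - chi_TS(T0)` exactly.
#'
#' @param data A data frame with columns `T_K` and `chi` (optionally
#'   `std_error` used for inverse-variance weights), e.g. one [fit_chi()]
#'   row per temperature.
#' @param T0 Reference temperature, K.
#' @return A tibble with rows `chi_a`, `chi_b`, `chi_T0`, `chi_H_T0`,
#'   `chi_TS_T0` (`estimate`, `std_error`; derived rows carry propagated
#'   errors where defined, otherwise `NA`).
#' @export
fit_chi_temperature <- function(data, T0 = fh_constants$T_ref) {
  stopifnot(all(c("T_K", "chi") %in% names(data)))
  if (length(unique(data$T_K)) < 3) {
    abort("Need chi estimates at >= 3 distinct temperatures for a van't Hoff split.")
  }
  known_var <- "std_error" %in% names(data) && all(is.finite(data$std_error)) &&
    all(data$std_error > 0)
  w <- if (known_var) 1 / data$std_error^2 else rep(1, nrow(data))
  inv_T <- 1 / data$T_K
  fit <- lm(chi ~ inv_T, data = tibble::tibble(chi = data$chi, inv_T = inv_T),
            weights = w)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  V <- if (known_var) {
    # supplied per-point errors are taken as the truth (generalized least
    # squares covariance), not rescaled by the few-df residual variance
    X <- cbind(1, inv_T)
    solve(crossprod(X, w * X))
  } else {
    suppressWarnings(vcov(fit))
  }
  se <- sqrt(diag(V))
  # chi(T0) = a + b/T0; var via delta method
  se_chi0 <- sqrt(V[1, 1] + V[2, 2] / T0^2 + 2 * V[1, 2] / T0)
  tibble::tibble(
    term = c("chi_a", "chi_b", "chi_T0", "chi_H_T0", "chi_TS_T0"),
    estimate = c(a, b, a + b / T0, b / T0, -a),
    std_error = c(unname(se[1]), unname(se[2]), se_chi0,
                  unname(se[2]) / T0, unname(se[1]))
  )
}

#' Osmotic pressure of the binary mixture
#'
#' `Pi = -(R T / Vbar_S) * ln a_S`, with the activity from
#' [water_activity_fh()]. In the dilute (van't Hoff) regime this reduces to
#' `Pi = R T * molarity`.
#'
#' @param molality Cosolute molality, mol/kg (vectorized).
#' @param params A [cosolute_params()] object.
#' @param T_K Temperature, K. `chi` is evaluated at `T_K` via [chi_at()]
#'   unless overridden.
#' @param chi Optional fixed chi (otherwise `chi_at(params, T_K)`).
#' @return A tibble with `molality`, `phi_C`, `water_activity`, `Pi_Pa`.
#' @examples
#' tre <- cosolute_params("trehalose", 342.3, 209.5, chi_a = 1.2, chi_b = -180)
#' osmotic_pressure(seq(0, 1.5, 0.5), tre, T_K = 298)
#' @export
osmotic_pressure <- function(molality, params, T_K = fh_constants$T_ref,
                             chi = NULL) {
  stopifnot(inherits(params, "cosolute_params"), length(T_K) == 1)
  chi <- chi %||% chi_at(params, T_K)
  comp <- molality_to_composition(molality, params)
  a_S <- water_activity_fh(comp$phi_C, params$nu, chi)
  Vbar_S_m3 <- params$Vbar_S * 1e-6
  tibble::tibble(
    molality = molality,
    phi_C = comp$phi_C,
    water_activity = a_S,
    Pi_Pa = -(fh_constants$R * T_K / Vbar_S_m3) * log(a_S)
  )
}

#' Molality at which the binary mixture reaches a target osmotic pressure
#'
#' Numerically inverts [osmotic_pressure()]; used to place model curves on a
#' pressure abscissa for osmotic-stress analysis.
#'
#' @param Pi_Pa Target osmotic pressure(s), Pa (>= 0).
#' @param params A [cosolute_params()] object.
#' @param T_K Temperature, K.
#' @param m_max Upper bracket for the search, mol/kg.
#' @return Molality, mol/kg.
#' @export
molality_at_pressure <- function(Pi_Pa, params, T_K = fh_constants$T_ref,
                                 m_max = 20) {
  vapply(Pi_Pa, function(target) {
    if (target < 0) abort("Osmotic pressure must be >= 0.")
    if (target == 0) return(0)
    f <- function(m) osmotic_pressure(m, params, T_K)$Pi_Pa - target
    uniroot(f, c(0, m_max), tol = 1e-12)$root
  }, numeric(1))
}
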