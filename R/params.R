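#' Cosolute parameter set
#'
#' Bundles everything the crowding model needs to know about one cosolute:
#' its molar mass, the partial molar volumes of cosolute and solvent, the
#' excluded-volume ratio `nu = Vbar_C / Vbar_S`, and the Flory-Huggins
#' interaction parameter as a van't Hoff temperature law
#' `chi(T) = chi_a + chi_b / T`, whose enthalpic part is `chi_H(T) = chi_b/T`
#' and entropic part `chi_TS(T) = -chi_a`, so that
#' `chi = chi_H - chi_TS` holds identically.
#'
#' @param name Cosolute name (e.g. `"trehalose"`).
#' @param M_C Cosolute molar mass, g/mol.
#' @param Vbar_C Cosolute partial molar volume, cm^3/mol.
#' @param Vbar_S Solvent (water) partial molar volume, cm^3/mol.
#' @param M_S Solvent molar mass, g/mol.
#' @param chi_a Temperature-independent (entropic) chi coefficient,
#'   dimensionless.
#' @param chi_b Enthalpic chi coefficient, units of K.
#'
#' @return An object of class `cosolute_params`.
#' @examples
#' tre <- cosolute_params("trehalose", M_C = 342.3, Vbar_C = 209.5,
#'                        chi_a = 1.2, chi_b = -180)
#' tre$nu
#' chi_at(tre, 298)
#' @export
cosolute_params <- function(name, M_C, Vbar_C,
                            Vbar_S = fh_constants$Vbar_water,
                            M_S = fh_constants$M_water,
                            chi_a = 0, chi_b = 0) {
  stopifnot(is.character(name), length(name) == 1)
  for (v in c(M_C = M_C, Vbar_C = Vbar_C, Vbar_S = Vbar_S, M_S = M_S)) {
    if (!is.finite(v) || v <= 0) {
      abort("M_C, Vbar_C, Vbar_S and M_S must be positive and finite.")
    }
  }
  structure(
    list(
      name = name, M_C = M_C, Vbar_C = Vbar_C, Vbar_S = Vbar_S, M_S = M_S,
      nu = Vbar_C / Vbar_S, chi_a = chi_a, chi_b = chi_b
    ),
    class = "cosolute_params"
  )
}

#' Flory-Huggins chi and its enthalpy/entropy split at a temperature
#'
#' @param params A [cosolute_params()] object.
#' @param T_K Temperature(s), K.
#' @return `chi_at()` returns `chi(T)` as a numeric vector; `chi_split()`
#'   returns a tibble with columns `T_K`, `chi`, `chi_H`, `chi_TS` satisfying
#'   `chi = chi_H - chi_TS` exactly.
#' @export
chi_at <- function(params, T_K) {
  stopifnot(inherits(params, "cosolute_params"), all(T_K > 0))
  params$chi_a + params$chi_b / T_K
}

#' @rdname chi_at
#' @export
chi_split <- function(params, T_K = fh_constants$T_ref) {
  chi_H <- params$chi_b / T_K
  chi_TS <- rep(-params$chi_a, length(T_K))
  tibble::tibble(T_K = T_K, chi = chi_H - chi_TS, chi_H = chi_H, chi_TS = chi_TS)
}

#' @export
print.cosolute_params <- function(x, ...) {
  cat("<cosolute_params> ", x$name, "\n", sep = "")
  cat(sprintf("  M_C = %.2f g/mol, Vbar_C = %.2f cm^3/mol, nu = %.3f\n",
              x$M_C, x$Vbar_C, x$nu))
  cat(sprintf("  chi(T) = %.4f + %.1f/T; chi(298) = %.4f\n",
              x$chi_a, x$chi_b, chi_at(x, 298)))
  invisible(x)
}

#' @export
tidy.cosolute_params <- function(x, T_K = fh_constants$T_ref, ...) {
  sp <- chi_split(x, T_K)
  tibble::tibble(
    name = x$name, M_C = x$M_C, Vbar_C = x$Vbar_C, Vbar_S = x$Vbar_S,
    nu = x$nu, chi_a = x$chi_a, chi_b = x$chi_b,
    T_K = sp$T_K, chi = sp$chi, chi_H = sp$chi_H, chi_TS = sp$chi_TS
  )
}

#' Protein parameter set for the crowding model
#'
#' Holds the surface-area change upon folding and the soft-interaction
#' parameter, with its enthalpy/entropy split. The per-contact free energy of
#' replacing a protein-water contact with a protein-cosolute contact follows
#' `epsilon(T) = eps_h * T0 / T + eps_s` (dimensionless, units of kT), so
#' `epsilon_H(T0) = eps_h` and `epsilon_TS(T0) = -eps_s`, and
#' `epsilon = epsilon_H - epsilon_TS` holds identically at `T0`.
#'
#' The lattice-site edge length `d_s` (Angstrom) defaults to the cube root of
#' the solvent molecular volume and sets the derived quantities
#' `n_buried = dsasa / d_s^2` (number of solvent-sized contact sites buried
#' upon folding) and the depletion-layer thickness
#' `delta = (d_s / 2) * (nu^{1/3} - 1)`, which vanishes for solvent-sized
#' cosolutes.
#'
#' @param name Protein name.
#' @param dsasa Solvent-accessible surface area buried upon folding,
#'   Angstrom^2 (positive).
#' @param epsilon Soft-interaction parameter at `T0`, dimensionless (kT).
#' @param eps_ts Entropic component `epsilon_TS(T0)`; defaults to 0
#'   (athermal epsilon). The split is stored as `eps_s = -eps_ts`,
#'   `eps_h = epsilon + eps_ts`, preserving `epsilon(T0) = epsilon`.
#' @param d_s Lattice site length, Angstrom. `NULL` (default) uses
#'   `(Vbar_S / N_A)^{1/3}`.
#' @param Vbar_S Solvent partial molar volume used for the default `d_s`,
#'   cm^3/mol.
#' @param T0 Reference temperature, K.
#'
#' @return An object of class `protein_params`.
#' @examples
#' met <- protein_params("MET16", dsasa = 1000, epsilon = 0.3, eps_ts = 1.5)
#' met$n_buried
#' epsilon_at(met, c(288, 298, 308))
#' @export
protein_params <- function(name, dsasa, epsilon = 0, eps_ts = 0,
                           d_s = NULL, Vbar_S = fh_constants$Vbar_water,
                           T0 = fh_constants$T_ref) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(dsasa) || dsasa <= 0) abort("dsasa must be positive (area buried upon folding).")
  if (is.null(d_s)) {
    # cm^3/molecule -> Angstrom^3/molecule (1 cm^3 = 1e24 A^3)
    d_s <- (Vbar_S / fh_constants$N_A * 1e24)^(1 / 3)
  }
  eps_s <- -eps_ts
  eps_h <- epsilon - eps_s
  structure(
    list(
      name = name, dsasa = dsasa, epsilon = epsilon,
      eps_h = eps_h, eps_s = eps_s, d_s = d_s, T0 = T0,
      n_buried = dsasa / d_s^2
    ),
    class = "protein_params"
  )
}

#' Soft-interaction parameter and its split at a temperature
#'
#' @param params A [protein_params()] object.
#' @param T_K Temperature(s), K.
#' @return `epsilon_at()` returns `epsilon(T)`; `epsilon_split()` a tibble
#'   with `T_K`, `epsilon`, `epsilon_H`, `epsilon_TS` satisfying
#'   `epsilon = epsilon_H - epsilon_TS` exactly.
#' @export
epsilon_at <- function(params, T_K) {
  stopifnot(inherits(params, "protein_params"), all(T_K > 0))
  params$eps_h * params$T0 / T_K + params$eps_s
}

#' @rdname epsilon_at
#' @export
epsilon_split <- function(params, T_K = params$T0) {
  eps_H <- params$eps_h * params$T0 / T_K
  eps_TS <- rep(-params$eps_s, length(T_K))
  tibble::tibble(T_K = T_K, epsilon = eps_H - eps_TS,
                 epsilon_H = eps_H, epsilon_TS = eps_TS)
}

#' Depletion-layer thickness for a cosolute at a protein surface
#'
#' `delta = (d_s / 2) * (nu^{1/3} - 1)`, in Angstrom; zero when the cosolute
#' is solvent-sized (`nu = 1`).
#'
#' @param protein A [protein_params()] object (supplies `d_s`).
#' @param cosolute A [cosolute_params()] object (supplies `nu`).
#' @return Thickness in Angstrom.
#' @export
depletion_thickness <- function(protein, cosolute) {
  (protein$d_s / 2) * (cosolute$nu^(1 / 3) - 1)
}

#' @export
print.protein_params <- function(x, ...) {
  cat("<protein_params> ", x$name, "\n", sep = "")
  cat(sprintf("  dSASA = %.0f A^2, d_s = %.3f A, N_buried = %.1f sites\n",
              x$dsasa, x$d_s, x$n_buried))
  cat(sprintf("  epsilon(T0=%g K) = %.3f kT (eps_H = %.3f, eps_TS = %.3f)\n",
              x$T0, x$epsilon, x$eps_h, -x$eps_s))
  invisible(x)
}

#' @export
tidy.protein_params <- function(x, ...) {
  tibble::tibble(
    name = x$name, dsasa = x$dsasa, epsilon = x$epsilon,
    epsilon_H = x$eps_h, epsilon_TS = -x$eps_s,
    d_s = x$d_s, n_buried = x$n_buried, T0 = x$T0
  )
}

#' Read or write parameter sets as JSON
#'
#' Round-trippable JSON serialization for [cosolute_params()] and
#' [protein_params()] objects.
#'
#' @param x Parameter object.
#' @param path File path.
#' @return `write_params_json()` returns `path` invisibly; the readers return
#'   the reconstructed object.
#' @export
write_params_json <- function(x, path) {
  stopifnot(inherits(x, c("cosolute_params", "protein_params")))
  out <- unclass(x)
  out$.class <- class(x)[[1]]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_cosolute_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cosolute_params(p$name, M_C = p$M_C, Vbar_C = p$Vbar_C, Vbar_S = p$Vbar_S,
                  M_S = p$M_S, chi_a = p$chi_a, chi_b = p$chi_b)
}

#' @rdname write_params_json
#' @export
read_protein_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  protein_params(p$name, dsasa = p$dsasa, epsilon = p$epsilon,
                 eps_ts = -p$eps_s, d_s = p$d_s, T0 = p$T0)
}
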