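# Two-domain mean-field crowding model. The ternary protein-cosolute-solvent
# system is split into a bulk domain and a protein surface domain:
#   * a sterically cosolute-free depletion shell of thickness
#     delta = (d_s/2)(nu^{1/3} - 1) carries the osmotic work term
#     ddG_nu = -Pi * dSASA * delta;
#   * a contact lattice layer of N_buried = dSASA / d_s^2 solvent-sized sites
#     carries the nonideal-mixing and soft-interaction physics, with the
#     surface cosolute volume fraction phi_s set by exchange equilibrium
#     against the bulk.
# All three terms vanish as c -> 0 and sum exactly to the total.

#' Exchange chemical potential of a Flory-Huggins lattice mixture
#'
#' The free-energy cost (in kT) of swapping nu solvent molecules for one
#' cosolute molecule at volume fraction `phi`:
#' `mu = ln(phi) - nu * ln(1 - phi) + (1 - nu) + chi * nu * ((1-phi)^2 - phi^2)`.
#' For `nu = 1, chi = 0` this reduces to the Langmuir form
#' `ln(phi / (1 - phi))`. Strictly increasing in `phi` for `chi <= 0.5`.
#'
#' @param phi Cosolute volume fraction, strictly inside (0, 1) (vectorized).
#' @param nu Excluded-volume ratio.
#' @param chi Flory-Huggins parameter.
#' @return Exchange potential in kT.
#' @export
exchange_potential <- function(phi, nu, chi) {
  if (any(phi <= 0 | phi >= 1)) abort("phi must lie strictly inside (0, 1).")
  log(phi) - nu * log1p(-phi) + (1 - nu) + chi * nu * ((1 - phi)^2 - phi^2)
}

#' Surface composition from exchange equilibrium
#'
#' Solves for the cosolute volume fraction `phi_s` in the protein contact
#' layer such that `mu(phi_s) + nu * epsilon = mu(phi_b)`: a cosolute at the
#' surface pays the per-contact replacement free energy `epsilon` on each of
#' the `nu` solvent-sized sites it occupies. Repulsive `epsilon > 0` depletes
#' the surface (`phi_s < phi_b`); attractive `epsilon < 0` enriches it.
#'
#' The root is located by a deterministic bracketed search (first sign change
#' scanning up from dilute compositions, then Brent's method, relative
#' tolerance 1e-12); when the chi is large enough for the exchange potential
#' to be non-monotone, the most dilute root - the branch continuously
#' connected to the bulk solution - is returned.
#'
#' @param phi_b Bulk cosolute volume fraction, in (0, 1) (vectorized).
#' @param nu Excluded-volume ratio.
#' @param chi Flory-Huggins parameter.
#' @param epsilon Per-contact soft-interaction free energy, kT.
#' @param Vbar_S Solvent partial molar volume (cm^3/mol), used to express the
#'   surface composition as a molarity.
#' @return A tibble with `phi_b`, `phi_s`, `mu_b` (bulk exchange potential,
#'   kT) and `m_surf` (surface cosolute molarity, mol/L).
#' @examples
#' surface_composition(0.1, nu = 1, chi = 0, epsilon = log(9))  # phi_s = 1/82
#' @export
surface_composition <- function(phi_b, nu, chi, epsilon,
                                Vbar_S = fh_constants$Vbar_water) {
  if (any(phi_b <= 0 | phi_b >= 1)) abort("phi_b must lie strictly inside (0, 1).")
  mu_b <- mu_hat(phi_b, nu, chi)
  phi_s <- vapply(phi_b, solve_phi_s, numeric(1), nu = nu, chi = chi,
                  epsilon = epsilon)
  tibble::tibble(
    phi_b = phi_b,
    phi_s = phi_s,
    mu_b = mu_b,
    # phi = molarity * nu * Vbar_S / 1000  =>  mol/L
    m_surf = 1000 * phi_s / (nu * Vbar_S)
  )
}

# Plain-numeric evaluation of the model terms; the hot path shared by the
# public decomposition wrapper and the fitting objectives (no data-frame
# construction). molality and T_K must already have a common length.
ddg_parts <- function(molality, T_K, cosolute, protein) {
  nu <- cosolute$nu
  delta <- (protein$d_s / 2) * (nu^(1 / 3) - 1)
  chiT <- cosolute$chi_a + cosolute$chi_b / T_K
  epsT <- protein$eps_h * protein$T0 / T_K + protein$eps_s
  n_S <- 1000 / cosolute$M_S
  vol <- n_S * cosolute$Vbar_S + molality * cosolute$Vbar_C
  phi_b <- molality * cosolute$Vbar_C / vol
  ln_aS <- log1p(-phi_b) + (1 - 1 / nu) * phi_b + chiT * phi_b^2
  Pi_Pa <- -(fh_constants$R * T_K / (cosolute$Vbar_S * 1e-6)) * ln_aS
  phi_s <- numeric(length(molality))
  nz <- which(molality > 0)
  if (length(nz)) {
    if (length(chiT) == 1) chiT <- rep_len(chiT, length(molality))
    if (length(epsT) == 1) epsT <- rep_len(epsT, length(molality))
    phi_s[nz] <- vapply(nz, function(i) {
      solve_phi_s(phi_b[i], nu, chiT[i], epsT[i])
    }, numeric(1))
  }
  # Pa * A^3/molecule -> J/mol: 1e-30 m^3 per A^3, times N_A
  RT <- fh_constants$R * T_K
  list(
    molality = molality, T_K = T_K, phi_b = phi_b, phi_s = phi_s,
    m_surf = 1000 * phi_s / (nu * cosolute$Vbar_S),
    Pi_Pa = Pi_Pa,
    ddg_nu = -Pi_Pa * protein$dsasa * delta * 1e-30 * fh_constants$N_A / 1000,
    ddg_chi = protein$n_buried * RT * chiT * (phi_s - phi_b)^2 / 1000,
    ddg_eps = -protein$n_buried * RT * epsT * phi_s / 1000
  )
}

ddg_total_fast <- function(molality, T_K, cosolute, protein) {
  p <- ddg_parts(molality, T_K, cosolute, protein)
  p$ddg_nu + p$ddg_chi + p$ddg_eps
}

# Unchecked vectorized exchange potential for internal hot paths.
mu_hat <- function(phi, nu, chi) {
  log(phi) - nu * log1p(-phi) + (1 - nu) + chi * nu * ((1 - phi)^2 - phi^2)
}

# Scalar root of mu_hat(phi) + nu*epsilon = mu_hat(phi_b).
# The exchange potential is monotone iff 2*chi*nu <= (1 + sqrt(nu))^2; in the
# non-monotone (demixing) regime the most dilute root - the branch
# continuously connected to the bulk solution - is selected by a first-sign-
# change scan. Extreme targets beyond floating-point brackets are handled by
# the asymptotic dilute/concentrated expansions of mu_hat.
solve_phi_s <- function(pb, nu, chi, epsilon) {
  if (epsilon == 0) return(pb)
  target <- mu_hat(pb, nu, chi) - nu * epsilon
  g <- function(phi) mu_hat(phi, nu, chi) - target
  lo <- 1e-12
  hi <- 1 - 1e-12
  g_lo <- g(lo)
  g_hi <- g(hi)
  if (g_lo > 0) {
    # root below machine bracket: mu_hat(phi) ~ ln(phi) + (1 - nu) + chi*nu
    return(exp(target - (1 - nu) - chi * nu))
  }
  if (g_hi < 0) {
    # root above bracket: mu_hat(phi) ~ -nu*ln(1 - phi) + (1 - nu) - chi*nu
    return(1 - exp(-(target - (1 - nu) + chi * nu) / nu))
  }
  monotone <- 2 * chi * nu <= (1 + sqrt(nu))^2
  if (!monotone) {
    grid <- stats::plogis(seq(stats::qlogis(lo), stats::qlogis(hi),
                              length.out = 600))
    gv <- g(grid)
    flip <- which(gv[-1] * gv[-length(gv)] <= 0)
    if (length(flip) == 0) {
      abort(sprintf(paste0(
        "No surface composition solves the exchange equilibrium for ",
        "phi_b = %.4g, nu = %.3g, chi = %.3g, epsilon = %.3g."),
        pb, nu, chi, epsilon))
    }
    i <- flip[[1]]
    lo <- grid[i]; hi <- grid[i + 1]
  }
  uniroot(g, c(lo, hi), tol = 1e-15)$root
}

#' Cosolute-induced change in folding free energy, decomposed
#'
#' Evaluates the crowding model at each (molality, temperature) pair and
#' splits the change in folding free energy into:
#' \describe{
#'   \item{`ddg_nu`}{Excluded volume: `-Pi(c,T) * dSASA * delta`, the osmotic
#'     work recovered when the cosolute-free depletion shell is buried;
#'     always stabilizing (<= 0) for `nu > 1`.}
#'   \item{`ddg_chi`}{Nonideal mixing: `N_buried * R T * chi(T) *
#'     (phi_s - phi_b)^2`, the penalty of mixing the differently concentrated
#'     surface layer into the bulk upon folding; destabilizing (>= 0)
#'     whenever `chi > 0`.}
#'   \item{`ddg_eps`}{Soft interactions: `-N_buried * R T * epsilon(T) *
#'     phi_s`, the per-contact replacement free energy released when the
#'     contact layer is buried; stabilizing for repulsive `epsilon > 0`,
#'     destabilizing for attractive `epsilon < 0`.}
#' }
#' The three terms sum to `ddg_total` exactly (shared code path). Energies
#' are kJ/mol; `*_per_sasa` copies are J/mol/Angstrom^2.
#'
#' @param molality Cosolute molality, mol/kg (vectorized).
#' @param T_K Temperature, K (length 1 or same length as `molality`).
#' @param cosolute A [cosolute_params()] object.
#' @param protein A [protein_params()] object.
#' @return A tibble with `molality`, `T_K`, `phi_b`, `phi_s`, `m_surf`,
#'   `Pi_Pa`, the three terms, `ddg_total`, and per-SASA copies.
#' @examples
#' tre <- cosolute_params("trehalose", 342.3, 209.5, chi_a = 1.2, chi_b = -180)
#' met <- protein_params("MET16", dsasa = 1000, epsilon = 0.3)
#' decompose_free_energy(seq(0, 1.5, 0.5), 298, tre, met)
#' @export
decompose_free_energy <- function(molality, T_K, cosolute, protein) {
  stopifnot(inherits(cosolute, "cosolute_params"),
            inherits(protein, "protein_params"))
  if (any(molality < 0)) abort("molality must be >= 0.")
  n <- max(length(molality), length(T_K))
  molality <- rep_len(molality, n)
  T_K <- rep_len(T_K, n)

  parts <- ddg_parts(molality, T_K, cosolute, protein)
  out <- tibble::as_tibble(parts)
  out$ddg_total <- out$ddg_nu + out$ddg_chi + out$ddg_eps
  for (col in c("ddg_nu", "ddg_chi", "ddg_eps", "ddg_total")) {
    out[[paste0(col, "_per_sasa")]] <- out[[col]] * 1000 / protein$dsasa
  }
  out
}

#' Asakura-Oosawa depletion baseline
#'
#' The literature excluded-volume estimate `ddG_AOM = Pi * dV_ex` with
#' `dV_ex = -dSASA * delta`: the osmotic work of burying the depletion shell.
#' It coincides with the crowding model's `ddg_nu` term by construction and
#' is reported separately as the steric baseline.
#'
#' @inheritParams decompose_free_energy
#' @return A tibble with `molality`, `T_K`, `Pi_Pa`, `dV_ex_A3` (Angstrom^3
#'   per protein), `ddg_aom` (kJ/mol).
#' @export
aom_free_energy <- function(molality, T_K, cosolute, protein) {
  stopifnot(inherits(cosolute, "cosolute_params"),
            inherits(protein, "protein_params"))
  n <- max(length(molality), length(T_K))
  molality <- rep_len(molality, n)
  T_K <- rep_len(T_K, n)
  delta <- depletion_thickness(protein, cosolute)
  dV_ex <- -protein$dsasa * delta
  purrr::map2_dfr(molality, T_K, function(m, Tk) {
    Pi <- if (m == 0) 0 else osmotic_pressure(m, cosolute, Tk)$Pi_Pa
    tibble::tibble(molality = m, T_K = Tk, Pi_Pa = Pi, dV_ex_A3 = dV_ex,
                   ddg_aom = Pi * dV_ex * 1e-30 * fh_constants$N_A / 1000)
  })
}

#' Preferential hydration change along an osmotic-stress curve
#'
#' The change upon folding in the preferential solvation coefficient,
#' `dGamma_S = (1 / Vbar_S) * d(ddG) / d(Pi)`, evaluated by central finite
#' differences of the model curve on an osmotic-pressure grid. Stabilizing
#' cosolutes give `dGamma_S < 0`; more negative means a larger stabilizing
#' effect (the slope is proportional to the m-value).
#'
#' @param cosolute A [cosolute_params()] object.
#' @param protein A [protein_params()] object.
#' @param molality Molality grid (positive, increasing). Either this or
#'   `Pi_grid` must be given.
#' @param Pi_grid Osmotic pressure grid, Pa (positive, increasing); inverted
#'   to molalities via [molality_at_pressure()].
#' @param T_K Temperature, K.
#' @return A tibble with `molality`, `Pi_Pa`, `ddg_total`, `dGamma_S`
#'   (dimensionless). A warning is raised when coarsening the grid changes
#'   the derivative by more than 0.1% (grid too coarse).
#' @export
preferential_hydration <- function(cosolute, protein, molality = NULL,
                                   Pi_grid = NULL, T_K = fh_constants$T_ref) {
  if (is.null(molality) && is.null(Pi_grid)) {
    abort("Supply either a molality grid or an osmotic-pressure grid.")
  }
  if (is.null(molality)) {
    if (any(Pi_grid <= 0) || is.unsorted(Pi_grid, strictly = TRUE)) {
      abort("Pi_grid must be positive and strictly increasing.")
    }
    molality <- molality_at_pressure(Pi_grid, cosolute, T_K)
  }
  if (any(molality <= 0) || is.unsorted(molality, strictly = TRUE)) {
    abort("molality grid must be positive and strictly increasing.")
  }
  if (length(molality) < 5) abort("Need at least 5 grid points.")
  dec <- decompose_free_energy(molality, T_K, cosolute, protein)
  dg_J <- dec$ddg_total * 1000
  Pi <- dec$Pi_Pa
  Vbar_S_m3 <- cosolute$Vbar_S * 1e-6

  slope <- function(x, y) {
    n <- length(x)
    s <- numeric(n)
    s[1] <- (y[2] - y[1]) / (x[2] - x[1])
    s[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    for (i in 2:(n - 1)) {
      h1 <- x[i] - x[i - 1]; h2 <- x[i + 1] - x[i]
      # three-point derivative on a non-uniform grid
      s[i] <- (-h2 / (h1 * (h1 + h2))) * y[i - 1] +
        ((h2 - h1) / (h1 * h2)) * y[i] +
        (h1 / (h2 * (h1 + h2))) * y[i + 1]
    }
    s
  }
  dGamma <- slope(Pi, dg_J) / Vbar_S_m3
  # coarseness check: recompute on every other point and compare
  if (length(Pi) >= 9) {
    idx <- seq(1, length(Pi), by = 2)
    coarse <- slope(Pi[idx], dg_J[idx]) / Vbar_S_m3
    interior <- seq(2, length(idx) - 1)
    rel <- abs(coarse[interior] - dGamma[idx][interior]) /
      pmax(abs(dGamma[idx][interior]), 1e-300)
    if (max(rel) > 1e-3) {
      warn("Osmotic-pressure grid may be too coarse for a converged dGamma_S (step-halving change > 0.1%).")
    }
  }
  tibble::tibble(molality = molality, Pi_Pa = Pi,
                 ddg_total = dec$ddg_total, dGamma_S = dGamma)
}

#' Model enthalpy and entropy of the cosolute effect
#'
#' Differentiates the model free energy with respect to temperature through
#' the Gibbs-Helmholtz relation, `ddH = d(ddG / T) / d(1 / T)`, using a
#' central difference with step `dT` (default 0.5 K); the entropic part is
#' then fixed by the identity `T * ddS = ddH - ddG`, which holds exactly by
#' construction. Per-term columns decompose the enthalpy the same way.
#'
#' @inheritParams decompose_free_energy
#' @param dT Finite-difference step, K.
#' @return A tibble with `molality`, `T_K`, `ddg`, `ddh`, `tdds` (kJ/mol)
#'   and per-term enthalpies `ddh_nu`, `ddh_chi`, `ddh_eps`.
#' @export
model_enthalpy_entropy <- function(molality, T_K, cosolute, protein, dT = 0.5) {
  n <- max(length(molality), length(T_K))
  molality <- rep_len(molality, n)
  T_K <- rep_len(T_K, n)
  lo <- ddg_parts(molality, T_K - dT, cosolute, protein)
  hi <- ddg_parts(molality, T_K + dT, cosolute, protein)
  mid <- ddg_parts(molality, T_K, cosolute, protein)
  tot <- function(p) p$ddg_nu + p$ddg_chi + p$ddg_eps
  gh <- function(g_lo, g_hi) {
    (g_lo / (T_K - dT) - g_hi / (T_K + dT)) / (1 / (T_K - dT) - 1 / (T_K + dT))
  }
  ddh <- gh(tot(lo), tot(hi))
  tibble::tibble(
    molality = molality, T_K = T_K,
    ddg = tot(mid),
    ddh = ddh,
    tdds = ddh - tot(mid),
    ddh_nu = gh(lo$ddg_nu, hi$ddg_nu),
    ddh_chi = gh(lo$ddg_chi, hi$ddg_chi),
    ddh_eps = gh(lo$ddg_eps, hi$ddg_eps)
  )
}
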