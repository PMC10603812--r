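# Reduction of two-state folding measurements: CD-style fractions, folding
# free energies, van't Hoff fits with optional constant heat capacity, and
# assembly of cosolute-induced deltas relative to buffer.

#' Fraction native from a two-state CD signal
#'
#' Linear two-state reduction at a single analysis wavelength:
#' `f_N = (MRE - MRE_D) / (MRE_N - MRE_D)`. Values outside (0, 1) are clipped
#' to `[1e-6, 1 - 1e-6]` with a warning (noise can push end points past the
#' baselines).
#'
#' @param mre Measured mean residue ellipticity values (deg cm^2/dmol).
#' @param mre_n,mre_d Native and denatured baselines at the same wavelength.
#' @return Fraction native, numeric.
#' @export
fraction_native <- function(mre, mre_n, mre_d) {
  if (isTRUE(all.equal(mre_n, mre_d))) {
    abort("Degenerate baselines: MRE_N and MRE_D must differ.")
  }
  f <- (mre - mre_d) / (mre_n - mre_d)
  out_of_range <- f < 0 | f > 1
  if (any(out_of_range)) {
    warn(sprintf("%d fraction(s) outside (0, 1) clipped to [1e-6, 1-1e-6].",
                 sum(out_of_range)))
  }
  pmin(pmax(f, 1e-6), 1 - 1e-6)
}

#' Folding free energy from the native fraction
#'
#' Two-state D = N equilibrium: `dG0 = -R T ln(f_N / (1 - f_N))` (kJ/mol),
#' so `f_N > 0.5` corresponds to `dG0 < 0` (folding favourable).
#'
#' @param f_native Fraction native, strictly inside (0, 1).
#' @param T_K Temperature, K.
#' @return Folding free energy, kJ/mol.
#' @examples
#' free_energy_from_fraction(0.9, 298)  # about -5.44 kJ/mol
#' @export
free_energy_from_fraction <- function(f_native, T_K) {
  if (any(f_native <= 0 | f_native >= 1)) {
    abort("f_native must lie strictly inside (0, 1).")
  }
  -fh_constants$R_kJ * T_K * log(f_native / (1 - f_native))
}

#' Native fraction implied by a folding free energy
#'
#' Inverse of [free_energy_from_fraction()].
#'
#' @param dg0 Folding free energy, kJ/mol.
#' @param T_K Temperature, K.
#' @return Fraction native.
#' @export
fraction_from_free_energy <- function(dg0, T_K) {
  1 / (1 + exp(dg0 / (fh_constants$R_kJ * T_K)))
}

#' Integrated van't Hoff fit of folding free energy versus temperature
#'
#' Fits `dG0(T) = dH0 - T dS0 + dCp * ((T - T0) - T ln(T / T0))` by linear
#' least squares, with the heat capacity change between native and denatured
#' states treated as a constant. When `fit_dcp = FALSE` the `dCp` term is
#' fixed at `dcp_fixed` (default 0) and only `dH0`, `dS0` are estimated; the
#' default follows the usual practice of releasing `dCp` only when the
#' temperature span supports it.
#'
#' @param data A data frame with columns `T_K` and `dG0_kJ_mol` (optionally
#'   `sigma` for inverse-variance weights).
#' @param T0 Reference temperature, K.
#' @param fit_dcp Estimate `dCp`? `NULL` (default) fits it only when the
#'   temperature span exceeds 25 K.
#' @param dcp_fixed Fixed heat capacity change (J/mol/K) used when
#'   `fit_dcp = FALSE`.
#' @return An object of class `vant_hoff_fit` with components `dh0` (kJ/mol),
#'   `ds0` (J/mol/K), `dcp` (J/mol/K), `T0`, `vcov` (kJ-based), `fitted`,
#'   `residuals`, `data`. Use [tidy()] / [glance()] / [predict()] to inspect.
#' @examples
#' d <- tibble::tibble(T_K = seq(283, 313, 5),
#'                     dG0_kJ_mol = -10 + T_K * 20 / 1000)
#' vant_hoff_fit(d)
#' @export
vant_hoff_fit <- function(data, T0 = fh_constants$T_ref, fit_dcp = NULL,
                          dcp_fixed = 0) {
  stopifnot(all(c("T_K", "dG0_kJ_mol") %in% names(data)))
  span <- diff(range(data$T_K))
  if (is.null(fit_dcp)) fit_dcp <- span > 25
  n_T <- length(unique(data$T_K))
  if (n_T < 3) abort("Need >= 3 distinct temperatures.")
  if (fit_dcp && n_T < 4) abort("Need >= 4 distinct temperatures to also fit dCp.")

  Tk <- data$T_K
  y <- data$dG0_kJ_mol
  w <- if ("sigma" %in% names(data)) 1 / pmax(data$sigma, 1e-12)^2 else rep(1, length(y))
  x_s <- -Tk                                  # coefficient = dS0 in kJ/mol/K
  x_c <- (Tk - T0) - Tk * log(Tk / T0)        # coefficient = dCp in kJ/mol/K

  if (fit_dcp) {
    fit <- lm(y ~ x_s + x_c, weights = w)
    if (any(!is.finite(coef(fit)))) {
      abort("Rank-deficient van't Hoff design: dCp is not identifiable from these temperatures.")
    }
    cf <- coef(fit); V <- suppressWarnings(vcov(fit))
    dh0 <- unname(cf[1]); ds0 <- unname(cf[2]) * 1000; dcp <- unname(cf[3]) * 1000
  } else {
    y_adj <- y - (dcp_fixed / 1000) * x_c
    fit <- lm(y_adj ~ x_s, weights = w)
    cf <- coef(fit); V <- suppressWarnings(vcov(fit))
    dh0 <- unname(cf[1]); ds0 <- unname(cf[2]) * 1000; dcp <- dcp_fixed
  }
  structure(
    list(dh0 = dh0, ds0 = ds0, dcp = dcp, T0 = T0, fit_dcp = fit_dcp,
         vcov = V, fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit)),
         data = tibble::as_tibble(data[, c("T_K", "dG0_kJ_mol")])),
    class = "vant_hoff_fit"
  )
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat("<vant_hoff_fit>\n")
  cat(sprintf("  dH0(T0=%g K) = %.3f kJ/mol, dS0 = %.2f J/mol/K, dCp = %.1f J/mol/K%s\n",
              x$T0, x$dh0, x$ds0, x$dcp, if (x$fit_dcp) "" else " (fixed)"))
  cat(sprintf("  dG0(T0) = %.3f kJ/mol; RMS residual = %.3g kJ/mol on %d points\n",
              x$dh0 - x$T0 * x$ds0 / 1000, sqrt(mean(x$residuals^2)),
              length(x$residuals)))
  invisible(x)
}

#' @export
tidy.vant_hoff_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  terms <- c("dH0_kJ_mol", "dS0_J_mol_K", "dCp_J_mol_K")
  est <- c(x$dh0, x$ds0, x$dcp)
  ses <- c(se[1], se[2] * 1000, if (x$fit_dcp) se[3] * 1000 else NA_real_)
  tibble::tibble(term = terms, estimate = est, std_error = unname(ses))
}

#' @export
glance.vant_hoff_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$residuals),
    sigma = sqrt(sum(x$residuals^2) / max(1, length(x$residuals) - 2 - x$fit_dcp)),
    dG0_T0 = x$dh0 - x$T0 * x$ds0 / 1000,
    fit_dcp = x$fit_dcp
  )
}

#' @export
predict.vant_hoff_fit <- function(object, T_K = object$data$T_K, ...) {
  object$dh0 - T_K * object$ds0 / 1000 +
    (object$dcp / 1000) * ((T_K - object$T0) - T_K * log(T_K / object$T0))
}

#' Assemble cosolute-induced deltas relative to buffer
#'
#' Subtracts the buffer (`molality == 0`) row from every condition:
#' `ddX(c) = X(c) - X(0)` for each value column, propagating variances by
#' summation when `*_se` columns are present.
#'
#' @param data A data frame with a `molality` column (containing 0) and one
#'   or more value columns (e.g. `dG0_kJ_mol`, `dH0_kJ_mol`,
#'   `dS0_J_mol_K`); extra grouping columns (e.g. `T_K`) are preserved and
#'   deltas are taken within them.
#' @param cols Character vector of value columns to difference; default all
#'   numeric columns except `molality` and grouping columns.
#' @param by Optional character vector of grouping columns.
#' @return A tibble like `data` with each value column replaced by its delta
#'   (prefixed `dd_`); the buffer rows carry exact zeros.
#' @export
assemble_deltas <- function(data, cols = NULL, by = NULL) {
  stopifnot("molality" %in% names(data))
  if (is.null(cols)) {
    cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                    c("molality", by))
    cols <- cols[!grepl("_se$", cols)]
  }
  grouped <- if (is.null(by)) data else dplyr::group_by(data, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::mutate(
    grouped,
    dplyr::across(dplyr::all_of(cols), function(x) {
      ref <- x[.data$molality == 0]
      if (length(ref) != 1) abort("Each group needs exactly one molality = 0 (buffer) row.")
      x - ref
    }, .names = "dd_{.col}"),
    dplyr::across(dplyr::any_of(paste0(cols, "_se")), function(x) {
      ref <- x[.data$molality == 0]
      sqrt(x^2 + ref^2)
    }, .names = "dd_{.col}")
  )
  dplyr::ungroup(out)
}

#' Finite-difference Gibbs-Helmholtz reduction of a folding surface
#'
#' Estimates the folding enthalpy at the reference temperature directly from
#' a measured `dG0(c, T)` surface as the numerical van't Hoff derivative
#' `dH0 = d(dG0/T) / d(1/T)`, using a central difference between the
#' `T0 - dT` and `T0 + dT` columns, and then forms the cosolute-induced
#' deltas relative to buffer: `ddg`, `ddh` and `tdds = ddh - ddg` (all at
#' `T0`, kJ/mol). Because it uses the same temperature step as the model's
#' own Gibbs-Helmholtz route ([model_enthalpy_entropy()]), the reduction is
#' exactly invertible on noiseless model-generated surfaces; for noisy data
#' prefer the smoothing [vant_hoff_fit()] per concentration.
#'
#' @param data Folding table with columns `molality`, `T_K`, `dG0_kJ_mol`,
#'   containing temperatures `T0 - dT`, `T0` and `T0 + dT` at every
#'   molality (including the buffer `molality = 0`).
#' @param T0 Reference temperature, K.
#' @param dT Temperature step, K (must match rows present in `data`).
#' @return A tibble with `molality`, `ddg`, `ddh`, `tdds` (kJ/mol; buffer
#'   row exactly zero).
#' @export
gibbs_helmholtz_deltas <- function(data, T0 = fh_constants$T_ref, dT = 0.5) {
  stopifnot(all(c("molality", "T_K", "dG0_kJ_mol") %in% names(data)))
  grab <- function(Tk) {
    d <- data[abs(data$T_K - Tk) < 1e-9, c("molality", "dG0_kJ_mol")]
    if (nrow(d) == 0) {
      abort(sprintf("Folding table lacks the T = %g K column needed for the central difference.", Tk))
    }
    dplyr::arrange(d, .data$molality)
  }
  lo <- grab(T0 - dT); mid <- grab(T0); hi <- grab(T0 + dT)
  if (!identical(lo$molality, mid$molality) ||
      !identical(hi$molality, mid$molality)) {
    abort("The three temperature columns must share the same molalities.")
  }
  if (!any(mid$molality == 0)) abort("Need a buffer (molality = 0) column.")
  dh <- (lo$dG0_kJ_mol / (T0 - dT) - hi$dG0_kJ_mol / (T0 + dT)) /
    (1 / (T0 - dT) - 1 / (T0 + dT))
  ref <- which(mid$molality == 0)
  tibble::tibble(
    molality = mid$molality,
    ddg = mid$dG0_kJ_mol - mid$dG0_kJ_mol[ref],
    ddh = dh - dh[ref],
    tdds = (dh - dh[ref]) - (mid$dG0_kJ_mol - mid$dG0_kJ_mol[ref])
  )
}

#' Locate the isodichroic point of a spectra set
#'
#' Finds the wavelength at which CD spectra recorded under different
#' conditions cross: the wavelength minimizing the across-spectra standard
#' deviation of MRE. A small spread at an interior minimum supports a
#' two-state equilibrium (only the native/denatured populations change, not
#' the structures).
#'
#' @param data Long-format spectra: columns `wavelength_nm`, `mre`, and one
#'   or more condition columns (e.g. `T_K`, `molality`).
#' @param threshold Spread (deg cm^2/dmol) below which two-state support is
#'   claimed.
#' @return A one-row tibble: `wavelength_nm`, `spread` (SD of MRE across
#'   spectra at that wavelength), `two_state` (spread below threshold),
#'   `interior` (minimum not at the grid edge), `degenerate` (all spectra
#'   identical everywhere).
#' @export
isodichroic_locate <- function(data, threshold = 100) {
  stopifnot(all(c("wavelength_nm", "mre") %in% names(data)))
  prof <- data |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(spread = sd(.data$mre), n = dplyr::n(), .groups = "drop")
  if (any(prof$n < 3)) abort("Need >= 3 spectra at each wavelength.")
  degenerate <- all(prof$spread < 1e-12)
  i <- which.min(prof$spread)
  interior <- i > 1 && i < nrow(prof)
  if (!interior && !degenerate) {
    # monotone variance profile: no crossing inside the scanned range
    return(tibble::tibble(wavelength_nm = NA_real_, spread = prof$spread[i],
                          two_state = FALSE, interior = FALSE,
                          degenerate = FALSE))
  }
  tibble::tibble(
    wavelength_nm = prof$wavelength_nm[i],
    spread = prof$spread[i],
    two_state = prof$spread[i] < threshold,
    interior = interior,
    degenerate = degenerate
  )
}
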