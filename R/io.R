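# CSV readers for the pipeline's tabular inputs. Each reader validates the
# schema and the cheap physical invariants so that generated bundles parse
# back with zero warnings.

read_checked <- function(path, col_types, required) {
  d <- readr::read_csv(path, col_types = col_types, show_col_types = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    abort(paste0(basename(path), " lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  d
}

#' Read pipeline CSV inputs
#'
#' Schema-validating readers for the tabular formats used throughout:
#' \describe{
#'   \item{density}{`cosolute, T_K, molality, density_g_cm3`; must include
#'     `molality = 0`, positive densities, strictly increasing molalities
#'     within each cosolute/temperature.}
#'   \item{activity}{`cosolute, T_K, molality, water_activity` with
#'     activities in (0, 1].}
#'   \item{folding}{`protein, cosolute, molality, T_K` plus `f_native`
#'     and/or `dG0_kJ_mol`.}
#'   \item{spectra}{long format `wavelength_nm, T_K, molality, mre`.}
#'   \item{hbonds}{`protein, state, condition, pair_id, donor_class,
#'     acceptor_class, n_mean, gbar_kJ_mol` with counts >= 0.}
#'   \item{md_energy}{`protein, sugar, dde_el, dde_vdw, p_ddv, dde_tot`.}
#' }
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @name readers
NULL

#' @rdname readers
#' @export
read_density_csv <- function(path) {
  d <- read_checked(path, readr::cols(cosolute = "c", .default = "d"),
                    c("cosolute", "T_K", "molality", "density_g_cm3"))
  if (any(d$density_g_cm3 <= 0)) abort("Densities must be positive.")
  if (any(d$molality < 0)) abort("Molalities must be >= 0.")
  grp <- dplyr::group_by(d, .data$cosolute, .data$T_K)
  ok <- dplyr::summarise(grp, has0 = any(.data$molality == 0),
                         incr = !is.unsorted(.data$molality, strictly = TRUE),
                         .groups = "drop")
  if (!all(ok$has0)) abort("Each density series must include molality = 0.")
  if (!all(ok$incr)) abort("Molalities must be strictly increasing within a series.")
  d
}

#' @rdname readers
#' @export
read_activity_csv <- function(path) {
  d <- read_checked(path, readr::cols(cosolute = "c", .default = "d"),
                    c("cosolute", "T_K", "molality", "water_activity"))
  if (any(d$water_activity <= 0 | d$water_activity > 1)) {
    abort("water_activity must lie in (0, 1].")
  }
  d
}

#' @rdname readers
#' @export
read_folding_csv <- function(path) {
  d <- read_checked(path, readr::cols(protein = "c", cosolute = "c",
                                      .default = "d"),
                    c("protein", "cosolute", "molality", "T_K"))
  if (!any(c("f_native", "dG0_kJ_mol") %in% names(d))) {
    abort("folding table needs an f_native or dG0_kJ_mol column.")
  }
  if ("f_native" %in% names(d) &&
      any(d$f_native <= 0 | d$f_native >= 1)) {
    abort("f_native must lie strictly inside (0, 1).")
  }
  d
}

#' @rdname readers
#' @export
read_spectra_csv <- function(path) {
  d <- read_checked(path, readr::cols(.default = "d"),
                    c("wavelength_nm", "T_K", "molality", "mre"))
  if (any(!is.finite(d$mre))) abort("MRE values must be finite.")
  d
}

#' @rdname readers
#' @export
read_hbonds_csv <- function(path) {
  d <- read_checked(path, readr::cols(n_mean = "d", gbar_kJ_mol = "d",
                                      .default = "c"),
                    c("protein", "state", "condition", "pair_id",
                      "donor_class", "acceptor_class", "n_mean",
                      "gbar_kJ_mol"))
  if (any(d$n_mean < 0)) abort("H-bond counts must be >= 0.")
  if (!all(d$state %in% c("N", "D"))) abort("state must be 'N' or 'D'.")
  d
}

#' @rdname readers
#' @export
read_md_energy_csv <- function(path) {
  read_checked(path, readr::cols(protein = "c", sugar = "c", .default = "d"),
               c("protein", "sugar", "dde_el", "dde_vdw"))
}
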