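# Synthetic-data generators. Every input the pipeline consumes can be
# produced here from a ground-truth parameter set, so each downstream fit can
# be validated by noiseless inversion and calibrated under realistic noise.
#
# One seed governs all tables: each generator draws under truth$seed plus a
# fixed per-table offset (density +101, activity +202, folding +303,
# spectra +404, hbonds +505), so bundles are reproducible piecewise.

#' Ground-truth parameter set for synthetic data
#'
#' Collects the cosolute, protein, buffer-folding baseline and noise scales
#' that define a synthetic study. Defaults emulate a trehalose-like
#' disaccharide (`nu` about 11.6, `chi(298)` about 0.6 with negative
#' entropic part) acting on a marginally stable MET16-like miniprotein
#' (repulsive soft interactions, `epsilon > 0`, with the entropic component
#' `epsilon_TS > 0`), and noise scales resembling typical densitometry,
#' water-activity and CD scatter.
#'
#' @param cosolute A [cosolute_params()] object.
#' @param protein A [protein_params()] object.
#' @param dh0,ds0,dcp Buffer folding baseline at `T0`: enthalpy (kJ/mol),
#'   entropy (J/mol/K) and constant heat-capacity change (J/mol/K).
#' @param T0 Reference temperature, K.
#' @param noise Named list of noise standard deviations: `density`
#'   (g/cm^3), `activity` (water activity), `dg` (kJ/mol), `mre`
#'   (deg cm^2/dmol). All must be >= 0.
#' @param seed Integer seed governing all generated tables.
#' @param spectra_class `"sheet"` (single CD minimum, MET16-like) or
#'   `"helix"` (double minimum, AQ16-like).
#' @param iso_nm Wavelength at which the synthetic basis spectra cross, nm.
#' @param analysis_nm Analysis wavelength for the two-state reduction;
#'   `NULL` picks the native-basis minimum (215-like for sheet, 222-like
#'   for helix).
#' @return An object of class `ground_truth`.
#' @examples
#' truth <- ground_truth(seed = 42)
#' truth$cosolute$nu
#' @export
ground_truth <- function(cosolute = cosolute_params("trehalose", M_C = 342.3,
                                                    Vbar_C = 209.5,
                                                    chi_a = 1.2, chi_b = -180),
                         protein = protein_params("MET16", dsasa = 1000,
                                                  epsilon = 0.05, eps_ts = 1.0),
                         dh0 = -10, ds0 = -20, dcp = -150,
                         T0 = fh_constants$T_ref,
                         noise = list(density = 5e-5, activity = 1e-4,
                                      dg = 0.1, mre = 200),
                         seed = 1234,
                         spectra_class = c("sheet", "helix"),
                         iso_nm = 207, analysis_nm = NULL) {
  spectra_class <- match.arg(spectra_class)
  stopifnot(inherits(cosolute, "cosolute_params"),
            inherits(protein, "protein_params"))
  defaults <- list(density = 5e-5, activity = 1e-4, dg = 0.1, mre = 200)
  noise <- utils::modifyList(defaults, as.list(noise))
  if (any(unlist(noise) < 0)) abort("Noise scales must be >= 0.")
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    abort("seed must be a single integer.")
  }
  if (is.null(analysis_nm)) {
    analysis_nm <- if (spectra_class == "sheet") 215 else 222
  }
  structure(
    list(cosolute = cosolute, protein = protein,
         baseline = list(dh0 = dh0, ds0 = ds0, dcp = dcp, T0 = T0),
         noise = noise, seed = as.integer(seed),
         spectra = list(class = spectra_class, iso_nm = iso_nm,
                        analysis_nm = analysis_nm)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> seed =", x$seed, "\n")
  print(x$cosolute)
  print(x$protein)
  cat(sprintf("  baseline: dH0 = %g kJ/mol, dS0 = %g J/mol/K, dCp = %g J/mol/K at T0 = %g K\n",
              x$baseline$dh0, x$baseline$ds0, x$baseline$dcp, x$baseline$T0))
  cat(sprintf("  spectra: %s class, isodichroic %g nm, analysis %g nm\n",
              x$spectra$class, x$spectra$iso_nm, x$spectra$analysis_nm))
  invisible(x)
}

#' Buffer folding free energy of a ground truth at given temperatures
#'
#' The integrated van't Hoff baseline
#' `dG0(T) = dH0 - T dS0 + dCp ((T - T0) - T ln(T/T0))`, kJ/mol.
#'
#' @param truth A [ground_truth()] object.
#' @param T_K Temperatures, K.
#' @return Numeric vector, kJ/mol.
#' @export
baseline_free_energy <- function(truth, T_K) {
  b <- truth$baseline
  b$dh0 - T_K * b$ds0 / 1000 +
    (b$dcp / 1000) * ((T_K - b$T0) - T_K * log(T_K / b$T0))
}

#' Generate a binary-solution density series
#'
#' Densities follow constant partial molar volumes: per kg water the volume
#' is `(1000 / M_S) * Vbar_S + m * Vbar_C` and the mass `1000 + m * M_C`,
#' plus additive Gaussian noise.
#'
#' @param truth A [ground_truth()] object.
#' @param molalities Molalities, mol/kg (>= 0; should include 0 for the
#'   downstream volume fit).
#' @param T_K Nominal measurement temperature recorded in the table, K.
#' @param noise Add Gaussian noise (sd `truth$noise$density`)?
#' @return A tibble: `cosolute`, `T_K`, `molality`, `density_g_cm3`.
#' @export
gen_density_series <- function(truth, molalities, T_K = truth$baseline$T0,
                               noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(molalities < 0)) abort("molalities must be >= 0.")
  cs <- truth$cosolute
  vol <- (1000 / cs$M_S) * cs$Vbar_S + molalities * cs$Vbar_C
  rho <- (1000 + molalities * cs$M_C) / vol
  if (noise && truth$noise$density > 0) {
    rho <- withr::with_seed(truth$seed + 101L, {
      rho + rnorm(length(rho), sd = truth$noise$density)
    })
  }
  tibble::tibble(cosolute = cs$name, T_K = T_K, molality = molalities,
                 density_g_cm3 = rho)
}

#' Generate a multi-temperature water-activity series
#'
#' Activities follow the Flory-Huggins closed form with
#' `chi(T) = chi_a + chi_b / T`, plus additive Gaussian noise. Values pushed
#' outside (0, 1] by noise are clipped back (reported via a message).
#'
#' @param truth A [ground_truth()] object.
#' @param molalities Molalities, mol/kg.
#' @param temperatures Temperatures, K; three or more distinct values are
#'   needed downstream for the van't Hoff split of chi.
#' @param noise Add Gaussian noise (sd `truth$noise$activity`)?
#' @return A tibble: `cosolute`, `T_K`, `molality`, `water_activity`.
#' @export
gen_activity_series <- function(truth, molalities,
                                temperatures = c(288, 293, 298, 303, 308),
                                noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(molalities < 0)) abort("molalities must be >= 0.")
  if (length(unique(temperatures)) < 3) {
    warn("Fewer than 3 distinct temperatures: downstream van't Hoff split of chi will not be possible.")
  }
  cs <- truth$cosolute
  grid <- tidyr::expand_grid(T_K = temperatures, molality = molalities)
  comp <- molality_to_composition(grid$molality, cs)
  a_S <- water_activity_fh(comp$phi_C, cs$nu, chi_at(cs, grid$T_K))
  if (noise && truth$noise$activity > 0) {
    a_S <- withr::with_seed(truth$seed + 202L, {
      a_S + rnorm(length(a_S), sd = truth$noise$activity)
    })
    n_clip <- sum(a_S > 1 | a_S <= 0)
    if (n_clip > 0) {
      rlang::inform(sprintf("%d activity value(s) clipped back into (0, 1].", n_clip))
      a_S <- pmin(pmax(a_S, 1e-9), 1)
    }
  }
  tibble::tibble(cosolute = cs$name, T_K = grid$T_K, molality = grid$molality,
                 water_activity = a_S)
}

#' Generate a folding dataset (and optionally CD spectra)
#'
#' Folding free energies are the buffer van't Hoff baseline plus the
#' crowding-model prediction:
#' `dG0(c, T) = baseline(T) + ddG_model(c, T)`. Native fractions follow the
#' two-state relation. With `spectra = TRUE`, long-format CD spectra are
#' built as `f_N * MRE_N + (1 - f_N) * MRE_D` from synthetic basis curves
#' crossing at the configured isodichroic wavelength.
#'
#' Noise: `noise_on = "dg"` adds Gaussian noise (sd `truth$noise$dg`) to the
#' free energies (fractions recomputed consistently); `noise_on = "mre"`
#' leaves the free energies exact and perturbs the spectra (sd
#' `truth$noise$mre`); `"none"` is fully noiseless.
#'
#' @param truth A [ground_truth()] object.
#' @param molalities Molalities, mol/kg (include 0 for the buffer column).
#' @param temperatures Temperatures, K.
#' @param spectra Also generate CD spectra?
#' @param wavelengths Wavelength grid, nm.
#' @param noise_on One of `"dg"`, `"mre"`, `"none"`.
#' @return With `spectra = FALSE`, a tibble `protein`, `cosolute`,
#'   `molality`, `T_K`, `f_native`, `dG0_kJ_mol`. Otherwise a list with
#'   elements `folding` and `spectra` (`wavelength_nm`, `T_K`, `molality`,
#'   `mre`).
#' @export
gen_folding_dataset <- function(truth, molalities,
                                temperatures = c(288, 293, 298, 303, 308),
                                spectra = FALSE,
                                wavelengths = seq(190, 260, by = 0.5),
                                noise_on = c("dg", "mre", "none")) {
  stopifnot(inherits(truth, "ground_truth"))
  noise_on <- match.arg(noise_on)
  grid <- tidyr::expand_grid(T_K = temperatures, molality = molalities)
  dec <- decompose_free_energy(grid$molality, grid$T_K,
                               truth$cosolute, truth$protein)
  dg <- baseline_free_energy(truth, grid$T_K) + dec$ddg_total
  if (noise_on == "dg" && truth$noise$dg > 0) {
    dg <- withr::with_seed(truth$seed + 303L, {
      dg + rnorm(length(dg), sd = truth$noise$dg)
    })
  }
  folding <- tibble::tibble(
    protein = truth$protein$name, cosolute = truth$cosolute$name,
    molality = grid$molality, T_K = grid$T_K,
    f_native = fraction_from_free_energy(dg, grid$T_K),
    dG0_kJ_mol = dg
  )
  if (!spectra) return(folding)

  basis <- cd_basis(wavelengths, class = truth$spectra$class,
                    iso_nm = truth$spectra$iso_nm)
  sp <- tidyr::expand_grid(
    folding[, c("molality", "T_K", "f_native")],
    tibble::tibble(wavelength_nm = wavelengths)
  ) |>
    dplyr::left_join(basis, by = "wavelength_nm") |>
    dplyr::mutate(mre = .data$f_native * .data$mre_n +
                    (1 - .data$f_native) * .data$mre_d) |>
    dplyr::select("wavelength_nm", "T_K", "molality", "mre")
  if (noise_on == "mre" && truth$noise$mre > 0) {
    sp$mre <- withr::with_seed(truth$seed + 404L, {
      sp$mre + rnorm(nrow(sp), sd = truth$noise$mre)
    })
  }
  list(folding = folding, spectra = sp)
}

#' Synthetic CD basis spectra
#'
#' Gaussian-mixture curves shaped like the CD signatures of an alpha-helix
#' (double minimum near 208/222 nm), a beta-sheet (single minimum near
#' 215 nm) and a disordered coil; the denatured basis is offset so native
#' and denatured curves cross exactly at `iso_nm`. These are props for
#' testing the two-state reduction, not spectroscopic models.
#'
#' @param wavelength Wavelengths, nm.
#' @param class `"sheet"` or `"helix"` native shape.
#' @param iso_nm Crossing (isodichroic) wavelength, nm.
#' @return A tibble: `wavelength_nm`, `mre_n`, `mre_d` (deg cm^2/dmol).
#' @export
cd_basis <- function(wavelength, class = c("sheet", "helix"), iso_nm = 207) {
  class <- match.arg(class)
  gauss <- function(x, mu, sig) exp(-((x - mu) / sig)^2)
  native_f <- function(x) {
    if (class == "helix") {
      -30000 * gauss(x, 208, 9) - 28000 * gauss(x, 222, 10) +
        55000 * gauss(x, 193, 8)
    } else {
      -20000 * gauss(x, 215, 11) + 28000 * gauss(x, 198, 7)
    }
  }
  coil_f <- function(x) -38000 * gauss(x, 198, 9) + 2500 * gauss(x, 220, 14)
  offset <- native_f(iso_nm) - coil_f(iso_nm)
  tibble::tibble(wavelength_nm = wavelength, mre_n = native_f(wavelength),
                 mre_d = coil_f(wavelength) + offset)
}

#' Default H-bond perturbation tables
#'
#' A small, structured set of donor-acceptor pair classes for both protein
#' states in water and in a sugar condition, emulating the perturbation seen
#' in MD summaries: protein-water bonds weaken (per-bond free energy rises)
#' and lose counts when sugar is added, while small protein-sugar terms
#' appear. `weaken_d > weaken_n` yields a denatured-state-dominant
#' perturbation (net H-bond stabilization of folding, MET16-like); reverse
#' the two for an AQ16-like destabilization.
#'
#' @param protein Protein label.
#' @param sugar Condition label for the sugar tables.
#' @param weaken_n,weaken_d Per-bond weakening of protein-water bonds in the
#'   native / denatured state, kJ/mol (positive = weaker).
#' @param dn_n,dn_d Change in protein-water bond counts (typically
#'   negative).
#' @param sugar_n,sugar_g Count and per-bond free energy of the
#'   protein-sugar-hydroxyl bonds that appear in the sugar condition.
#' @return A long tibble: `protein`, `state`, `condition`, `pair_id`,
#'   `donor_class`, `acceptor_class`, `n_mean`, `gbar_kJ_mol`.
#' @export
hbond_truth_tables <- function(protein = "MET16", sugar = "trehalose",
                               weaken_n = 0.15, weaken_d = 0.30,
                               dn_n = -1.4, dn_d = -1.5,
                               sugar_n = 1.2, sugar_g = -1.0) {
  base <- tibble::tibble(
    pair_id = c("bb-W", "sc-W", "bb-bb"),
    donor_class = c("backbone", "side_chain", "backbone"),
    acceptor_class = c("water", "water", "backbone"),
    n_n = c(18, 9, 6), g_n = c(-2.4, -2.0, -3.0),
    n_d = c(24, 11, 2), g_d = c(-2.2, -1.9, -3.0)
  )
  water <- dplyr::bind_rows(
    dplyr::transmute(base, state = "N", condition = "water",
                     pair_id = .data$pair_id, donor_class = .data$donor_class,
                     acceptor_class = .data$acceptor_class,
                     n_mean = .data$n_n, gbar_kJ_mol = .data$g_n),
    dplyr::transmute(base, state = "D", condition = "water",
                     pair_id = .data$pair_id, donor_class = .data$donor_class,
                     acceptor_class = .data$acceptor_class,
                     n_mean = .data$n_d, gbar_kJ_mol = .data$g_d)
  )
  perturb_one <- function(df, weaken, dn) {
    is_pw <- df$acceptor_class == "water"
    df$gbar_kJ_mol[is_pw] <- df$gbar_kJ_mol[is_pw] + weaken
    # spread the count loss across protein-water pairs proportionally
    df$n_mean[is_pw] <- pmax(0, df$n_mean[is_pw] +
                               dn * df$n_mean[is_pw] / sum(df$n_mean[is_pw]))
    df$condition <- sugar
    df
  }
  sugar_rows <- function(state, condition, n) {
    tibble::tibble(protein = protein, state = state, condition = condition,
                   pair_id = "bb-H", donor_class = "backbone",
                   acceptor_class = "sugar_hydroxyl",
                   n_mean = n, gbar_kJ_mol = sugar_g)
  }
  water$protein <- protein
  sugar_tabs <- dplyr::bind_rows(
    perturb_one(water[water$state == "N", ], weaken_n, dn_n),
    perturb_one(water[water$state == "D", ], weaken_d, dn_d),
    sugar_rows("N", sugar, sugar_n), sugar_rows("D", sugar, sugar_n)
  )
  # protein-sugar pairs exist with zero counts in pure water, keeping pair
  # sets aligned across conditions
  dplyr::bind_rows(water,
                   sugar_rows("N", "water", 0), sugar_rows("D", "water", 0),
                   sugar_tabs)
}

#' Generate H-bond record tables from truth tables
#'
#' Validates and (optionally) perturbs per-pair truth tables with Gaussian
#' noise on counts (truncated at zero) and per-bond free energies. Pair sets
#' must match across conditions within each state unless `zero_fill = TRUE`,
#' in which case missing pairs are added with zero counts (their per-bond
#' free energy borrowed from the condition where they exist).
#'
#' @param pairs Long truth tables as from [hbond_truth_tables()]: columns
#'   `state`, `condition`, `pair_id`, `donor_class`, `acceptor_class`,
#'   `n_mean`, `gbar_kJ_mol` (plus optional `protein`).
#' @param truth Optional [ground_truth()] supplying the seed; or give
#'   `seed` directly.
#' @param seed Integer seed (used as `seed + 505`).
#' @param noise_n,noise_g Gaussian noise sd on counts and per-bond free
#'   energies.
#' @param zero_fill Accept pair sets that differ across conditions.
#' @return A tibble of validated H-bond records.
#' @export
gen_hbond_tables <- function(pairs, truth = NULL, seed = NULL,
                             noise_n = 0, noise_g = 0, zero_fill = FALSE) {
  validate_hbond_records(pairs, require = c("state", "condition",
                                            "donor_class", "acceptor_class"))
  seed <- seed %||% (if (!is.null(truth)) truth$seed else 0L)
  out <- pairs |>
    dplyr::group_split(.data$state) |>
    purrr::map(function(df) {
      st <- df$state[[1]]
      conds <- unique(df$condition)
      ids <- lapply(conds, function(cc) df$pair_id[df$condition == cc])
      sets_match <- all(vapply(ids, setequal, logical(1), y = ids[[1]]))
      if (!sets_match) {
        if (!zero_fill) {
          abort("Pair sets differ across conditions within a state; set zero_fill = TRUE to zero-fill.")
        }
        all_pairs <- dplyr::distinct(df, .data$pair_id, .data$donor_class,
                                     .data$acceptor_class)
        filled <- tidyr::expand_grid(condition = conds, all_pairs) |>
          dplyr::left_join(df, by = c("condition", "pair_id", "donor_class",
                                      "acceptor_class")) |>
          dplyr::group_by(.data$pair_id) |>
          dplyr::mutate(
            gbar_kJ_mol = dplyr::coalesce(.data$gbar_kJ_mol,
                                          mean(.data$gbar_kJ_mol, na.rm = TRUE)),
            n_mean = dplyr::coalesce(.data$n_mean, 0),
            state = st
          ) |>
          dplyr::ungroup()
        if ("protein" %in% names(df)) {
          filled$protein <- df$protein[[1]]
        }
        df <- filled
      }
      df
    }) |>
    dplyr::bind_rows()
  if (noise_n > 0 || noise_g > 0) {
    out <- withr::with_seed(as.integer(seed) + 505L, {
      dplyr::mutate(out,
                    n_mean = pmax(0, .data$n_mean + rnorm(dplyr::n(), sd = noise_n)),
                    gbar_kJ_mol = .data$gbar_kJ_mol + rnorm(dplyr::n(), sd = noise_g))
    })
  }
  tibble::as_tibble(out)
}

#' Generate a full synthetic bundle
#'
#' Produces every table the pipeline consumes - density, multi-temperature
#' water activity, folding free energies, CD spectra and H-bond records -
#' from one [ground_truth()], together with a provenance block echoing the
#' truth. Deterministic under the truth's seed.
#'
#' @param truth A [ground_truth()] object.
#' @param molalities,temperatures Grids shared by the activity and folding
#'   tables.
#' @param wavelengths Spectra wavelength grid, nm.
#' @param hbond_pairs H-bond truth tables (default [hbond_truth_tables()]).
#' @param noise Generate with noise (`TRUE`) or noiseless (`FALSE`)?
#' @return An object of class `synthetic_bundle`: a list with elements
#'   `density`, `activity`, `folding`, `spectra`, `hbonds`, `truth`.
#' @export
synthetic_bundle <- function(truth = ground_truth(),
                             molalities = seq(0, 1.5, by = 0.25),
                             temperatures = c(288, 293, 298, 303, 308),
                             wavelengths = seq(190, 260, by = 0.5),
                             hbond_pairs = hbond_truth_tables(
                               protein = truth$protein$name,
                               sugar = truth$cosolute$name),
                             noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  fold <- gen_folding_dataset(truth, molalities, temperatures, spectra = TRUE,
                              wavelengths = wavelengths,
                              noise_on = if (noise) "dg" else "none")
  structure(
    list(
      density = gen_density_series(truth, molalities, noise = noise),
      activity = gen_activity_series(truth, molalities, temperatures,
                                     noise = noise),
      folding = fold$folding,
      spectra = fold$spectra,
      hbonds = gen_hbond_tables(hbond_pairs, truth = truth),
      truth = truth
    ),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>\n")
  for (nm in c("density", "activity", "folding", "spectra", "hbonds")) {
    cat(sprintf("  %-8s %5d rows\n", nm, nrow(x[[nm]])))
  }
  cat("  truth seed:", x$truth$seed, "\n")
  invisible(x)
}

ground_truth_to_list <- function(truth) {
  list(
    cosolute = unclass(truth$cosolute),
    protein = unclass(truth$protein),
    baseline = truth$baseline,
    noise = truth$noise,
    seed = truth$seed,
    spectra = truth$spectra
  )
}

ground_truth_from_list <- function(p) {
  ground_truth(
    cosolute = cosolute_params(p$cosolute$name, M_C = p$cosolute$M_C,
                               Vbar_C = p$cosolute$Vbar_C,
                               Vbar_S = p$cosolute$Vbar_S, M_S = p$cosolute$M_S,
                               chi_a = p$cosolute$chi_a, chi_b = p$cosolute$chi_b),
    protein = protein_params(p$protein$name, dsasa = p$protein$dsasa,
                             epsilon = p$protein$epsilon,
                             eps_ts = -p$protein$eps_s, d_s = p$protein$d_s,
                             T0 = p$protein$T0),
    dh0 = p$baseline$dh0, ds0 = p$baseline$ds0, dcp = p$baseline$dcp,
    T0 = p$baseline$T0, noise = p$noise, seed = p$seed,
    spectra_class = p$spectra$class, iso_nm = p$spectra$iso_nm,
    analysis_nm = p$spectra$analysis_nm
  )
}

#' Write or read a synthetic bundle as CSV files plus a provenance sidecar
#'
#' `write_bundle()` writes `density.csv`, `activity.csv`, `folding.csv`,
#' `spectra.csv`, `hbonds.csv` and `provenance.json` (the full ground truth)
#' into a directory; `read_bundle()` parses them back through the module
#' readers and reconstructs the truth, so bundles round-trip.
#'
#' @param bundle A [synthetic_bundle()].
#' @param dir Directory (created if needed).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()` a
#'   `synthetic_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$density, file.path(dir, "density.csv"))
  readr::write_csv(bundle$activity, file.path(dir, "activity.csv"))
  readr::write_csv(bundle$folding, file.path(dir, "folding.csv"))
  readr::write_csv(bundle$spectra, file.path(dir, "spectra.csv"))
  readr::write_csv(bundle$hbonds, file.path(dir, "hbonds.csv"))
  jsonlite::write_json(ground_truth_to_list(bundle$truth),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  truth <- ground_truth_from_list(
    jsonlite::read_json(file.path(dir, "provenance.json"),
                        simplifyVector = TRUE))
  structure(
    list(
      density = read_density_csv(file.path(dir, "density.csv")),
      activity = read_activity_csv(file.path(dir, "activity.csv")),
      folding = read_folding_csv(file.path(dir, "folding.csv")),
      spectra = read_spectra_csv(file.path(dir, "spectra.csv")),
      hbonds = read_hbonds_csv(file.path(dir, "hbonds.csv")),
      truth = truth
    ),
    class = "synthetic_bundle"
  )
}
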