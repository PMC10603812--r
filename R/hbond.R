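# Hydrogen-bond network free-energy bookkeeping on MD summary tables.
# Records carry, for one protein state (N or D) and solvent condition
# (water or a named sugar), the mean count n_mean and per-bond free energy
# gbar_kJ_mol of each donor-acceptor pair class. The network free energy is
# the count-weighted sum; sugar-induced changes and their exact
# decompositions follow by arithmetic.

hbond_classes <- c("backbone", "side_chain", "water", "sugar_hydroxyl",
                   "sugar_ether")
protein_classes <- c("backbone", "side_chain")

validate_hbond_records <- function(data, require = character()) {
  needed <- c("pair_id", "n_mean", "gbar_kJ_mol", require)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(paste0("H-bond records lack columns: ", paste(missing, collapse = ", ")))
  }
  if (any(data$n_mean < 0)) abort("H-bond counts n_mean must be >= 0.")
  invisible(data)
}

#' Total hydrogen-bond network free energy
#'
#' The count-weighted sum `sum(n_i * gbar_i)` over all donor-acceptor pair
#' classes of one protein/state/condition record set.
#'
#' @param data H-bond records with columns `pair_id`, `n_mean`,
#'   `gbar_kJ_mol` (one protein/state/condition).
#' @param allow_empty Return 0 for an empty record set instead of erroring.
#' @return Total free energy, kJ/mol.
#' @examples
#' network_free_energy(tibble::tibble(pair_id = "bb-W", n_mean = 10,
#'                                    gbar_kJ_mol = -2))
#' @export
network_free_energy <- function(data, allow_empty = FALSE) {
  if (nrow(data) == 0) {
    if (allow_empty) return(0)
    abort("Empty H-bond record set (use allow_empty = TRUE for 0).")
  }
  validate_hbond_records(data)
  if (anyDuplicated(data$pair_id)) {
    abort("Duplicate pair_id within one protein/state/condition record set.")
  }
  sum(data$n_mean * data$gbar_kJ_mol)
}

# Align two conditions on pair_id; pairs absent in one condition enter with
# n = 0 there and borrow the other condition's per-bond free energy (the
# borrowed value always multiplies a zero count, so totals are unaffected).
align_conditions <- function(reference, perturbed) {
  validate_hbond_records(reference)
  validate_hbond_records(perturbed)
  dplyr::full_join(
    dplyr::select(reference, "pair_id",
                  dplyr::any_of(c("donor_class", "acceptor_class")),
                  n_ref = "n_mean", g_ref = "gbar_kJ_mol"),
    dplyr::select(perturbed, "pair_id",
                  dplyr::any_of(c("donor_class", "acceptor_class")),
                  n_per = "n_mean", g_per = "gbar_kJ_mol"),
    by = intersect(c("pair_id", "donor_class", "acceptor_class"),
                   intersect(names(reference), names(perturbed)))
  ) |>
    dplyr::mutate(
      n_ref = dplyr::coalesce(.data$n_ref, 0),
      n_per = dplyr::coalesce(.data$n_per, 0),
      g_ref = dplyr::coalesce(.data$g_ref, .data$g_per),
      g_per = dplyr::coalesce(.data$g_per, .data$g_ref)
    )
}

#' Sugar-induced change in a state's H-bond network free energy
#'
#' `ddG_tot = sum(n_i' * gbar_i') - sum(n_i * gbar_i)` between a perturbed
#' condition (e.g. +sugar) and a reference condition (water) for one protein
#' state. Pairs absent in one condition (e.g. protein-sugar bonds in pure
#' water) are zero-filled. Weakened bonds (gbar rising toward zero) at
#' constant counts give a positive value, i.e. state destabilization.
#'
#' @param reference,perturbed H-bond records for the two conditions (same
#'   protein and state).
#' @return Change in total network free energy, kJ/mol.
#' @export
state_perturbation <- function(reference, perturbed) {
  al <- align_conditions(reference, perturbed)
  sum(al$n_per * al$g_per) - sum(al$n_ref * al$g_ref)
}

#' H-bond contribution to the folding free-energy change
#'
#' `ddG_fold = ddG_tot_N - ddG_tot_D`: negative values mean the denatured
#' state is more destabilized by the sugar than the native state, i.e. a net
#' H-bond stabilization of folding; positive values the reverse.
#'
#' @param ddg_tot_n,ddg_tot_d State perturbations from
#'   [state_perturbation()] for the native and denatured states, kJ/mol.
#' @return `ddG_fold`, kJ/mol.
#' @export
folding_perturbation <- function(ddg_tot_n, ddg_tot_d) {
  ddg_tot_n - ddg_tot_d
}

#' Split a state perturbation into strength and number components
#'
#' Exact decomposition of [state_perturbation()]:
#' \describe{
#'   \item{strength}{`sum(n_ref * (g_per - g_ref))` - reference counts times
#'     the change in per-bond free energy.}
#'   \item{number}{`sum((n_per - n_ref) * g_per)` - count changes valued at
#'     the perturbed per-bond free energy.}
#' }
#' The two components sum to the state perturbation by algebraic identity.
#' With `symmetric = TRUE` a Shapley-style split is used instead (strength
#' changes valued at mean counts, count changes at mean strengths), which is
#' also exact.
#'
#' @inheritParams state_perturbation
#' @param symmetric Use the symmetric (Shapley) convention.
#' @return A one-row tibble with `strength`, `number`, `total` (kJ/mol).
#' @export
strength_number_split <- function(reference, perturbed, symmetric = FALSE) {
  al <- align_conditions(reference, perturbed)
  if (symmetric) {
    strength <- sum((al$n_ref + al$n_per) / 2 * (al$g_per - al$g_ref))
    number <- sum((al$n_per - al$n_ref) * (al$g_ref + al$g_per) / 2)
  } else {
    strength <- sum(al$n_ref * (al$g_per - al$g_ref))
    number <- sum((al$n_per - al$n_ref) * al$g_per)
  }
  tibble::tibble(strength = strength, number = number,
                 total = strength + number)
}

#' Roll up H-bond records by protein moiety and partner class
#'
#' Groups records by which protein moiety (backbone or side chain) donates
#' or accepts, and by the partner class on the other side (water, sugar
#' hydroxyl, sugar ether, or another protein group), summing `n_mean *
#' gbar_kJ_mol` within groups. Group sums re-add to the grand total exactly.
#'
#' @param data H-bond records with `donor_class` and `acceptor_class` among
#'   backbone, side_chain, water, sugar_hydroxyl, sugar_ether.
#' @return A tibble with `moiety`, `partner`, `n_total`, `g_total`
#'   (kJ/mol).
#' @export
partner_rollup <- function(data) {
  validate_hbond_records(data, require = c("donor_class", "acceptor_class"))
  bad <- setdiff(unique(c(data$donor_class, data$acceptor_class)), hbond_classes)
  if (length(bad)) {
    abort(paste0("Unknown H-bond class label(s): ", paste(bad, collapse = ", "),
                 ". Valid labels: ", paste(hbond_classes, collapse = ", "), "."))
  }
  d <- data |>
    dplyr::mutate(
      donor_is_protein = .data$donor_class %in% protein_classes,
      acceptor_is_protein = .data$acceptor_class %in% protein_classes,
      moiety = dplyr::case_when(
        .data$donor_is_protein & .data$acceptor_is_protein ~ "protein-protein",
        .data$donor_is_protein ~ .data$donor_class,
        .data$acceptor_is_protein ~ .data$acceptor_class,
        TRUE ~ "solution-solution"
      ),
      partner = dplyr::case_when(
        .data$donor_is_protein & .data$acceptor_is_protein ~ "protein",
        .data$donor_is_protein ~ .data$acceptor_class,
        .data$acceptor_is_protein ~ .data$donor_class,
        TRUE ~ "solution"
      )
    )
  d |>
    dplyr::group_by(.data$moiety, .data$partner) |>
    dplyr::summarise(n_total = sum(.data$n_mean),
                     g_total = sum(.data$n_mean * .data$gbar_kJ_mol),
                     .groups = "drop")
}

#' Nonbonded energy sum of an MD energy summary
#'
#' `ddE_nb = ddE_el + ddE_vdW`, row-wise, on a summary table of
#' sugar-induced native-minus-denatured potential-energy differences.
#'
#' @param data A data frame with columns `dde_el` and `dde_vdw` (kJ/mol);
#'   other columns (protein, sugar, `p_ddv`, `dde_tot`) pass through.
#' @return The input tibble with a `dde_nb` column appended (or replaced).
#' @export
nb_sum <- function(data) {
  stopifnot(all(c("dde_el", "dde_vdw") %in% names(data)))
  dplyr::mutate(tibble::as_tibble(data), dde_nb = .data$dde_el + .data$dde_vdw)
}
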