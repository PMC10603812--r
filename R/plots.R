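# ggplot2 visualizations for the main result types.

#' Plot a free-energy decomposition
#'
#' Draws the excluded-volume, nonideal-mixing and soft-interaction
#' contributions and their total against molality, one line per term,
#' faceted by temperature when several are present.
#'
#' @param data Output of [decompose_free_energy()].
#' @param per_sasa Plot the per-buried-area columns (J/mol/Angstrom^2)
#'   instead of kJ/mol.
#' @return A ggplot object.
#' @export
plot_decomposition <- function(data, per_sasa = FALSE) {
  cols <- if (per_sasa) {
    c(excluded_volume = "ddg_nu_per_sasa", nonideal_mixing = "ddg_chi_per_sasa",
      soft_interaction = "ddg_eps_per_sasa", total = "ddg_total_per_sasa")
  } else {
    c(excluded_volume = "ddg_nu", nonideal_mixing = "ddg_chi",
      soft_interaction = "ddg_eps", total = "ddg_total")
  }
  long <- data |>
    dplyr::select("molality", "T_K", dplyr::all_of(unname(cols))) |>
    tidyr::pivot_longer(-c("molality", "T_K"), names_to = "term",
                        values_to = "value") |>
    dplyr::mutate(term = names(cols)[match(.data$term, cols)])
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$molality, y = .data$value,
                                          colour = .data$term)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "cosolute molality (mol/kg)",
                  y = if (per_sasa) expression(Delta * Delta * G^0 / Delta * SASA ~ "(J/mol/Å²)")
                  else expression(Delta * Delta * G^0 ~ "(kJ/mol)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(data$T_K)) > 1) p <- p + ggplot2::facet_wrap(~T_K)
  p
}

#' Plot a preferential-hydration curve
#'
#' @param data Output of [preferential_hydration()].
#' @return A ggplot object of `dGamma_S` against osmotic pressure.
#' @export
plot_preferential_hydration <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$Pi_Pa / 1e6, y = .data$dGamma_S)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Pi ~ "(MPa)"),
                  y = expression(Delta * Gamma[S])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vant_hoff_fit <- function(object, ...) {
  Tgrid <- seq(min(object$data$T_K), max(object$data$T_K), length.out = 100)
  pred <- tibble::tibble(T_K = Tgrid, dG0_kJ_mol = predict(object, Tgrid))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$T_K, y = .data$dG0_kJ_mol)) +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "T (K)", y = expression(Delta * G^0 ~ "(kJ/mol)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fit_result <- function(object, ...) {
  d <- object$data
  n <- nrow(d)
  if (object$parameter == "epsilon") {
    df <- tibble::tibble(molality = d$molality, observed = d$ddg,
                         fitted = object$fitted)
    ylab <- expression(Delta * Delta * G^0 ~ "(kJ/mol)")
  } else {
    df <- tibble::tibble(
      molality = rep(d$molality, 2),
      component = rep(c("ddH", "TddS"), each = n),
      observed = c(d$ddh, d$tdds),
      fitted = object$fitted
    )
    ylab <- "kJ/mol"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$molality)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "cosolute molality (mol/kg)", y = ylab,
                  title = paste0(object$parameter, " = ",
                                 signif(object$estimate, 4))) +
    ggplot2::theme_minimal()
  if (object$parameter != "epsilon") p <- p + ggplot2::facet_wrap(~component)
  p
}

#' Plot a spectra set with its isodichroic point
#'
#' @param data Long-format spectra (`wavelength_nm`, `mre`, condition
#'   columns).
#' @param iso Optional result of [isodichroic_locate()] to mark.
#' @return A ggplot object.
#' @export
plot_spectra <- function(data, iso = NULL) {
  d <- dplyr::mutate(data,
                     condition = interaction(.data$T_K, .data$molality,
                                             drop = TRUE))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$wavelength_nm, y = .data$mre,
                                       group = .data$condition,
                                       colour = .data$condition)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(MRE ~ "(deg" %.% "cm"^2 %.% "dmol"^-1 * ")")) +
    ggplot2::theme_minimal()
  if (!is.null(iso) && is.finite(iso$wavelength_nm)) {
    p <- p + ggplot2::geom_vline(xintercept = iso$wavelength_nm,
                                 colour = "grey40", linetype = 2)
  }
  p
}
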