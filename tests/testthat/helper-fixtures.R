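# Shared fixture builders. Truths are parameterized by the quantities the
# closure tests sweep: size ratio nu, chi at 298 K, and the soft-interaction
# pair (epsilon, epsilon_TS). chi(T) keeps a fixed enthalpic coefficient so
# the entropy/enthalpy split is nontrivial.

make_truth <- function(nu = 11.59269, chi0 = 0.6, eps = 0.05, eps_ts = 1,
                       chi_b = -150, dsasa = 1000, seed = 1, ...) {
  Vbar_S <- fh_constants$Vbar_water
  ground_truth(
    cosolute = cosolute_params("syn-cosolute", M_C = nu * 30,
                               Vbar_C = nu * Vbar_S,
                               chi_a = chi0 - chi_b / 298, chi_b = chi_b),
    protein = protein_params("syn-protein", dsasa = dsasa, epsilon = eps,
                             eps_ts = eps_ts),
    seed = seed, ...
  )
}

# Reduce a noiseless folding surface at T0 +/- dT to (ddg, ddh, tdds) and
# refit (epsilon, epsilon_TS); the end-to-end inversion used by the closure
# tests.
invert_folding <- function(truth, molalities = seq(0, 1.5, by = 0.25),
                           T0 = 298, dT = 0.5) {
  fold <- gen_folding_dataset(truth, molalities, c(T0 - dT, T0, T0 + dT),
                              noise_on = "none")
  gh <- gibbs_helmholtz_deltas(fold, T0 = T0, dT = dT)
  fe <- fit_epsilon(dplyr::transmute(gh, molality, ddg),
                    truth$cosolute, dsasa = truth$protein$dsasa, T_K = T0)
  fts <- fit_epsilon_ts(gh, epsilon = fe$estimate, truth$cosolute,
                        dsasa = truth$protein$dsasa, T0 = T0, dT = dT)
  list(epsilon = fe, epsilon_ts = fts)
}
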