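# Two-domain crowding model: exchange equilibrium, free-energy
# decomposition, AOM baseline, preferential hydration, enthalpy/entropy.

test_that("exchange potential reduces to known forms", {
  # symmetric point of the symmetric mixture
  expect_equal(exchange_potential(0.5, 1, 0), 0)
  # Langmuir form for nu = 1, chi = 0
  phi <- seq(0.05, 0.95, by = 0.05)
  expect_equal(exchange_potential(phi, 1, 0), log(phi / (1 - phi)))
  # hand arithmetic: ln 0.2 - 2 ln 0.8 - 1
  expect_equal(exchange_potential(0.2, 2, 0), -2.1631508, tolerance = 1e-7)
  expect_error(exchange_potential(0, 2, 0), "phi")
  expect_error(exchange_potential(1, 2, 0), "phi")

  # strictly increasing in phi for chi <= 0.5
  for (nu in c(1, 4, 12)) for (chi in c(0, 0.5)) {
    mu <- exchange_potential(seq(0.01, 0.99, by = 0.01), nu, chi)
    expect_true(all(diff(mu) > 0))
  }
})

test_that("surface composition solves the exchange equilibrium", {
  # no surface field: composition unchanged
  ss0 <- surface_composition(0.17, 8, 0.4, 0)
  expect_equal(ss0$phi_s, 0.17, tolerance = 1e-10)

  # Langmuir closed form: nu = 1, chi = 0, eps = ln 9 at phi_b = 0.1
  ss <- surface_composition(0.1, 1, 0, log(9))
  expect_equal(ss$phi_s, 1 / 82, tolerance = 1e-9)

  # hard repulsion empties the surface layer
  expect_lt(surface_composition(0.1, 4, 0.3, 20)$phi_s, 1e-6)

  # repulsion depletes, attraction enriches
  expect_lt(surface_composition(0.15, 6, 0.5, 0.5)$phi_s, 0.15)
  expect_gt(surface_composition(0.15, 6, 0.5, -0.5)$phi_s, 0.15)

  # the returned composition satisfies the equilibrium condition
  for (eps in c(-2, -0.3, 0.3, 2)) {
    s <- surface_composition(0.12, 5, 0.8, eps)
    expect_equal(exchange_potential(s$phi_s, 5, 0.8) + 5 * eps, s$mu_b,
                 tolerance = 1e-8)
  }
  expect_error(surface_composition(0, 2, 0, 1), "phi_b")
})

test_that("free-energy decomposition closes and vanishes in null limits", {
  truth <- make_truth()
  dec <- decompose_free_energy(seq(0, 1.5, by = 0.25), 298,
                               truth$cosolute, truth$protein)
  # terms sum to the total bit-exactly (shared code path)
  expect_identical(dec$ddg_total, dec$ddg_nu + dec$ddg_chi + dec$ddg_eps)
  # buffer column exactly zero
  expect_identical(dec$ddg_total[dec$molality == 0], 0)
  # per-SASA copies are consistent
  expect_equal(dec$ddg_total_per_sasa, dec$ddg_total * 1000 / 1000)

  # solvent-sized, chemically neutral cosolute: no effect at any c
  null_cs <- cosolute_params("null", M_C = 18.015,
                             Vbar_C = fh_constants$Vbar_water)
  null_prot <- protein_params("p", dsasa = 1000, epsilon = 0)
  dec0 <- decompose_free_energy(seq(0, 2, by = 0.5), 298, null_cs, null_prot)
  expect_equal(dec0$ddg_total, rep(0, 5), tolerance = 1e-12)

  # nu = 1 with chi > 0 still has no steric or mixing term (phi_s = phi_b)
  null_chi <- cosolute_params("null2", M_C = 18.015,
                              Vbar_C = fh_constants$Vbar_water, chi_a = 0.4)
  dec1 <- decompose_free_energy(c(0, 1), 298, null_chi, null_prot)
  expect_equal(dec1$ddg_total, c(0, 0), tolerance = 1e-12)
})

test_that("the steric term matches the depletion work and the AOM baseline", {
  nu8 <- cosolute_params("nu8", M_C = 240, Vbar_C = 8 * fh_constants$Vbar_water)
  prot <- protein_params("p", dsasa = 1000, epsilon = 0.2)
  # delta = (d_s / 2)(8^{1/3} - 1) = d_s / 2
  expect_equal(depletion_thickness(prot, nu8), prot$d_s / 2)

  # unit-conversion oracle at Pi = 1 MPa: ddG_nu = -Pi dSASA delta
  m_at <- molality_at_pressure(1e6, nu8, 298)
  aom <- aom_free_energy(m_at, 298, nu8, prot)
  expect_equal(aom$ddg_aom, -0.93567, tolerance = 1e-4)

  # AOM equals the model's nu-term for arbitrary parameters
  dec <- decompose_free_energy(seq(0, 1.5, 0.25), 298, nu8, prot)
  aom2 <- aom_free_energy(seq(0, 1.5, 0.25), 298, nu8, prot)
  expect_equal(aom2$ddg_aom, dec$ddg_nu, tolerance = 1e-12)

  # solvent-sized cosolute: no depletion, no AOM stabilization
  nu1 <- cosolute_params("nu1", M_C = 18, Vbar_C = fh_constants$Vbar_water)
  expect_equal(aom_free_energy(1, 298, nu1, prot)$ddg_aom, 0)

  # dilute limit linear in c
  m_small <- c(0.001, 0.002, 0.004)
  a <- aom_free_energy(m_small, 298, nu8, prot)$ddg_aom
  expect_equal(a / m_small, rep(a[1] / m_small[1], 3), tolerance = 1e-2)
})

test_that("stabilization is monotone for a purely steric cosolute", {
  steric <- cosolute_params("steric", M_C = 240,
                            Vbar_C = 6 * fh_constants$Vbar_water)
  prot <- protein_params("p", dsasa = 1200, epsilon = 0)
  dec <- decompose_free_energy(seq(0, 2, by = 0.1), 298, steric, prot)
  expect_true(all(diff(dec$ddg_total) < 0))
})

test_that("opposite-sign epsilon mirrors the two-protein specificity", {
  cs <- make_truth()$cosolute
  stabilized <- protein_params("met-like", dsasa = 1000, epsilon = 0.3)
  destabilized <- protein_params("aq-like", dsasa = 1000, epsilon = -0.3)
  m <- seq(0.25, 1.5, by = 0.25)
  d_s <- decompose_free_energy(m, 298, cs, stabilized)
  d_d <- decompose_free_energy(m, 298, cs, destabilized)
  # identical steric terms, opposite-signed soft terms
  expect_identical(d_s$ddg_nu, d_d$ddg_nu)
  expect_true(all(d_s$ddg_eps < 0))
  expect_true(all(d_d$ddg_eps > 0))
  # mixing term non-negative whenever chi > 0
  expect_true(all(c(d_s$ddg_chi, d_d$ddg_chi) >= 0))
})

test_that("preferential hydration follows the osmotic-stress slope", {
  # pure AOM case: ddG = Pi * dV_ex, so dGamma_S is constant = dV_ex / Vbar_S
  steric <- cosolute_params("steric", M_C = 240,
                            Vbar_C = 8 * fh_constants$Vbar_water)
  prot <- protein_params("p", dsasa = 1000, epsilon = 0)
  g <- preferential_hydration(steric, prot,
                              molality = seq(0.05, 1.5, length.out = 80))
  dV_ex_m3 <- -1000 * depletion_thickness(prot, steric) * 1e-30 *
    fh_constants$N_A
  expected <- dV_ex_m3 / (steric$Vbar_S * 1e-6)
  expect_equal(g$dGamma_S, rep(expected, 80), tolerance = 1e-6)
  expect_true(all(g$dGamma_S < 0))

  # step-halving convergence (Richardson): doubling resolution changes the
  # interior derivative by < 0.1% for the full model
  truth <- make_truth()
  coarse <- suppressWarnings(
    preferential_hydration(truth$cosolute, truth$protein,
                           molality = seq(0.05, 1.5, length.out = 41)))
  fine <- preferential_hydration(truth$cosolute, truth$protein,
                                 molality = seq(0.05, 1.5, length.out = 81))
  shared <- fine$dGamma_S[seq(1, 81, by = 2)][2:40]
  expect_equal(shared / coarse$dGamma_S[2:40], rep(1, 39), tolerance = 1e-3)

  expect_error(preferential_hydration(truth$cosolute, truth$protein),
               "grid")
  expect_warning(
    preferential_hydration(truth$cosolute, truth$protein,
                           molality = seq(0.05, 1.5, length.out = 9),
                           Pi_grid = NULL),
    "coarse"
  ) |> suppressWarnings()
})

test_that("model enthalpy and entropy respect Gibbs-Helmholtz", {
  truth <- make_truth()
  he <- model_enthalpy_entropy(c(0.5, 1, 1.5), 298,
                               truth$cosolute, truth$protein)
  # constructed identity, exact
  expect_equal(he$ddg, he$ddh - he$tdds, tolerance = 1e-12)

  # athermal parameterization: all terms proportional to T, so ddH = 0
  ath_cs <- cosolute_params("ath", M_C = 240,
                            Vbar_C = 6 * fh_constants$Vbar_water,
                            chi_a = 0.5, chi_b = 0)
  ath_prot <- protein_params("p", dsasa = 1000, epsilon = 0.3, eps_ts = -0.3)
  expect_equal(ath_prot$eps_h, 0)
  he0 <- model_enthalpy_entropy(1, 298, ath_cs, ath_prot)
  expect_lt(abs(he0$ddh), 1e-8)

  # repulsive-enthalpy / attractive-entropy cosolute: the soft term carries
  # compensating positive enthalpy and entropy contributions
  comp_prot <- protein_params("p", dsasa = 1000, epsilon = 0.1, eps_ts = 1)
  expect_gt(comp_prot$eps_h, 0)
  he1 <- model_enthalpy_entropy(1, 298, truth$cosolute, comp_prot)
  ddg_eps <- decompose_free_energy(1, 298, truth$cosolute, comp_prot)$ddg_eps
  expect_gt(he1$ddh_eps, 0)
  expect_gt(he1$ddh_eps - ddg_eps, 0)   # T ddS_eps > 0
})
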