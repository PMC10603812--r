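# Binary-solution parameterization: composition bookkeeping, partial molar
# volumes from density, chi from water activity, osmotic pressure.

test_that("molality converts to composition consistently", {
  cs <- cosolute_params("toy", M_C = 180, Vbar_C = 180, Vbar_S = 18.0,
                        M_S = 18.015)
  c0 <- molality_to_composition(0, cs)
  expect_equal(c0$phi_C, 0)
  expect_equal(c0$phi_S, 1)

  # hand arithmetic: phi_C = 180 / (55.509 * 18 + 180)
  c1 <- molality_to_composition(1, cs)
  expect_equal(c1$phi_C, 0.152650, tolerance = 1e-5)

  # phi_C / molarity equals Vbar_C (in L/mol) at every molality
  grid <- molality_to_composition(seq(0.1, 2, by = 0.1), cs)
  expect_equal(grid$phi_C / grid$molarity, rep(180 / 1000, nrow(grid)))
  expect_equal(grid$phi_C + grid$phi_S, rep(1, nrow(grid)))

  # inversion round trip
  m <- composition_to_molality(grid$phi_C, cs)
  expect_equal(m, grid$molality, tolerance = 1e-12)
  expect_error(molality_to_composition(-0.1, cs), "molality")
})

test_that("partial molar volumes are recovered from density series", {
  truth <- make_truth()
  dens <- gen_density_series(truth, seq(0, 1.5, by = 0.25), noise = FALSE)
  fit <- fit_partial_molar_volume(dens, M_C = truth$cosolute$M_C)
  expect_equal(fit$estimate[fit$term == "Vbar_C"], truth$cosolute$Vbar_C,
               tolerance = 1e-9)
  expect_equal(fit$estimate[fit$term == "Vbar_S"], truth$cosolute$Vbar_S,
               tolerance = 1e-9)
  expect_equal(unique(fit$nu), truth$cosolute$nu, tolerance = 1e-9)

  # the m = 0 point alone pins Vbar_S = M_S / rho_0
  rho0 <- dens$density_g_cm3[dens$molality == 0]
  expect_equal(fh_constants$M_water / rho0, truth$cosolute$Vbar_S,
               tolerance = 1e-12)

  expect_error(fit_partial_molar_volume(dens[1:2, ], M_C = 342), "3")
  no_zero <- dens[dens$molality > 0, ]
  expect_error(fit_partial_molar_volume(no_zero, M_C = 342), "m = 0")
})

test_that("density-fit uncertainty is calibrated under measurement noise", {
  # sigma_rho = 5e-5 g/cm^3, n = 10: Vbar_C within 2 SE in >= 90% of draws
  truth <- make_truth(seed = 7)
  mols <- seq(0, 1.8, length.out = 10)
  hits <- withr::with_seed(7, {
    vapply(1:200, function(b) {
      d <- gen_density_series(truth, mols, noise = FALSE)
      d$density_g_cm3 <- d$density_g_cm3 + rnorm(10, sd = 5e-5)
      f <- fit_partial_molar_volume(d, M_C = truth$cosolute$M_C)
      i <- f$term == "Vbar_C"
      abs(f$estimate[i] - truth$cosolute$Vbar_C) <= 2 * f$std_error[i]
    }, logical(1))
  })
  expect_gte(mean(hits), 0.90)
})

test_that("FH water activity matches its closed form and limits", {
  expect_equal(water_activity_fh(0, 10, 0.5), 1)
  # nu = 1, chi = 0 reduces to the ideal lattice a_S = phi_S
  phi <- seq(0, 0.9, by = 0.1)
  expect_equal(water_activity_fh(phi, 1, 0), 1 - phi)
  # hand evaluation: ln a_S = ln 0.8 + 0.9 * 0.2 + 0.5 * 0.04
  expect_equal(water_activity_fh(0.2, 10, 0.5), 0.9771222, tolerance = 1e-6)
  expect_error(water_activity_fh(1, 10, 0.5), "phi_C")

  # a_S strictly decreasing in phi_C for chi <= 0.5, nu >= 1
  for (nu in c(1, 3, 10)) for (chi in c(-0.2, 0, 0.5)) {
    a <- water_activity_fh(seq(0.01, 0.5, by = 0.01), nu, chi)
    expect_true(all(diff(a) < 0))
  }
})

test_that("chi is recovered from activity series", {
  truth <- make_truth(chi0 = 0.8, chi_b = 0)   # T-independent chi = 0.8
  act <- gen_activity_series(truth, seq(0, 1.5, by = 0.25), 298,
                             noise = FALSE) |> suppressWarnings()
  fit <- fit_chi(act, truth$cosolute)
  expect_equal(fit$estimate, 0.8, tolerance = 1e-10)
  expect_false(fit$suspect)

  ideal <- make_truth(chi0 = 0, chi_b = 0)
  act0 <- gen_activity_series(ideal, seq(0, 1.5, by = 0.25), 298,
                              noise = FALSE) |> suppressWarnings()
  expect_equal(fit_chi(act0, ideal$cosolute)$estimate, 0, tolerance = 1e-10)
})

test_that("the van't Hoff split of chi(T) is exact and self-consistent", {
  # a = 2, b = -500 K: chi(298) = 0.3221, chi_TS = -2, chi_H = -1.6779
  d <- tibble::tibble(T_K = c(288, 298, 308), chi = 2 - 500 / c(288, 298, 308))
  fit <- fit_chi_temperature(d)
  est <- setNames(fit$estimate, fit$term)
  expect_equal(unname(est["chi_a"]), 2, tolerance = 1e-9)
  expect_equal(unname(est["chi_b"]), -500, tolerance = 1e-6)
  expect_equal(unname(est["chi_T0"]), 0.3221477, tolerance = 1e-6)
  expect_equal(unname(est["chi_TS_T0"]), -2, tolerance = 1e-9)
  expect_equal(unname(est["chi_H_T0"]), -500 / 298, tolerance = 1e-9)
  # identity chi = chi_H - chi_TS, exactly
  expect_identical(est[["chi_T0"]], est[["chi_H_T0"]] - est[["chi_TS_T0"]])

  # athermal case: b = 0 gives purely entropic chi
  d0 <- tibble::tibble(T_K = c(288, 298, 308), chi = 0.7)
  f0 <- fit_chi_temperature(d0)
  expect_equal(f0$estimate[f0$term == "chi_H_T0"], 0, tolerance = 1e-10)
  expect_error(fit_chi_temperature(d0[1:2, ]), "3")
})

test_that("noisy chi(T) coefficients land inside their confidence intervals", {
  truth <- make_truth(chi0 = 0.6, chi_b = -150, seed = 1,
                      noise = list(activity = 1e-4))
  mols <- seq(0, 1.75, by = 0.25)
  temps <- c(288, 298, 308, 318)
  hits <- withr::with_seed(1, {
    vapply(1:200, function(b) {
      act <- gen_activity_series(truth, mols, temps, noise = FALSE)
      act$water_activity <- pmin(1, act$water_activity +
                                   rnorm(nrow(act), sd = 1e-4))
      per_T <- act |>
        dplyr::group_by(T_K) |>
        dplyr::group_modify(~fit_chi(.x, truth$cosolute)) |>
        dplyr::ungroup()
      f <- fit_chi_temperature(per_T |> dplyr::rename(chi = estimate))
      a_i <- f$term == "chi_a"; b_i <- f$term == "chi_b"
      c(abs(f$estimate[a_i] - truth$cosolute$chi_a) <= 1.96 * f$std_error[a_i],
        abs(f$estimate[b_i] - truth$cosolute$chi_b) <= 1.96 * f$std_error[b_i])
    }, logical(2))
  })
  expect_gte(mean(hits[1, ]), 0.85)   # nominal 95%
  expect_gte(mean(hits[2, ]), 0.85)
})

test_that("osmotic pressure has the right magnitude and dilute limit", {
  ideal <- cosolute_params("ideal", M_C = 18.015, Vbar_C = 18.0,
                           Vbar_S = 18.0)
  expect_equal(osmotic_pressure(0, ideal)$Pi_Pa, 0)

  # closed form at phi = 0.1: Pi = -(RT / 1.8e-5) ln 0.9
  m <- composition_to_molality(0.1, ideal)
  expect_equal(osmotic_pressure(m, ideal, 298)$Pi_Pa, 14502933,
               tolerance = 1e-6)

  # van't Hoff limit: Pi -> RT * molarity as phi -> 0
  big <- cosolute_params("big", M_C = 342, Vbar_C = 210, chi_a = 0.6)
  m_small <- composition_to_molality(c(1e-4, 5e-4, 1e-3), big)
  op <- osmotic_pressure(m_small, big, 298)
  molar <- molality_to_composition(m_small, big)$molarity
  ratio <- op$Pi_Pa / (fh_constants$R * 298 * molar * 1000)
  expect_true(all(abs(ratio - 1) < 0.01))

  # superlinear deviation from the van't Hoff law for nu > 1 (chi = 0):
  # Pi / (RT * molarity) grows with concentration
  hard <- cosolute_params("hard", M_C = 342, Vbar_C = 210)
  m_grid <- seq(0.2, 2, by = 0.2)
  molar2 <- molality_to_composition(m_grid, hard)$molarity
  ratio2 <- osmotic_pressure(m_grid, hard, 298)$Pi_Pa /
    (fh_constants$R * 298 * molar2 * 1000)
  expect_true(all(diff(ratio2) > 0))
  expect_true(all(ratio2 > 1))

  # pressure inversion round-trips
  pi_t <- c(1e5, 1e6, 1e7)
  m_back <- molality_at_pressure(pi_t, big, 298)
  expect_equal(osmotic_pressure(m_back, big, 298)$Pi_Pa, pi_t,
               tolerance = 1e-9)
})
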