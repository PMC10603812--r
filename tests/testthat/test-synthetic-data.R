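# Generators: deterministic under seed, physically exact when noiseless, and
# round-trippable through the readers.

test_that("density generator reproduces pure water and is seeded", {
  truth <- make_truth()
  d <- gen_density_series(truth, c(0, 0.5, 1), noise = FALSE)
  # rho(0) = M_S / Vbar_S = 18.015 / 18.07
  expect_equal(d$density_g_cm3[1], 0.9969563, tolerance = 1e-7)
  expect_error(gen_density_series(truth, c(-1, 0)), "molalities")

  d1 <- gen_density_series(truth, seq(0, 1, 0.25))
  d2 <- gen_density_series(truth, seq(0, 1, 0.25))
  expect_identical(d1, d2)
  expect_false(identical(d1$density_g_cm3,
                         gen_density_series(make_truth(seed = 2),
                                            seq(0, 1, 0.25))$density_g_cm3))
})

test_that("activity generator hits the pure-solvent limit and inverts", {
  truth <- make_truth(chi0 = 0.6)
  act <- gen_activity_series(truth, seq(0, 1, by = 0.25), c(288, 298, 308),
                             noise = FALSE)
  expect_equal(act$water_activity[act$molality == 0], rep(1, 3))
  expect_error(gen_activity_series(truth, c(-0.5, 0)), "molalities")

  # noiseless inversion recovers chi(T) exactly at each temperature
  per_T <- act |>
    dplyr::group_by(T_K) |>
    dplyr::group_modify(~fit_chi(.x, truth$cosolute)) |>
    dplyr::ungroup()
  expect_equal(per_T$estimate, chi_at(truth$cosolute, per_T$T_K),
               tolerance = 1e-10)

  a1 <- gen_activity_series(truth, seq(0, 1, 0.25), c(288, 298, 308))
  a2 <- gen_activity_series(truth, seq(0, 1, 0.25), c(288, 298, 308))
  expect_identical(a1, a2)
})

test_that("folding generator is exact at c = 0 and at the isodichroic point", {
  truth <- make_truth()
  out <- gen_folding_dataset(truth, c(0, 0.75, 1.5), c(293, 298, 303),
                             spectra = TRUE, noise_on = "none")
  buf <- out$folding[out$folding$molality == 0, ]
  expect_equal(buf$dG0_kJ_mol, baseline_free_energy(truth, buf$T_K),
               tolerance = 1e-12)
  # two-state consistency between the reported fraction and free energy
  expect_equal(out$folding$dG0_kJ_mol,
               free_energy_from_fraction(out$folding$f_native,
                                         out$folding$T_K),
               tolerance = 1e-9)
  # spectra identical across all conditions at the crossing wavelength
  at_iso <- out$spectra[out$spectra$wavelength_nm == truth$spectra$iso_nm, ]
  expect_equal(diff(range(at_iso$mre)), 0, tolerance = 1e-9)
})

test_that("hbond generator validates, zero-fills and is seeded", {
  tabs <- hbond_truth_tables()
  rec <- gen_hbond_tables(tabs, seed = 1)
  expect_identical(rec, gen_hbond_tables(tabs, seed = 1))

  # identical water and sugar tables: all downstream deltas vanish
  null_tabs <- dplyr::bind_rows(
    tabs[tabs$condition == "water", ],
    dplyr::mutate(tabs[tabs$condition == "water", ], condition = "sugar"))
  rec0 <- gen_hbond_tables(null_tabs)
  by_state <- function(recs, st, cond) {
    recs[recs$state == st & recs$condition == cond,
         c("pair_id", "donor_class", "acceptor_class", "n_mean", "gbar_kJ_mol")]
  }
  ddn <- state_perturbation(by_state(rec0, "N", "water"),
                            by_state(rec0, "N", "sugar"))
  ddd <- state_perturbation(by_state(rec0, "D", "water"),
                            by_state(rec0, "D", "sugar"))
  expect_equal(c(ddn, ddd), c(0, 0))

  # mismatched pair sets rejected unless zero-filled
  broken <- tabs[!(tabs$condition == "water" & tabs$pair_id == "sc-W"), ]
  expect_error(gen_hbond_tables(broken), "zero_fill")
  filled <- gen_hbond_tables(broken, zero_fill = TRUE)
  added <- filled[filled$condition == "water" & filled$pair_id == "sc-W", ]
  expect_equal(added$n_mean, c(0, 0))

  # noisy counts stay non-negative and are reproducible under the seed
  noisy1 <- gen_hbond_tables(tabs, seed = 3, noise_n = 0.5, noise_g = 0.1)
  noisy2 <- gen_hbond_tables(tabs, seed = 3, noise_n = 0.5, noise_g = 0.1)
  expect_identical(noisy1, noisy2)
  expect_true(all(noisy1$n_mean >= 0))
})

test_that("the default hbond truth gives a MET16-like folding stabilization", {
  tabs <- gen_hbond_tables(hbond_truth_tables())
  grab <- function(st, cond) {
    tabs[tabs$state == st & tabs$condition == cond, ]
  }
  ddn <- state_perturbation(grab("N", "water"), grab("N", "trehalose"))
  ddd <- state_perturbation(grab("D", "water"), grab("D", "trehalose"))
  # both states destabilized by sugar, denatured more so
  expect_gt(ddn, 0)
  expect_gt(ddd, ddn)
  expect_lt(folding_perturbation(ddn, ddd), 0)
})

test_that("bundles are deterministic and round-trip through the readers", {
  truth <- make_truth(seed = 99)
  b1 <- synthetic_bundle(truth, molalities = seq(0, 1, by = 0.25),
                         temperatures = c(293, 298, 303),
                         wavelengths = seq(200, 230, by = 1))
  b2 <- synthetic_bundle(truth, molalities = seq(0, 1, by = 0.25),
                         temperatures = c(293, 298, 303),
                         wavelengths = seq(200, 230, by = 1))
  expect_identical(b1[c("density", "activity", "folding", "spectra", "hbonds")],
                   b2[c("density", "activity", "folding", "spectra", "hbonds")])

  dir <- withr::local_tempdir()
  write_bundle(b1, dir)
  back <- read_bundle(dir)
  for (tab in c("density", "activity", "folding", "spectra", "hbonds")) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(b1[[tab]]),
                 tolerance = 1e-12)
  }
  # provenance reconstructs the truth, including derived parameters
  expect_equal(back$truth$cosolute$nu, truth$cosolute$nu)
  expect_equal(back$truth$protein$epsilon, truth$protein$epsilon)
  expect_equal(back$truth$seed, truth$seed)
})

test_that("parameter objects serialize to JSON and back", {
  cs <- make_truth()$cosolute
  prot <- make_truth()$protein
  dir <- withr::local_tempdir()
  write_params_json(cs, file.path(dir, "cosolute.json"))
  write_params_json(prot, file.path(dir, "protein.json"))
  cs2 <- read_cosolute_params(file.path(dir, "cosolute.json"))
  prot2 <- read_protein_params(file.path(dir, "protein.json"))
  expect_equal(cs2, cs)
  expect_equal(prot2, prot)
  expect_identical(cs2$nu, cs2$Vbar_C / cs2$Vbar_S)
  # epsilon split identity at T0 is preserved through the round trip
  sp <- epsilon_split(prot2)
  expect_identical(sp$epsilon, sp$epsilon_H - sp$epsilon_TS)
  expect_equal(sp$epsilon, prot2$epsilon, tolerance = 1e-12)
})
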