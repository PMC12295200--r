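test_that("acid speciation solves the second dissociation correctly", {
  for (C in c(0.05, 0.4)) {
    s <- acid_speciation(C)
    conc <- s$concentrations
    ## sulfate mass balance and charge balance
    expect_equal(conc[["HSO4m"]] + conc[["SO4m2"]], C, tolerance = 1e-12)
    expect_equal(conc[["H3Op"]],
                 conc[["HSO4m"]] + 2 * conc[["SO4m2"]], tolerance = 1e-10)
    ## equilibrium constant recovered
    Ka <- conc[["H3Op"]] * conc[["SO4m2"]] / conc[["HSO4m"]]
    expect_equal(Ka, 10^(-1.99), tolerance = 1e-8)
  }
  ## 0.4 M reference values
  c4 <- acid_speciation(0.4)$concentrations
  expect_equal(c4[["H3Op"]], 0.4097, tolerance = 1e-3)
  expect_equal(c4[["HSO4m"]], 0.3903, tolerance = 1e-3)
  expect_equal(acid_speciation(0.4)$ionic_strength, 0.42, tolerance = 0.02)
})

test_that("FeSO4 contributes to the ionic strength", {
  a <- acid_speciation(0.4)
  b <- acid_speciation(0.4, fe2_molarity = 1e-3)
  expect_equal(b$ionic_strength - a$ionic_strength, 0.5 * 1e-3 * 8,
               tolerance = 1e-12)
})

test_that("ionic strength factor follows the Debye-Bronsted law", {
  I <- 0.423
  expect_equal(ionic_strength_factor(0, 1, I), 1)
  expect_equal(ionic_strength_factor(-1, 1, I),
               10^(-1.02 * sqrt(I) / (1 + sqrt(I))), tolerance = 1e-12)
  ## like charges accelerate, unlike decelerate
  expect_gt(ionic_strength_factor(1, 1, I), 1)
  expect_lt(ionic_strength_factor(-1, 2, I), 1)
  expect_equal(ionic_strength_factor(-1, -1, I, exempt = TRUE), 1)
  expect_error(ionic_strength_factor(1, 1, -0.1))
})

test_that("packaged reaction network is element- and charge-balanced", {
  ## loading runs the validator; reaching here means it passed
  cfg <- fricke_chemistry_config()
  expect_s3_class(cfg$species, "data.frame")
  expect_gte(nrow(cfg$reactions), 18)
  ## a corrupted network is rejected
  bad <- yaml::read_yaml(system.file("extdata", "fricke_chemistry.yaml",
                                     package = "frickesim"))
  bad$reactions[[1]]$products <- list("H2O2")
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, tf)
  expect_error(fricke_chemistry_config(tf), "unbalanced")
})

test_that("rate partition satisfies the Noyes relation", {
  sys <- build_fricke_system(0.4, 1e-3, 2.5e-4)
  rx <- sys$reactions
  partial <- rx$control != "fully"
  lhs <- 1 / rx$k_obs[partial]
  rhs <- 1 / rx$k_act[partial] + 1 / rx$k_diff[partial]
  expect_lt(max(abs(lhs - rhs) / lhs), 1e-12)
  expect_true(all(rx$k_obs > 0))
  ## at f = 1 the observed constants equal the corrected inputs
  expect_equal(rx$k_obs, rx$k_eff, tolerance = 1e-12)
  ## fully controlled radii reproduce k_eff through Smoluchowski
  fully <- rx$control == "fully"
  k_smol <- 4 * pi * rx$D_rel[fully] * rx$R_eff[fully] * 6.02214076e23 * 1000
  expect_equal(k_smol, rx$k_eff[fully], tolerance = 1e-12)
})

test_that("self-reactions carry a doubled pairwise partition", {
  sys <- build_fricke_system(0.4, 1e-3, 2.5e-4)
  rx <- sys$reactions
  self <- rx$r1 == rx$r2 & rx$control != "fully"
  expect_true(any(self))
  ## pairwise k_act recombines with k_diff to 2 k_eff
  k_pair <- 1 / (1 / rx$k_act_pair[self] + 1 / rx$k_diff[self])
  expect_equal(k_pair, 2 * rx$k_eff[self], tolerance = 1e-12)
  ## cross-reactions are untouched
  cross <- rx$r1 != rx$r2
  expect_identical(rx$k_act_pair[cross], rx$k_act[cross])
})

test_that("viscosity scaling composes and shifts the partition", {
  sys <- build_fricke_system(0.4, 1e-3, 2.5e-4)
  a <- apply_viscosity(apply_viscosity(sys, 2), 5)
  b <- apply_viscosity(sys, 10)
  expect_equal(a$species$D, b$species$D, tolerance = 1e-12)
  expect_equal(a$reactions$k_obs, b$reactions$k_obs, tolerance = 1e-12)
  ## D scales exactly as D0 / f for every species, including the iron ions
  expect_equal(b$species$D, sys$species$D0 / 10, tolerance = 1e-12)
  ## fully controlled: k_obs drops by exactly f
  fully <- sys$reactions$control == "fully"
  expect_equal(b$reactions$k_obs[fully], sys$reactions$k_obs[fully] / 10,
               tolerance = 1e-12)
  ## partially controlled: k_act fixed, k_obs decreases by less than f
  part <- !fully
  expect_identical(b$reactions$k_act[part], sys$reactions$k_act[part])
  expect_true(all(b$reactions$k_obs[part] < sys$reactions$k_obs[part]))
  expect_true(all(b$reactions$k_obs[part] >
                    sys$reactions$k_obs[part] / 10 - 1e-9))
  ## the diffusion-controlled fraction alpha rises with viscosity
  alpha0 <- sys$reactions$k_obs[part] / sys$reactions$k_diff[part]
  alpha1 <- b$reactions$k_obs[part] / b$reactions$k_diff[part]
  expect_true(all(alpha1 > alpha0 - 1e-15))
  expect_error(apply_viscosity(sys, 0.5))
})

test_that("ferric diffusion matches reported gel bands under scaling", {
  sys <- build_fricke_system()
  D0 <- sys$species["Fe3p", "D0"]
  expect_equal(D0, 2e-9, tolerance = 1e-12)
  ## gelatin: 2.2e-10..3.9e-10 m^2/s -> f in [5.1, 9.1]
  gel <- apply_viscosity(sys, 7)
  expect_gt(gel$species["Fe3p", "D"], 2.2e-10)
  expect_lt(gel$species["Fe3p", "D"], 3.9e-10)
  ## agarose: 3.6e-10..5.6e-10 -> f in [3.6, 5.6]
  aga <- apply_viscosity(sys, 4.5)
  expect_gt(aga$species["Fe3p", "D"], 3.6e-10)
  expect_lt(aga$species["Fe3p", "D"], 5.6e-10)
})

test_that("stoichiometric yield applies the oxidation weights", {
  e <- escape_yields(H = 3.70, H2 = 0.40, OH = 2.90, H2O2 = 0.80, HO2 = 0.02)
  expect_equal(stoichiometric_yield(e),
               2.90 + 3 * 3.70 + 2 * 0.80 + 3 * 0.02, tolerance = 1e-12)
  expect_warning(stoichiometric_yield(escape_yields(OH = 1)), "missing")
  expect_error(escape_yields(H = -1))
})

test_that("unit conversion to mol/J", {
  expect_equal(to_mol_per_joule(1), 1.0364e-7, tolerance = 1e-12)
  expect_error(to_mol_per_joule(-2))
})

test_that("system constructor validates inputs", {
  expect_error(build_fricke_system(0), "acid")
  expect_error(build_fricke_system(2), "acid")
  expect_error(build_fricke_system(0.4, -1), "non-negative")
})
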