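# Influent chemistry: formula parsing, molarities, theoretical COD, P/C.

test_that("molar masses match hand sums of standard atomic weights", {
  expect_equal(molar_mass("H2O"), 18.015, tolerance = 1e-4)
  expect_equal(molar_mass("NH4Cl"), 53.49, tolerance = 1e-3)
  # sodium acetate trihydrate, hydrate suffix
  expect_equal(molar_mass("NaC2H3O2.3H2O"), 136.08, tolerance = 1e-4)
  # parenthesised group with multiplier and fractional subscripts
  expect_equal(molar_mass("(PO3)3MgK"),
               3 * (30.974 + 3 * 15.999) + 24.305 + 39.098,
               tolerance = 1e-9)
  expect_equal(molar_mass("CH2.09O0.54N0.2P0.015"), 26.02, tolerance = 1e-2)
})

test_that("malformed formulas are rejected with the offending token named", {
  expect_error(count_atoms("Xx2"), "unknown element")
  expect_error(count_atoms("NaQ3"), "unknown element")
  expect_error(count_atoms("((PO3)3)2"), "nested")
  expect_error(count_atoms(""), "non-empty")
  expect_error(count_atoms("2H"), "malformed")
})

test_that("component molarities reproduce the medium characterization", {
  # 860 mg/L sodium acetate trihydrate carries 12.6 C-mmol/L
  expect_equal(component_cmolarity("NaC2H3O2.3H2O", 860), 12.6,
               tolerance = 0.005)
  expect_identical(component_cmolarity("NaC2H3O2.3H2O", 0), 0)
  # exactly 1 mmol/L of the salt carries 2 C-mmol/L
  expect_equal(component_cmolarity("NaC2H3O2.3H2O", molar_mass("NaC2H3O2.3H2O")),
               2, tolerance = 1e-12)
  # 107 mg/L NH4Cl carries 2 N-mmol/L
  expect_equal(nitrogen_mmolarity("NH4Cl", 107), 2.0, tolerance = 0.005)
  expect_identical(nitrogen_mmolarity("NH4Cl", 0), 0)
  expect_equal(nitrogen_mmolarity("NH4Cl", molar_mass("NH4Cl")), 1,
               tolerance = 1e-12)
})

test_that("theoretical COD follows the electron balance", {
  # 2 mol O2 per mol acetate: 1 mmol/L acetate = 64 mg COD/L
  expect_equal(theoretical_cod("NaC2H3O2.3H2O", molar_mass("NaC2H3O2.3H2O")),
               64, tolerance = 0.01)
  cod860 <- theoretical_cod("NaC2H3O2.3H2O", 860)
  expect_gt(cod860, 404)
  expect_lt(cod860, 405)
  expect_identical(theoretical_cod("NaC2H3O2.3H2O", 0), 0)
  expect_error(theoretical_cod("KCl", 48), "oxidation stoichiometry")
})

test_that("influent P/C ratios reproduce the phase schedule", {
  expect_equal(round(influent_pc_ratio(0.64, 12.6), 3), 0.051)
  expect_equal(round(influent_pc_ratio(1.44, 12.6), 3), 0.114)
  expect_identical(influent_pc_ratio(0, 12.6), 0)
  expect_error(influent_pc_ratio(0.64, 0), "> 0")
})

test_that("molarities and COD are exactly linear in component mass", {
  base <- characterize_influent(sbr_medium(), phosphate_pmmol = NULL)
  for (k in c(0.25, 2, 7.5)) {
    scaled_recipe <- dplyr::mutate(sbr_medium(),
                                   mass_mg_per_l = mass_mg_per_l * k)
    scaled <- characterize_influent(scaled_recipe)
    expect_equal(scaled$hac_cmmol, k * base$hac_cmmol, tolerance = 1e-12)
    expect_equal(scaled$cod_mg, k * base$cod_mg, tolerance = 1e-12)
    expect_equal(scaled$tp_pmmol, k * base$tp_pmmol, tolerance = 1e-12)
    expect_equal(scaled$tn_nmmol, k * base$tn_nmmol, tolerance = 1e-12)
    # P/C is scale-invariant
    expect_equal(scaled$pc_ratio, base$pc_ratio, tolerance = 1e-12)
  }
})

test_that("characterize_influent summarises the medium and applies overrides", {
  inf <- characterize_influent(sbr_medium(), phosphate_pmmol = 0.96)
  expect_equal(inf$hac_cmmol, 12.6, tolerance = 0.005)
  expect_equal(inf$tp_pmmol, 0.96, tolerance = 1e-9)
  expect_equal(inf$tn_nmmol, 2.0, tolerance = 0.005)
  expect_equal(round(inf$pc_ratio, 3), 0.076)
  # override replaces, not adds to, an existing phosphorus source
  inf2 <- characterize_influent(sbr_medium(0.64), phosphate_pmmol = 0.64)
  expect_equal(inf2$tp_pmmol, 0.64, tolerance = 1e-9)
  expect_error(characterize_influent(
    tibble::tibble(formula = "NH4Cl", mass_mg_per_l = -1)), ">= 0")
})
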