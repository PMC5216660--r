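# Poly-P estimation: ash route, mass-balance route, cross-validation.

test_that("phosphorus fraction of poly-P compositions is computed from mass", {
  expect_equal(round(polyp_phosphorus_fraction("(PO3)3MgK"), 2), 0.31)
  expect_equal(polyp_phosphorus_fraction("PO3"), 30.974 / 78.971,
               tolerance = 1e-6)
  expect_identical(polyp_phosphorus_fraction("P"), 1)
  expect_error(polyp_phosphorus_fraction("MgK"), "no phosphorus")
})

test_that("parameter object validates fractions and formula consistency", {
  expect_s3_class(polyp_params(), "polyp_params")
  expect_error(polyp_params(f_issb_tss = 0), "in \\(0, 1\\)")
  expect_error(polyp_params(f_p_ppiss = 1.2), "in \\(0, 1\\)")
  # P fraction of bare metaphosphate (0.39) is inconsistent with 0.31
  expect_error(polyp_params(polyp_formula = "PO3"), "inconsistent")
  expect_silent(polyp_params(f_p_ppiss = 0.39, polyp_formula = "PO3"))
})

test_that("ash-based estimate evaluates the excess-ash closed form", {
  # ash ratio exactly at the non-EBPR baseline: zero poly-P
  base <- polyp_from_solids(tibble::tibble(vss = 0.975, iss = 0.025))
  expect_equal(base$polyp_mg_p, 0, tolerance = 1e-9)
  expect_true(is.na(base$flag))
  # hand evaluation: (1.24 - 0.025/0.975 * 2.76) * 0.31 g P/L
  est <- polyp_from_solids(tibble::tibble(vss = 2.76, iss = 1.24))
  expect_equal(est$polyp_mg_p, 362, tolerance = 0.002)
  expect_equal(est$polyp_pmmol, est$polyp_mg_p / 30.974, tolerance = 1e-9)
  expect_identical(est$method, "ash_based")
  # depleted-biomass ash ratio 0.07 scaled to 1 g TSS: ~14.3 mg P/g TSS
  dep <- polyp_from_solids(tibble::tibble(vss = 0.93, iss = 0.07))
  expect_equal(dep$polyp_mg_p, 14.3, tolerance = 0.005)
  # below the baseline: clamped to zero and flagged
  low <- polyp_from_solids(tibble::tibble(vss = 0.99, iss = 0.01))
  expect_equal(low$polyp_mg_p, 0)
  expect_identical(low$flag, "below_baseline")
  expect_error(polyp_from_solids(tibble::tibble(vss = -1, iss = 0.1)), ">= 0")
  expect_error(polyp_from_solids(tibble::tibble(vss = 1, iss = 0.5, tss = 2)),
               "tss != vss \\+ iss")
})

test_that("ash-based estimate is monotone in ISS at fixed VSS", {
  iss <- seq(0.05, 2, length.out = 40)
  est <- polyp_from_solids(tibble::tibble(vss = 2.5, iss = iss))$polyp_mg_p
  expect_true(all(diff(est) >= 0))
})

test_that("mass-balance estimate evaluates the steady-state closed form", {
  # 8 d / 0.5 d * 0.64 P-mmol/L * 30.97 - 0.023 * 2000 = ~271 mg P/L
  est <- polyp_from_balance(tibble::tibble(tp_in = 0.64, tp_eff = 0,
                                           srt_d = 8, hrt_d = 0.5, vss = 2.0))
  expect_equal(est$polyp_mg_p, 271, tolerance = 0.002)
  expect_identical(est$method, "mass_balance")
  # no net P removal: the balance goes negative, is clamped and flagged
  none <- polyp_from_balance(tibble::tibble(tp_in = 0.5, tp_eff = 0.5,
                                            srt_d = 8, hrt_d = 0.5, vss = 2))
  expect_equal(none$polyp_mg_p, 0)
  expect_identical(none$flag, "balance_inconsistent")
  expect_error(polyp_from_balance(tibble::tibble(tp_in = 1, tp_eff = 0,
                                                 srt_d = 0.2, hrt_d = 0.5,
                                                 vss = 2)), "srt_d")
})

test_that("cross-validation reports discrepancy and candidate assumptions", {
  ok <- cross_validate_polyp(362, 362, rel_tol = 0.1)
  expect_identical(ok$status, "pass")
  expect_equal(ok$discrepancy, 0)
  bad <- cross_validate_polyp(362, 271, rel_tol = 0.1)
  expect_identical(bad$status, "fail")
  expect_equal(round(bad$discrepancy, 2), 0.29)
  expect_match(bad$notes, "precipitation")
  expect_identical(cross_validate_polyp(0, 0)$status, "indeterminate")
})

test_that("the two routes agree on a noiseless simulated steady state", {
  cfg <- sbr_config()
  traj <- simulate_phases(cfg, schedule = data.frame(phase = 2,
                                                     tp_pmmol = 0.96))
  st <- attr(traj, "final_states")[["2"]]
  cfg$influent_tp_pmmol <- 0.96
  out <- simulate_cycle(st, cfg, noise_model(0))
  ea <- out$end_aerobic
  e1 <- polyp_from_solids(tibble::tibble(vss = ea$vss_g_l, iss = ea$iss_g_l))
  e2 <- polyp_from_balance(tibble::tibble(tp_in = 0.96, tp_eff = ea$po4_pmmol,
                                          srt_d = cfg$srt_d,
                                          hrt_d = sbr_hrt(cfg) / 24,
                                          vss = ea$vss_g_l))
  expect_equal(e1$polyp_mg_p, e2$polyp_mg_p, tolerance = 0.01)
  # and both agree with the generating poly-P pool
  expect_equal(e1$polyp_mg_p, ea$polyp_pmmol * 30.974, tolerance = 0.005)
  expect_identical(cross_validate_polyp(e1$polyp_mg_p, e2$polyp_mg_p,
                                        rel_tol = 0.05)$status, "pass")
})
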