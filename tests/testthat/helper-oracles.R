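# Independent oracles and small profile builders used across the suite.

# Brute-force 1-D grid search for the mixing coefficient, independent of the
# closed-form solution in mixing_fit().
grid_lam_oracle <- function(observed, ends = end_members(), n = 10001L) {
  cols <- c("p_hac", "gly_hac", "phb_hac", "phv_hac")
  obs <- unlist(as.list(observed)[cols])
  pao <- unlist(ends$s_pao[cols])
  gao <- unlist(ends$s_gao[cols])
  grid <- seq(0, 1, length.out = n)
  pred <- outer(grid, pao) + outer(1 - grid, gao)   # n x 4 candidates
  sse <- rowSums((pred - matrix(obs, n, 4, byrow = TRUE))^2)
  grid[which.min(sse)]
}

# Noiseless piecewise-linear cycle profile: zero-order acetate decline from
# `hac0` to zero over `t_uptake_min`, P release at `p_slope_h` during uptake
# and `m_slope_h` afterwards, sampled every `dt_min` until `t_end_min`.
linear_profile <- function(hac0 = 6.3, po4_0 = 0.64, t_uptake_min = 30,
                           p_slope_h = 0, m_slope_h = 0, t_end_min = 120,
                           dt_min = 5) {
  t <- seq(0, t_end_min, by = dt_min)
  uptake_rate_h <- hac0 / (t_uptake_min / 60)
  hac <- pmax(hac0 - uptake_rate_h * t / 60, 0)
  po4 <- ifelse(
    t <= t_uptake_min,
    po4_0 + p_slope_h * t / 60,
    po4_0 + p_slope_h * t_uptake_min / 60 +
      m_slope_h * (t - t_uptake_min) / 60
  )
  tibble::tibble(t_min = t, phase = "anaerobic", po4 = po4, hac = hac)
}

# Polymer panels consistent with a target stoichiometry for a given acetate
# consumption (C-mmol/L), via the monomer C-mol masses.
panels_for_stoich <- function(dhac, gly_hac, phb_hac, phv_hac,
                              gly0_mg = 600, phb0_mg = 20, phv0_mg = 10) {
  begin <- tibble::tibble(gly_mg_l = gly0_mg, phb_mg_l = phb0_mg,
                          phv_mg_l = phv0_mg)
  end <- tibble::tibble(
    gly_mg_l = gly0_mg - gly_hac * dhac * monomer_cmol_mass("glycogen"),
    phb_mg_l = phb0_mg + phb_hac * dhac * monomer_cmol_mass("phb"),
    phv_mg_l = phv0_mg + phv_hac * dhac * monomer_cmol_mass("phv")
  )
  list(begin = begin, end = end)
}
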