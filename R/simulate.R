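# Synthetic SBR generator: per-cycle anaerobic/aerobic dynamics and
# multi-phase long-term trajectories with exact internal mass balances, so
# every estimator in the package can be validated by parameter recovery.
#
# Anaerobic chemistry is mechanistic (zero-order acetate uptake with a
# state-dependent stoichiometry from the mixing model, then endogenous P
# release); the aerobic phase is a balance closure (glycogen replenishment
# from PHA, growth on the remainder, P uptake to poly-P, SRT wastage), which
# is sufficient because only the anaerobic analysis is in scope.

#' SBR operating configuration for the synthetic generator
#'
#' Defaults reproduce the enrichment reactor: 2.5 L working volume, 1.25 L
#' exchange volume, 6-h cycles (2.25 h anaerobic including 5 min N2 sparge
#' and 5 min feed, 2.25 h aerobic, 1.5 h settling), SRT 8 d. The hydraulic
#' retention time is never set: it emerges from the geometry via [sbr_hrt()]
#' (12 h for the defaults).
#'
#' @param working_volume_l,exchange_volume_l Reactor geometry, L.
#' @param cycle_h,anaerobic_h,aerobic_h,settle_h Cycle phase durations, h
#'   (must sum to `cycle_h`).
#' @param sparge_min,feed_min N2 sparge and feed durations at the start of
#'   the anaerobic phase; profile time zero is the end of feed.
#' @param srt_d Solids retention time, d.
#' @param medium Influent recipe, see [sbr_medium()]; sets the acetate load.
#' @param influent_tp_pmmol Influent orthophosphate, P-mmol/L.
#' @param qsa_max True maximum acetate-uptake rate, C-mmol/(C-mol active
#'   biomass h).
#' @param m_p True endogenous P-release rate, P-mmol/(C-mol h).
#' @param polyp_max Poly-P storage capacity, P-mol per C-mol active biomass.
#' @param gly_x_hi,gly_x_slope End-of-cycle glycogen target per active
#'   biomass, `gly_x_hi - gly_x_slope * lam` C-mol/C-mol: cells compensate a
#'   poly-P-poor phenotype with more glycogen.
#' @param y_growth Aerobic biomass yield on the PHA carbon left after
#'   glycogen replenishment, C-mol/C-mol (rest is oxidized to CO2).
#' @param lam_r50 Poly-P/glycogen ratio (P-mol/C-mol) at which the metabolic
#'   mix is halfway between the end members; 0.3 is the optimum ratio of the
#'   reference culture.
#' @param monod_ks Half-saturation constant for acetate uptake, C-mmol/L;
#'   0 (default) gives the zero-order kinetics seen in cycle tests.
#' @param sample_dt_min Sampling interval of emitted profiles, min.
#' @param params A [polyp_params()] (ash baseline used to reconstruct ISS).
#' @param ends An [end_members()] pair defining the stoichiometry at
#'   `lam = 0` and `lam = 1`.
#' @return A list of class `sbr_config`.
#' @export
sbr_config <- function(working_volume_l = 2.5, exchange_volume_l = 1.25,
                       cycle_h = 6, anaerobic_h = 2.25, aerobic_h = 2.25,
                       settle_h = 1.5, sparge_min = 5, feed_min = 5,
                       srt_d = 8, medium = sbr_medium(),
                       influent_tp_pmmol = 0.64,
                       qsa_max = 198, m_p = 2, polyp_max = 0.35,
                       gly_x_hi = 0.55, gly_x_slope = 0.30, y_growth = 0.70,
                       lam_r50 = 0.30, monod_ks = 0, sample_dt_min = 5,
                       params = polyp_params(), ends = end_members()) {
  stopifnot(working_volume_l > 0, exchange_volume_l > 0,
            exchange_volume_l <= working_volume_l,
            anaerobic_h > (sparge_min + feed_min) / 60, aerobic_h > 0,
            settle_h >= 0, srt_d > 0, qsa_max >= 0, m_p >= 0,
            polyp_max > 0, gly_x_hi > 0, gly_x_slope >= 0,
            y_growth > 0, y_growth <= 1, lam_r50 > 0, monod_ks >= 0,
            sample_dt_min > 0, influent_tp_pmmol >= 0)
  if (abs(cycle_h - (anaerobic_h + aerobic_h + settle_h)) > 1e-9) {
    stop("phase durations must sum to the cycle length", call. = FALSE)
  }
  influent <- characterize_influent(medium,
                                    phosphate_pmmol = influent_tp_pmmol)
  cfg <- structure(list(
    working_volume_l = working_volume_l, exchange_volume_l = exchange_volume_l,
    cycle_h = cycle_h, anaerobic_h = anaerobic_h, aerobic_h = aerobic_h,
    settle_h = settle_h, sparge_min = sparge_min, feed_min = feed_min,
    srt_d = srt_d, medium = medium,
    influent_hac_cmmol = influent$hac_cmmol,
    influent_tp_pmmol = influent_tp_pmmol,
    qsa_max = qsa_max, m_p = m_p, polyp_max = polyp_max,
    gly_x_hi = gly_x_hi, gly_x_slope = gly_x_slope, y_growth = y_growth,
    lam_r50 = lam_r50, monod_ks = monod_ks, sample_dt_min = sample_dt_min,
    params = params, ends = ends
  ), class = "sbr_config")
  if (srt_d < sbr_hrt(cfg) / 24) {
    stop("SRT must be >= HRT", call. = FALSE)
  }
  cfg
}

#' Hydraulic retention time implied by the reactor geometry
#'
#' `HRT = cycle length x working volume / exchange volume`; a 2.5 L reactor
#' exchanging 1.25 L every 6-h cycle has an HRT of 12 h.
#'
#' @param config An [sbr_config()].
#' @return HRT in hours.
#' @export
sbr_hrt <- function(config) {
  config$cycle_h * config$working_volume_l / config$exchange_volume_l
}

#' Measurement-noise model
#'
#' Multiplicative Gaussian noise truncated at zero, with a relative standard
#' deviation per analyte class. Applied only to emitted measurements; the
#' simulator's true state stays exact.
#'
#' @param rsd Default relative standard deviation for all analytes.
#' @param po4,hac,solids,polymers Per-analyte overrides.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(rsd = 0.02, po4 = rsd, hac = rsd, solids = rsd,
                        polymers = rsd) {
  vals <- c(po4 = po4, hac = hac, solids = solids, polymers = polymers)
  stopifnot(all(vals >= 0))
  structure(as.list(vals), class = "noise_model")
}

.apply_noise <- function(x, rsd) {
  if (rsd <= 0) return(x)
  pmax(0, x * (1 + stats::rnorm(length(x), 0, rsd)))
}

#' Initial true state of the simulated culture
#'
#' @param config An [sbr_config()].
#' @param x_cmmol Active biomass, C-mmol/L.
#' @param polyp_per_x,gly_per_x Initial storage contents per active biomass
#'   (P-mol/C-mol and C-mol/C-mol).
#' @return A list of class `sbr_state` with pools in mmol/L of working
#'   volume: `x_cmmol`, `polyp_pmmol`, `gly_cmmol`, `phb_cmmol`,
#'   `phv_cmmol`, `orgp_pmmol` (organically bound biomass P), `po4_pmmol`,
#'   `hac_cmmol`.
#' @export
initial_state <- function(config = sbr_config(), x_cmmol = 50,
                          polyp_per_x = 0.10, gly_per_x = 0.45) {
  stopifnot(x_cmmol > 0, polyp_per_x >= 0, gly_per_x >= 0)
  st <- list(x_cmmol = x_cmmol, polyp_pmmol = polyp_per_x * x_cmmol,
             gly_cmmol = gly_per_x * x_cmmol, phb_cmmol = 0, phv_cmmol = 0,
             orgp_pmmol = 0, po4_pmmol = 0, hac_cmmol = 0)
  st$orgp_pmmol <- .orgp_target(st, config)
  structure(st, class = "sbr_state")
}


# Cached monomer C-mol masses (formula parsing is not free and sits on the
# simulator hot path).
.mono_env <- new.env(parent = emptyenv())
.cmass <- function(key) {
  v <- get0(key, envir = .mono_env, inherits = FALSE)
  if (is.null(v)) {
    v <- monomer_cmol_mass(key)
    assign(key, v, envir = .mono_env)
  }
  v
}

# Plain-list convex combination of the end members (fast path used inside
# the cycle loop; predict_stoichiometry() is the user-facing equivalent).
.mix_stoich <- function(lam, ends) {
  p <- ends$s_pao; g <- ends$s_gao
  list(p_hac = lam * p$p_hac + (1 - lam) * g$p_hac,
       gly_hac = lam * p$gly_hac + (1 - lam) * g$gly_hac,
       phb_hac = lam * p$phb_hac + (1 - lam) * g$phb_hac,
       phv_hac = lam * p$phv_hac + (1 - lam) * g$phv_hac)
}

.state_vss_g <- function(state) {
  (state$x_cmmol * .cmass("active_biomass") +
     state$gly_cmmol * .cmass("glycogen") +
     state$phb_cmmol * .cmass("phb") +
     state$phv_cmmol * .cmass("phv")) / 1000
}

# ISS is baseline biomass ash plus poly-P ash (the inverse of the ash-based
# poly-P estimator, so that estimator is exact on noiseless panels).
.state_iss_g <- function(state, params) {
  f <- params$f_issb_tss
  polyp_mg <- state$polyp_pmmol * .p_molar_mass()
  f / (1 - f) * .state_vss_g(state) + polyp_mg / params$f_p_ppiss / 1000
}

.orgp_target <- function(state, config) {
  config$params$f_p_bvss * .state_vss_g(state) * 1000 / .p_molar_mass()
}

.lam_from_state <- function(state, config) {
  if (state$gly_cmmol <= 0) return(1)
  r <- state$polyp_pmmol / state$gly_cmmol
  r / (r + config$lam_r50)
}

.solids_panel <- function(state, config, noise) {
  vss <- .apply_noise(.state_vss_g(state), noise$solids)
  iss <- .apply_noise(.state_iss_g(state, config$params), noise$solids)
  tibble::tibble(vss_g_l = vss, iss_g_l = iss, tss_g_l = vss + iss)
}

.polymer_panel <- function(state, noise) {
  tibble::tibble(
    gly_mg_l = .apply_noise(state$gly_cmmol * .cmass("glycogen"),
                            noise$polymers),
    phb_mg_l = .apply_noise(state$phb_cmmol * .cmass("phb"),
                            noise$polymers),
    phv_mg_l = .apply_noise(state$phv_cmmol * .cmass("phv"),
                            noise$polymers)
  )
}

# Piecewise-linear evaluation of a concentration trace built from segments
# (t0_h, t1_h, c0, slope_per_h).
.eval_segments <- function(segments, t_h, final_value) {
  vapply(t_h, function(tt) {
    for (s in segments) {
      if (tt <= s$t1 + 1e-12 && tt >= s$t0 - 1e-12) {
        return(s$c0 + s$slope * (tt - s$t0))
      }
    }
    final_value
  }, numeric(1))
}

#' Simulate one SBR cycle
#'
#' Feeds the reactor, runs the anaerobic phase mechanistically (zero-order
#' acetate uptake at the state's true rate with the stoichiometry of the
#' state's metabolic mix, then endogenous P release after exhaustion),
#' closes the aerobic phase by mass balance (glycogen replenishment from
#' PHA, growth, P uptake into poly-P up to capacity) and applies SRT
#' wastage. If the poly-P pool runs out mid-uptake the stoichiometry
#' gracefully re-evaluates at `lam = 0` (the depleted, glycogen-only
#' phenotype). Measurement noise perturbs only the emitted profile and
#' panels; the returned state is exact.
#'
#' @param state An [initial_state()] (or the `state` of a previous cycle).
#' @param config An [sbr_config()].
#' @param noise A [noise_model()].
#' @param emit_profile If `FALSE`, skip building the sampled profile
#'   (faster for long trajectories).
#' @return A list: `profile` (tibble `t_min`, `phase`, `po4`, `hac`),
#'   `panel_begin`/`panel_end` (anaerobic begin/end polymer + solids
#'   panels; `NULL` when `emit_profile = FALSE`), `end_aerobic`
#'   (pre-wastage end-of-aerobic state summary, named list), `state`
#'   (post-wastage, start of next cycle), `truth` (the generating lam,
#'   stoichiometry, rates, active biomass), `books` (named vector of P/C
#'   amounts moved this cycle, mmol), `flags`.
#' @export
simulate_cycle <- function(state, config = sbr_config(),
                           noise = noise_model(0), emit_profile = TRUE) {
  stopifnot(inherits(config, "sbr_config"))
  if (state$x_cmmol < 1e-6) {
    stop("washout: active biomass has collapsed to zero", call. = FALSE)
  }
  vw <- config$working_volume_l
  vex <- config$exchange_volume_l
  fr <- vex / vw
  flags <- character(0)

  books <- c(
    p_in = config$influent_tp_pmmol * vex,
    p_eff = state$po4_pmmol * vex,
    c_in = config$influent_hac_cmmol * vex,
    c_eff = state$hac_cmmol * vex,
    p_wasted = 0, c_wasted = 0, co2 = 0
  )

  # Decant + feed: soluble species dilute, particulates are retained.
  st <- state
  st$po4_pmmol <- state$po4_pmmol * (1 - fr) + config$influent_tp_pmmol * fr
  st$hac_cmmol <- state$hac_cmmol * (1 - fr) + config$influent_hac_cmmol * fr

  lam <- .lam_from_state(st, config)
  stoich <- .mix_stoich(lam, config$ends)
  truth <- list(
    lam = lam,
    stoich = stoich[c("p_hac", "gly_hac", "phb_hac", "phv_hac")],
    qsa = config$qsa_max,
    qp = config$qsa_max * stoich$p_hac,
    m_p = config$m_p,
    x_cmol = st$x_cmmol / 1000,
    vss_g = .state_vss_g(st)
  )

  panel_begin <- if (emit_profile) {
    dplyr::bind_cols(.polymer_panel(st, noise),
                     .solids_panel(st, config, noise))
  }

  t_ana_h <- config$anaerobic_h - (config$sparge_min + config$feed_min) / 60
  ana <- if (config$monod_ks > 0) {
    .run_anaerobic_monod(st, config, t_ana_h)
  } else {
    .run_anaerobic(st, config, t_ana_h)
  }
  st <- ana$state
  flags <- c(flags, ana$flags)
  books[["co2"]] <- books[["co2"]] + ana$co2 * vw

  panel_end <- if (emit_profile) {
    dplyr::bind_cols(.polymer_panel(st, noise),
                     .solids_panel(st, config, noise))
  }
  po4_end_ana <- st$po4_pmmol
  hac_end_ana <- st$hac_cmmol

  # ---- aerobic balance closure ----
  if (st$hac_cmmol > 0) {          # leftover substrate oxidized aerobically
    books[["co2"]] <- books[["co2"]] + st$hac_cmmol * vw
    if (st$hac_cmmol > 1e-9) flags <- c(flags, "acetate_carryover")
    st$hac_cmmol <- 0
  }
  pha <- st$phb_cmmol + st$phv_cmmol
  gly_target <- (config$gly_x_hi - config$gly_x_slope * lam) * st$x_cmmol
  gly_formed <- min(max(gly_target - st$gly_cmmol, 0), pha)
  remainder <- pha - gly_formed
  growth <- config$y_growth * remainder
  books[["co2"]] <- books[["co2"]] + (1 - config$y_growth) * remainder * vw
  st$gly_cmmol <- st$gly_cmmol + gly_formed
  st$x_cmmol <- st$x_cmmol + growth
  st$phb_cmmol <- 0
  st$phv_cmmol <- 0

  d_org <- .orgp_target(st, config) - st$orgp_pmmol
  if (d_org > st$po4_pmmol) {
    d_org <- st$po4_pmmol
    flags <- c(flags, "p_limited_growth")
  }
  st$orgp_pmmol <- st$orgp_pmmol + d_org
  st$po4_pmmol <- st$po4_pmmol - d_org

  capacity <- max(config$polyp_max * st$x_cmmol - st$polyp_pmmol, 0)
  uptake_p <- min(capacity, st$po4_pmmol)
  if (st$po4_pmmol - uptake_p > 1e-9) flags <- c(flags, "polyp_saturated")
  st$polyp_pmmol <- st$polyp_pmmol + uptake_p
  st$po4_pmmol <- st$po4_pmmol - uptake_p

  vss_ea <- .state_vss_g(st)
  iss_ea <- .state_iss_g(st, config$params)
  end_aerobic <- list(
    x_cmmol = st$x_cmmol, polyp_pmmol = st$polyp_pmmol,
    gly_cmmol = st$gly_cmmol, orgp_pmmol = st$orgp_pmmol,
    po4_pmmol = st$po4_pmmol,
    vss_g_l = vss_ea, iss_g_l = iss_ea, tss_g_l = vss_ea + iss_ea
  )

  # ---- SRT wastage (mixed-liquor wastage before settling) ----
  w <- config$cycle_h / (config$srt_d * 24)
  books[["p_wasted"]] <- w * (st$polyp_pmmol + st$orgp_pmmol) * vw
  books[["c_wasted"]] <- w * (st$x_cmmol + st$gly_cmmol) * vw
  for (pool in c("x_cmmol", "polyp_pmmol", "gly_cmmol", "phb_cmmol",
                 "phv_cmmol", "orgp_pmmol")) {
    st[[pool]] <- st[[pool]] * (1 - w)
  }

  profile <- NULL
  if (emit_profile) {
    t_grid <- unique(c(seq(0, t_ana_h * 60, by = config$sample_dt_min),
                       t_ana_h * 60))
    po4_ana <- .eval_segments(ana$po4_segments, t_grid / 60, po4_end_ana)
    hac_ana <- .eval_segments(ana$hac_segments, t_grid / 60, hac_end_ana)
    t_aer <- seq(config$sample_dt_min, config$aerobic_h * 60,
                 by = config$sample_dt_min)
    frac <- t_aer / (config$aerobic_h * 60)
    po4_aer <- po4_end_ana + frac * (st$po4_pmmol - po4_end_ana)
    hac_aer <- hac_end_ana * (1 - frac)
    profile <- tibble::tibble(
      t_min = c(t_grid, t_ana_h * 60 + t_aer),
      phase = rep(c("anaerobic", "aerobic"), c(length(t_grid), length(t_aer))),
      po4 = .apply_noise(c(po4_ana, po4_aer), noise$po4),
      hac = .apply_noise(c(hac_ana, hac_aer), noise$hac)
    )
  }

  list(profile = profile, panel_begin = panel_begin, panel_end = panel_end,
       end_aerobic = end_aerobic, state = structure(st, class = "sbr_state"),
       truth = truth, books = books, flags = unique(flags))
}

# Zero-order anaerobic phase as an event loop: uptake segments can be cut
# short by acetate exhaustion, poly-P depletion (stoichiometry re-evaluated
# at lam = 0) or glycogen depletion (uptake stalls); afterwards endogenous P
# release runs until the pool or the clock runs out.
.run_anaerobic <- function(st, config, t_ana_h) {
  flags <- character(0)
  co2 <- 0
  po4_seg <- list()
  hac_seg <- list()
  t <- 0
  stoich <- .mix_stoich(.lam_from_state(st, config), config$ends)
  guard <- 0
  while (t < t_ana_h - 1e-12 && st$hac_cmmol > 1e-12) {
    guard <- guard + 1
    if (guard > 10) break
    v <- config$qsa_max * st$x_cmmol / 1000     # C-mmol/(L h)
    if (v <= 0) break
    caps <- c(hac = st$hac_cmmol, time = v * (t_ana_h - t))
    if (stoich$p_hac > 0) caps["polyp"] <- st$polyp_pmmol / stoich$p_hac
    if (stoich$gly_hac > 0) caps["gly"] <- st$gly_cmmol / stoich$gly_hac
    u <- max(min(caps), 0)
    limiting <- names(caps)[which.min(caps)]
    if (u > 0) {
      dt <- u / v
      po4_seg[[length(po4_seg) + 1]] <-
        list(t0 = t, t1 = t + dt, c0 = st$po4_pmmol,
             slope = stoich$p_hac * v)
      hac_seg[[length(hac_seg) + 1]] <-
        list(t0 = t, t1 = t + dt, c0 = st$hac_cmmol, slope = -v)
      st$hac_cmmol <- st$hac_cmmol - u
      st$po4_pmmol <- st$po4_pmmol + stoich$p_hac * u
      st$polyp_pmmol <- max(st$polyp_pmmol - stoich$p_hac * u, 0)
      st$gly_cmmol <- max(st$gly_cmmol - stoich$gly_hac * u, 0)
      st$phb_cmmol <- st$phb_cmmol + stoich$phb_hac * u
      st$phv_cmmol <- st$phv_cmmol + stoich$phv_hac * u
      co2 <- co2 + (1 + stoich$gly_hac - stoich$phb_hac - stoich$phv_hac) * u
      t <- t + dt
    }
    if (st$hac_cmmol <= 1e-12 || t >= t_ana_h - 1e-12) break
    if (limiting == "polyp") {
      flags <- c(flags, "polyp_depleted")
      stoich <- .mix_stoich(0, config$ends)
      if (st$polyp_pmmol < stoich$p_hac * st$hac_cmmol) {
        stoich$p_hac <- 0          # pool empty: release cannot continue
      }
    } else if (limiting == "gly") {
      flags <- c(flags, "gly_depleted")
      break                        # no reducing power: uptake stalls
    } else if (u <= 0) {
      break
    }
  }

  # endogenous (maintenance) P release in the substrate-free window
  if (t < t_ana_h - 1e-12 && config$m_p > 0 && st$hac_cmmol <= 1e-12) {
    rate <- config$m_p * st$x_cmmol / 1000      # P-mmol/(L h)
    dur <- t_ana_h - t
    rel_cap <- st$polyp_pmmol
    t_run <- if (rate > 0) min(dur, rel_cap / rate) else 0
    if (t_run > 0) {
      po4_seg[[length(po4_seg) + 1]] <-
        list(t0 = t, t1 = t + t_run, c0 = st$po4_pmmol, slope = rate)
      hac_seg[[length(hac_seg) + 1]] <-
        list(t0 = t, t1 = t_ana_h, c0 = 0, slope = 0)
      st$po4_pmmol <- st$po4_pmmol + rate * t_run
      st$polyp_pmmol <- st$polyp_pmmol - rate * t_run
      t <- t + t_run
      if (t < t_ana_h - 1e-12) flags <- c(flags, "polyp_depleted")
    }
  }

  list(state = st, flags = flags, co2 = co2, po4_segments = po4_seg,
       hac_segments = hac_seg)
}

# Monod-limited variant (optional, off by default): forward-Euler
# integration at fine resolution, same stoichiometric bookkeeping.
.run_anaerobic_monod <- function(st, config, t_ana_h) {
  flags <- character(0)
  co2 <- 0
  dt <- 0.1 / 60                    # 0.1 min
  stoich <- .mix_stoich(.lam_from_state(st, config), config$ends)
  n <- ceiling(t_ana_h / dt)
  po4_seg <- list()
  hac_seg <- list()
  t <- 0
  for (i in seq_len(n)) {
    s <- st$hac_cmmol
    if (s <= 1e-9) break
    v <- config$qsa_max * st$x_cmmol / 1000 * s / (config$monod_ks + s)
    u <- min(v * dt, s, if (stoich$p_hac > 0) st$polyp_pmmol / stoich$p_hac
             else Inf,
             if (stoich$gly_hac > 0) st$gly_cmmol / stoich$gly_hac else Inf)
    po4_seg[[length(po4_seg) + 1]] <-
      list(t0 = t, t1 = t + dt, c0 = st$po4_pmmol,
           slope = stoich$p_hac * u / dt)
    hac_seg[[length(hac_seg) + 1]] <-
      list(t0 = t, t1 = t + dt, c0 = st$hac_cmmol, slope = -u / dt)
    st$hac_cmmol <- st$hac_cmmol - u
    st$po4_pmmol <- st$po4_pmmol + stoich$p_hac * u
    st$polyp_pmmol <- max(st$polyp_pmmol - stoich$p_hac * u, 0)
    st$gly_cmmol <- max(st$gly_cmmol - stoich$gly_hac * u, 0)
    st$phb_cmmol <- st$phb_cmmol + stoich$phb_hac * u
    st$phv_cmmol <- st$phv_cmmol + stoich$phv_hac * u
    co2 <- co2 + (1 + stoich$gly_hac - stoich$phb_hac - stoich$phv_hac) * u
    t <- t + dt
    if (st$polyp_pmmol <= 1e-12 && stoich$p_hac > 0) {
      flags <- c(flags, "polyp_depleted")
      stoich <- .mix_stoich(0, config$ends)
      stoich$p_hac <- 0
    }
  }
  if (t < t_ana_h && config$m_p > 0 && st$hac_cmmol <= 1e-9) {
    rate <- config$m_p * st$x_cmmol / 1000
    t_run <- min(t_ana_h - t, if (rate > 0) st$polyp_pmmol / rate else 0)
    if (t_run > 0) {
      po4_seg[[length(po4_seg) + 1]] <-
        list(t0 = t, t1 = t + t_run, c0 = st$po4_pmmol, slope = rate)
      st$po4_pmmol <- st$po4_pmmol + rate * t_run
      st$polyp_pmmol <- st$polyp_pmmol - rate * t_run
    }
  }
  list(state = st, flags = unique(flags), co2 = co2,
       po4_segments = po4_seg, hac_segments = hac_seg)
}

#' Simulate the reactor through an influent phase schedule
#'
#' Runs noiseless cycles phase by phase until the end-of-cycle pools
#' stabilise (relative change below `tol` per cycle), mirroring long-term
#' operation under a stepwise influent P/C schedule. Per-cycle end-of-aerobic
#' observations (pre-wastage, i.e. what a solids panel would measure) are
#' recorded.
#'
#' @param config An [sbr_config()].
#' @param schedule A data frame with columns `phase` and `tp_pmmol`
#'   (default [influent_phases()]).
#' @param state Optional starting state (default [initial_state()]).
#' @param tol Convergence tolerance on the relative pool change per cycle.
#' @param max_cycles Per-phase cycle cap.
#' @return A tibble of class `sbr_trajectory` (one row per cycle) with the
#'   end-of-aerobic state, solids and derived ratios, plus attributes:
#'   `final_states` (list of end-of-phase states), `truths` (generating
#'   parameters at the end of each phase), `balance` (whole-run P and C
#'   ledgers), `config`.
#' @export
simulate_phases <- function(config = sbr_config(),
                            schedule = influent_phases(),
                            state = initial_state(config), tol = 1e-8,
                            max_cycles = 3000) {
  stopifnot(is.data.frame(schedule),
            all(c("phase", "tp_pmmol") %in% names(schedule)))
  noise0 <- noise_model(0)
  vw <- config$working_volume_l
  p_total <- function(s) (s$po4_pmmol + s$polyp_pmmol + s$orgp_pmmol) * vw
  c_total <- function(s) (s$hac_cmmol + s$x_cmmol + s$gly_cmmol +
                            s$phb_cmmol + s$phv_cmmol) * vw
  ledger <- c(p_in = 0, p_eff = 0, p_wasted = 0, c_in = 0, c_eff = 0,
              c_wasted = 0, co2 = 0)
  p_initial <- p_total(state)
  c_initial <- c_total(state)

  rows <- list()
  final_states <- list()
  truths <- list()
  cycle_global <- 0L

  for (i in seq_len(nrow(schedule))) {
    cfg <- config
    cfg$influent_tp_pmmol <- schedule$tp_pmmol[i]
    converged <- FALSE
    for (j in seq_len(max_cycles)) {
      pools_before <- unlist(state[c("x_cmmol", "polyp_pmmol", "gly_cmmol")])
      out <- simulate_cycle(state, cfg, noise0, emit_profile = FALSE)
      state <- out$state
      cycle_global <- cycle_global + 1L
      ledger <- ledger + out$books[names(ledger)]

      ea <- out$end_aerobic
      rows[[cycle_global]] <- c(
        phase = schedule$phase[i], cycle = cycle_global, cycle_in_phase = j,
        tp_in = schedule$tp_pmmol[i],
        pc_in = schedule$tp_pmmol[i] / cfg$influent_hac_cmmol,
        lam = out$truth$lam,
        x_cmmol = ea$x_cmmol, polyp_pmmol = ea$polyp_pmmol,
        gly_cmmol = ea$gly_cmmol,
        vss_g_l = ea$vss_g_l, iss_g_l = ea$iss_g_l, tss_g_l = ea$tss_g_l,
        iss_tss = ea$iss_g_l / ea$tss_g_l,
        po4_eff = ea$po4_pmmol
      )

      pools_after <- unlist(state[c("x_cmmol", "polyp_pmmol", "gly_cmmol")])
      rel <- max(abs(pools_after - pools_before) /
                   pmax(pools_after, .Machine$double.eps))
      if (rel < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      warning("phase ", schedule$phase[i], " did not reach steady state in ",
              max_cycles, " cycles", call. = FALSE)
    }
    final_states[[as.character(schedule$phase[i])]] <- state
    truths[[as.character(schedule$phase[i])]] <- out$truth
  }

  traj <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  structure(
    traj,
    final_states = final_states,
    truths = truths,
    balance = tibble::tibble(
      p_in = ledger[["p_in"]], p_eff = ledger[["p_eff"]],
      p_wasted = ledger[["p_wasted"]], p_initial = p_initial,
      p_final = p_total(state),
      c_in = ledger[["c_in"]], c_eff = ledger[["c_eff"]],
      c_wasted = ledger[["c_wasted"]], co2 = ledger[["co2"]],
      c_initial = c_initial, c_final = c_total(state)
    ),
    config = config,
    class = c("sbr_trajectory", class(traj))
  )
}

#' Per-phase steady-state summary of a simulated trajectory
#'
#' @param trajectory An object from [simulate_phases()].
#' @return A tibble with the last cycle of each phase plus the generating
#'   metabolic mix and storage ratios.
#' @export
steady_states <- function(trajectory) {
  stopifnot(inherits(trajectory, "sbr_trajectory"))
  traj <- tibble::as_tibble(trajectory)
  last <- dplyr::slice_tail(dplyr::group_by(traj, .data$phase), n = 1)
  last <- dplyr::ungroup(last)
  dplyr::bind_cols(
    last,
    storage_ratios(last$x_cmmol, last$polyp_pmmol, last$gly_cmmol)
  )
}

#' Write a deterministic synthetic fixture bundle
#'
#' Simulates the full phase schedule to steady state, then emits one noisy
#' cycle test per phase: a cycle-profile CSV, a panels CSV (begin/end
#' anaerobic), a phase-summary CSV and a YAML description of the
#' configuration. Identical seeds produce identical bytes.
#'
#' @param seed Integer seed for the measurement noise.
#' @param out_dir Output directory (created if needed).
#' @param config An [sbr_config()].
#' @param noise A [noise_model()] for the emitted measurements.
#' @param schedule Phase schedule, see [simulate_phases()].
#' @return Invisibly, the character vector of files written.
#' @export
make_fixtures <- function(seed, out_dir, config = sbr_config(),
                          noise = noise_model(0.02),
                          schedule = influent_phases()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traj <- simulate_phases(config, schedule)
  states <- attr(traj, "final_states")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  files <- character(0)
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  panels <- list()
  for (i in seq_len(nrow(schedule))) {
    ph <- as.character(schedule$phase[i])
    cfg <- config
    cfg$influent_tp_pmmol <- schedule$tp_pmmol[i]
    out <- simulate_cycle(states[[ph]], cfg, noise)
    wcsv(out$profile, sprintf("cycle_phase%s.csv", ph))
    panels[[length(panels) + 1]] <- dplyr::bind_rows(
      dplyr::mutate(out$panel_begin, phase = schedule$phase[i],
                    panel = "begin_anaerobic"),
      dplyr::mutate(out$panel_end, phase = schedule$phase[i],
                    panel = "end_anaerobic")
    )
  }
  wcsv(dplyr::bind_rows(panels), "panels.csv")
  wcsv(steady_states(traj), "steady_states.csv")

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(list(
    working_volume_l = config$working_volume_l,
    exchange_volume_l = config$exchange_volume_l,
    cycle_h = config$cycle_h, anaerobic_h = config$anaerobic_h,
    aerobic_h = config$aerobic_h, settle_h = config$settle_h,
    srt_d = config$srt_d, hrt_h = sbr_hrt(config),
    qsa_max = config$qsa_max, m_p = config$m_p,
    influent_hac_cmmol = config$influent_hac_cmmol,
    schedule = as.list(stats::setNames(schedule$tp_pmmol,
                                       paste0("phase", schedule$phase))),
    seed = as.integer(seed)
  ), cfg_path)
  files <- c(files, cfg_path)
  invisible(files)
}
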