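# Anaerobic cycle-test analysis: maximum acetate-uptake and P-release rates,
# endogenous (maintenance) P release, and the stoichiometric ratios of the
# anaerobic conversions HAc + poly-P + glycogen -> PHB/PHV + CO2 + ortho-P.

#' Linear-window policy for rate estimation
#'
#' Maximum rates are taken as the slope of the longest initial window of the
#' concentration series in which (i) a straight line still fits with
#' `R^2 >= r2_min` and (ii) acetate remains above `hac_floor_frac` of its
#' initial value, so the zero-order regime is not contaminated by substrate
#' limitation near exhaustion. Ties break toward the longer window.
#'
#' @param r2_min Minimum coefficient of determination for the window fit.
#' @param hac_floor_frac Fraction of initial acetate below which samples are
#'   excluded from the maximum-rate window.
#' @param exhaustion_frac Fraction of initial acetate below which acetate is
#'   considered exhausted (defines the maintenance window).
#' @param min_points Minimum number of samples in a rate window.
#' @return A list of class `window_policy`.
#' @export
window_policy <- function(r2_min = 0.98, hac_floor_frac = 0.10,
                          exhaustion_frac = 0.02, min_points = 3L) {
  stopifnot(r2_min > 0, r2_min <= 1, hac_floor_frac >= 0,
            hac_floor_frac < 1, exhaustion_frac >= 0,
            exhaustion_frac <= hac_floor_frac, min_points >= 2L)
  structure(list(r2_min = r2_min, hac_floor_frac = hac_floor_frac,
                 exhaustion_frac = exhaustion_frac,
                 min_points = as.integer(min_points)),
            class = "window_policy")
}

# Longest initial window [1..k] (k >= min_points, within `limit` points) whose
# OLS fit has R^2 >= r2_min. A flat series (no variance) counts as a perfect
# fit with slope 0. Returns slope per hour.
.initial_linear_fit <- function(t_min, y, limit, policy) {
  n <- min(limit, length(y))
  if (n < policy$min_points) return(NULL)
  t_h <- t_min / 60
  for (k in seq(n, policy$min_points)) {
    tt <- t_h[seq_len(k)]
    yy <- y[seq_len(k)]
    sst <- sum((yy - mean(yy))^2)
    if (sst <= .Machine$double.eps * max(1, mean(yy)^2) * k) {
      return(list(slope = 0, r2 = 1, n = k))
    }
    fit <- stats::lm.fit(cbind(1, tt), yy)
    sse <- sum(fit$residuals^2)
    r2 <- 1 - sse / sst
    if (r2 >= policy$r2_min) {
      return(list(slope = unname(fit$coefficients[2]), r2 = r2, n = k))
    }
  }
  NULL
}

.anaerobic_series <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("t_min", "po4", "hac") %in% names(profile)))
  if ("phase" %in% names(profile)) {
    profile <- profile[profile$phase == "anaerobic", , drop = FALSE]
  }
  if (nrow(profile) < 2L) {
    stop("need at least two anaerobic samples", call. = FALSE)
  }
  if (is.unsorted(profile$t_min, strictly = TRUE)) {
    stop("`t_min` must be strictly increasing", call. = FALSE)
  }
  if (any(profile$po4 < 0, na.rm = TRUE) || any(profile$hac < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  profile
}

# Number of leading samples with acetate above `frac` of its initial value.
.substrate_window <- function(hac, frac) {
  above <- hac >= frac * hac[1] & hac > 0
  if (!above[1]) return(0L)
  which.min(c(above, FALSE)) - 1L
}

#' Maximum specific acetate-uptake rate from a cycle profile
#'
#' Fits the initial linear segment of the anaerobic acetate series (see
#' [window_policy()]) and normalises the volumetric slope by active biomass.
#'
#' @param profile A cycle profile data frame with columns `t_min`, `po4`
#'   (P-mmol/L), `hac` (C-mmol/L) and optionally `phase`
#'   (`"anaerobic"`/`"aerobic"`; only anaerobic samples are used).
#' @param x_cmol Active biomass, C-mol/L (for the per-C-mol basis).
#' @param vss_g_l Volatile suspended solids, g/L (for the per-gVSS basis).
#' @param policy A [window_policy()].
#' @return A one-row tibble: `rate_cmmol_l_h` (volumetric), `qsa_cmol`
#'   (C-mmol per C-mol active biomass per h), `qsa_gvss` (C-mmol per gVSS
#'   per h), `r2`, `n_window`.
#' @export
estimate_uptake_rate <- function(profile, x_cmol = NULL, vss_g_l = NULL,
                                 policy = window_policy()) {
  profile <- .anaerobic_series(profile)
  k <- .substrate_window(profile$hac, policy$hac_floor_frac)
  if (k < policy$min_points) {
    stop("insufficient resolution: acetate exhausted before ",
         policy$min_points, " samples were taken", call. = FALSE)
  }
  fit <- .initial_linear_fit(profile$t_min, profile$hac, k, policy)
  if (is.null(fit)) {
    stop("no initial window satisfies the linearity policy", call. = FALSE)
  }
  rate <- max(0, -fit$slope)
  tibble::tibble(
    rate_cmmol_l_h = rate,
    qsa_cmol = if (!is.null(x_cmol)) rate / .check_pos(x_cmol, "x_cmol") else NA_real_,
    qsa_gvss = if (!is.null(vss_g_l)) rate / .check_pos(vss_g_l, "vss_g_l") else NA_real_,
    r2 = fit$r2, n_window = fit$n
  )
}

#' Maximum specific P-release rate during acetate uptake
#'
#' Mirrors [estimate_uptake_rate()] on the orthophosphate series, restricted
#' to the window where acetate is still present. This is the gross release
#' rate during uptake; the endogenous component is estimated separately by
#' [estimate_maintenance_rate()].
#'
#' @inheritParams estimate_uptake_rate
#' @return A one-row tibble: `rate_pmmol_l_h`, `qp_cmol`, `qp_gvss`, `r2`,
#'   `n_window`.
#' @export
estimate_release_rate <- function(profile, x_cmol = NULL, vss_g_l = NULL,
                                  policy = window_policy()) {
  profile <- .anaerobic_series(profile)
  k <- .substrate_window(profile$hac, policy$hac_floor_frac)
  if (k < policy$min_points) {
    stop("insufficient resolution: acetate exhausted before ",
         policy$min_points, " samples were taken", call. = FALSE)
  }
  fit <- .initial_linear_fit(profile$t_min, profile$po4, k, policy)
  if (is.null(fit)) {
    stop("no initial window satisfies the linearity policy", call. = FALSE)
  }
  rate <- max(0, fit$slope)
  tibble::tibble(
    rate_pmmol_l_h = rate,
    qp_cmol = if (!is.null(x_cmol)) rate / .check_pos(x_cmol, "x_cmol") else NA_real_,
    qp_gvss = if (!is.null(vss_g_l)) rate / .check_pos(vss_g_l, "vss_g_l") else NA_real_,
    r2 = fit$r2, n_window = fit$n
  )
}

#' Endogenous (maintenance) P-release rate
#'
#' Slope of the orthophosphate series over the substrate-free anaerobic
#' window (after acetate exhaustion), per unit active biomass. Glycogen
#' consumption for maintenance is deliberately not estimated: its magnitude
#' is below the resolution of routine glycogen assays.
#'
#' @inheritParams estimate_uptake_rate
#' @return A one-row tibble: `rate_pmmol_l_h`, `mp_cmol`, `mp_gvss`, `r2`,
#'   `n_window`.
#' @export
estimate_maintenance_rate <- function(profile, x_cmol = NULL, vss_g_l = NULL,
                                      policy = window_policy()) {
  profile <- .anaerobic_series(profile)
  hac0 <- profile$hac[1]
  idle <- profile$hac <= max(policy$exhaustion_frac * hac0, 1e-12)
  if (sum(idle) < 2L) {
    stop("no maintenance window: acetate never exhausted in the cycle",
         call. = FALSE)
  }
  sub <- profile[idle, , drop = FALSE]
  t_h <- sub$t_min / 60
  sst <- sum((sub$po4 - mean(sub$po4))^2)
  if (sst <= .Machine$double.eps * max(1, mean(sub$po4)^2) * nrow(sub)) {
    slope <- 0; r2 <- 1
  } else {
    fit <- stats::lm.fit(cbind(1, t_h), sub$po4)
    slope <- unname(fit$coefficients[2])
    r2 <- 1 - sum(fit$residuals^2) / sst
  }
  rate <- max(0, slope)
  tibble::tibble(
    rate_pmmol_l_h = rate,
    mp_cmol = if (!is.null(x_cmol)) rate / .check_pos(x_cmol, "x_cmol") else NA_real_,
    mp_gvss = if (!is.null(vss_g_l)) rate / .check_pos(vss_g_l, "vss_g_l") else NA_real_,
    r2 = r2, n_window = nrow(sub)
  )
}

.check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive number", call. = FALSE)
  }
  x
}

#' Anaerobic stoichiometry from a cycle test
#'
#' Computes the ratios of the anaerobic deltas: P released, glycogen
#' consumed, PHB and PHV formed, each per C-mol of acetate taken up.
#' Acetate uptake is the begin-to-end drop of the anaerobic acetate series.
#' P release per HAc is taken as the ratio of the fitted P-release and
#' HAc-uptake slopes over the acetate-present window, which excludes the
#' endogenous release that continues after exhaustion (the maintenance
#' regime is reported separately). Polymer deltas come from the begin/end
#' anaerobic panels.
#'
#' @inheritParams estimate_uptake_rate
#' @param panel_begin,panel_end One-row data frames (or named lists) with
#'   `gly_mg_l`, `phb_mg_l`, `phv_mg_l` measured at the start and end of the
#'   anaerobic phase.
#' @return A one-row tibble with `p_hac` (P-mol/C-mol), `gly_hac`,
#'   `phb_hac`, `phv_hac`, and the derived `phv_phb`, `gly_phb`, `phv_gly`
#'   (C-mol/C-mol), plus `dhac_cmmol`, `dp_pmmol` and a `flag` column
#'   (`"negative_formation"` when a polymer delta runs against the expected
#'   direction; the value is reported as measured).
#' @export
compute_stoichiometry <- function(profile, panel_begin, panel_end,
                                  policy = window_policy()) {
  profile <- .anaerobic_series(profile)
  pb <- .as_polymer_panel(panel_begin)
  pe <- .as_polymer_panel(panel_end)

  dhac <- profile$hac[1] - profile$hac[nrow(profile)]
  if (dhac <= 0) {
    stop("no acetate consumed in the anaerobic phase (delta HAc <= 0)",
         call. = FALSE)
  }

  up <- estimate_uptake_rate(profile, policy = policy)
  rel <- estimate_release_rate(profile, policy = policy)
  if (up$rate_cmmol_l_h <= 0) {
    stop("acetate uptake rate is zero; cannot form stoichiometric ratios",
         call. = FALSE)
  }
  p_hac <- rel$rate_pmmol_l_h / up$rate_cmmol_l_h

  gly_cons <- (pb$gly_mg_l - pe$gly_mg_l) / monomer_cmol_mass("glycogen")
  phb_form <- (pe$phb_mg_l - pb$phb_mg_l) / monomer_cmol_mass("phb")
  phv_form <- (pe$phv_mg_l - pb$phv_mg_l) / monomer_cmol_mass("phv")

  gly_hac <- gly_cons / dhac
  phb_hac <- phb_form / dhac
  phv_hac <- phv_form / dhac
  flag <- if (any(c(gly_hac, phb_hac, phv_hac) < 0)) {
    "negative_formation"
  } else NA_character_

  tibble::tibble(
    p_hac = p_hac, gly_hac = gly_hac, phb_hac = phb_hac, phv_hac = phv_hac,
    phv_phb = ifelse(phb_hac > 0, phv_hac / phb_hac, NA_real_),
    gly_phb = ifelse(phb_hac > 0, gly_hac / phb_hac, NA_real_),
    phv_gly = ifelse(gly_hac > 0, phv_hac / gly_hac, NA_real_),
    dhac_cmmol = dhac, dp_pmmol = p_hac * dhac, flag = flag
  )
}

.as_polymer_panel <- function(panel) {
  panel <- as.list(panel)
  need <- c("gly_mg_l", "phb_mg_l", "phv_mg_l")
  if (!all(need %in% names(panel))) {
    stop("panel must provide ", paste(need, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(panel[need])
  if (any(vals < 0, na.rm = TRUE)) {
    stop("polymer concentrations must be >= 0", call. = FALSE)
  }
  as.list(vals)
}

#' Convert a biomass-specific rate between unit bases
#'
#' Converts between the per-gVSS and per-C-mol-active-biomass bases using the
#' active-biomass content of the solids: `rate_cmol = rate_gvss * VSS / X`.
#'
#' @param rate Rate value(s) on the `from` basis.
#' @param from `"gvss"` or `"cmol"`.
#' @param vss_g_l VSS, g/L.
#' @param x_cmol Active biomass, C-mol/L.
#' @return The rate on the other basis.
#' @examples
#' # VSS that is entirely active biomass: the conversion factor is the
#' # biomass C-mol mass (~26 g/C-mol)
#' convert_rate_basis(1, "gvss", vss_g_l = 26.02,
#'                    x_cmol = mass_to_cmol(26.02))
#' @export
convert_rate_basis <- function(rate, from = c("gvss", "cmol"), vss_g_l,
                               x_cmol) {
  from <- match.arg(from)
  stopifnot(is.numeric(rate))
  .check_pos(vss_g_l, "vss_g_l")
  .check_pos(x_cmol, "x_cmol")
  if (from == "gvss") rate * vss_g_l / x_cmol else rate * x_cmol / vss_g_l
}

#' Full kinetic and stoichiometric analysis of one cycle test
#'
#' Convenience wrapper running [estimate_uptake_rate()],
#' [estimate_release_rate()], [estimate_maintenance_rate()] (when acetate is
#' exhausted within the anaerobic phase) and [compute_stoichiometry()] on a
#' cycle profile with its begin/end panels.
#'
#' @inheritParams compute_stoichiometry
#' @param panel_begin,panel_end One-row data frames with the polymer columns
#'   of [compute_stoichiometry()] plus `vss_g_l` (and optionally `iss_g_l`)
#'   so active biomass can be computed from the begin panel.
#' @return An object of class `cycle_fit` with components `rates` (tibble),
#'   `stoichiometry` (tibble), `x_cmol`, `vss_g_l`, `profile`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
analyze_cycle <- function(profile, panel_begin, panel_end,
                          policy = window_policy()) {
  pb <- as.list(panel_begin)
  if (is.null(pb$vss_g_l)) {
    stop("panel_begin must provide vss_g_l to compute active biomass",
         call. = FALSE)
  }
  x_cmol <- active_biomass_cmol(pb$vss_g_l, pb$phb_mg_l / 1000,
                                pb$phv_mg_l / 1000, pb$gly_mg_l / 1000)
  vss <- pb$vss_g_l

  up <- estimate_uptake_rate(profile, x_cmol, vss, policy)
  rel <- estimate_release_rate(profile, x_cmol, vss, policy)
  mnt <- tryCatch(estimate_maintenance_rate(profile, x_cmol, vss, policy),
                  error = function(e) NULL)
  stoich <- compute_stoichiometry(profile, panel_begin, panel_end, policy)

  rates <- dplyr::bind_rows(
    tibble::tibble(parameter = "qsa_max", per_cmol = up$qsa_cmol,
                   per_gvss = up$qsa_gvss, r2 = up$r2, n_window = up$n_window),
    tibble::tibble(parameter = "qp_max", per_cmol = rel$qp_cmol,
                   per_gvss = rel$qp_gvss, r2 = rel$r2, n_window = rel$n_window),
    if (!is.null(mnt)) {
      tibble::tibble(parameter = "m_p", per_cmol = mnt$mp_cmol,
                     per_gvss = mnt$mp_gvss, r2 = mnt$r2,
                     n_window = mnt$n_window)
    }
  )

  structure(
    list(rates = rates, stoichiometry = stoich, x_cmol = x_cmol,
         vss_g_l = vss, profile = tibble::as_tibble(profile),
         policy = policy),
    class = "cycle_fit"
  )
}

#' @export
print.cycle_fit <- function(x, ...) {
  cat("<cycle_fit>  active biomass:", signif(x$x_cmol * 1000, 4),
      "C-mmol/L; VSS:", signif(x$vss_g_l, 4), "g/L\n")
  cat("Rates (per C-mol active biomass / per gVSS, h^-1):\n")
  print(x$rates)
  cat("Anaerobic stoichiometry:\n")
  print(x$stoichiometry)
  invisible(x)
}
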