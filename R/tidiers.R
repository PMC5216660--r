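# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cycle-test analysis
#'
#' @param x A `cycle_fit` from [analyze_cycle()].
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity: kinetic rates on
#'   both unit bases and the stoichiometric ratios.
#' @export
tidy.cycle_fit <- function(x, ...) {
  rates <- tidyr::pivot_longer(x$rates, c("per_cmol", "per_gvss"),
                               names_to = "basis", values_to = "estimate")
  rates <- dplyr::transmute(
    rates,
    term = paste(.data$parameter, .data$basis, sep = "_"),
    estimate = .data$estimate,
    unit = dplyr::case_when(
      .data$parameter == "qsa_max" & .data$basis == "per_cmol" ~ "C-mmol/(C-mol h)",
      .data$parameter == "qsa_max" ~ "C-mmol/(gVSS h)",
      .data$basis == "per_cmol" ~ "P-mmol/(C-mol h)",
      TRUE ~ "P-mmol/(gVSS h)"
    )
  )
  st <- x$stoichiometry
  stoich <- tibble::tibble(
    term = c("p_hac", "gly_hac", "phb_hac", "phv_hac", "phv_phb",
             "gly_phb", "phv_gly"),
    estimate = c(st$p_hac, st$gly_hac, st$phb_hac, st$phv_hac, st$phv_phb,
                 st$gly_phb, st$phv_gly),
    unit = c("P-mol/C-mol", rep("C-mol/C-mol", 6))
  )
  dplyr::bind_rows(rates, stoich)
}

#' @rdname tidy.cycle_fit
#' @export
glance.cycle_fit <- function(x, ...) {
  st <- x$stoichiometry
  qsa <- x$rates[x$rates$parameter == "qsa_max", ]
  qp <- x$rates[x$rates$parameter == "qp_max", ]
  mp <- x$rates[x$rates$parameter == "m_p", ]
  tibble::tibble(
    qsa_cmol = qsa$per_cmol, qp_cmol = qp$per_cmol,
    mp_cmol = if (nrow(mp)) mp$per_cmol else NA_real_,
    p_hac = st$p_hac, gly_hac = st$gly_hac, phb_hac = st$phb_hac,
    phv_hac = st$phv_hac,
    x_cmol = x$x_cmol, vss_g_l = x$vss_g_l,
    n_obs = nrow(x$profile)
  )
}

#' Tidy a mixing-model fit
#'
#' @param x A `shift_fit` from [mixing_fit()].
#' @param ... Unused.
#' @return One row per stoichiometric ratio with observed, fitted and
#'   residual values.
#' @export
tidy.shift_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$observed),
    observed = unlist(x$observed),
    fitted = unlist(x$fitted),
    residual = unlist(x$residuals)
  )
}

#' @rdname tidy.shift_fit
#' @export
glance.shift_fit <- function(x, ...) {
  tibble::tibble(lam = x$lam, alpha = x$alpha, rss = x$rss)
}
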