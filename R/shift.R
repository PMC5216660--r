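# The poly-P/glycogen metabolic shift: anaerobic acetate uptake can be
# powered by poly-P hydrolysis (1 mol ATP per P-mol, released as ortho-P) or
# by glycolysis of glycogen (~0.5 mol ATP per C-mol). A culture's observed
# anaerobic stoichiometry is modelled as a convex mixture of two measured
# end members: a poly-P-saturated (PAO-like) and a poly-P-depleted
# (glycogen-only, GAO-like) metabolism.

#' Energetic parameters of the shift model
#'
#' @param y_atp_polyp ATP yield of poly-P hydrolysis, mol ATP per P-mol.
#' @param y_atp_gly ATP yield of anaerobic glycogen conversion to PHA, mol
#'   ATP per C-mol glycogen. The value depends on the glycolytic route (EMP
#'   vs ED); 0.5 is the conventional net yield.
#' @return A list of class `shift_params` also carrying the degrees of
#'   reduction of acetate, glycogen, PHB and PHV (recomputed from the
#'   monomer formulas).
#' @export
shift_params <- function(y_atp_polyp = 1.0, y_atp_gly = 0.5) {
  stopifnot(y_atp_polyp > 0, y_atp_gly > 0)
  structure(list(
    y_atp_polyp = y_atp_polyp,
    y_atp_gly = y_atp_gly,
    gamma = c(hac = degree_of_reduction("acetate"),
              glycogen = degree_of_reduction("glycogen"),
              phb = degree_of_reduction("phb"),
              phv = degree_of_reduction("phv"),
              co2 = 0)
  ), class = "shift_params")
}

.ratio_cols <- c("p_hac", "gly_hac", "phb_hac", "phv_hac")

#' End members of the mixing model
#'
#' Default end members are the two extreme reference conditions of
#' [clade_iic_reference()]: the poly-P-depleted culture (glycogen-only
#' metabolism, `p_hac` ~ 0) and the highest-P culture (poly-P-dominated
#' metabolism).
#'
#' @param s_pao,s_gao One-row data frames (or named lists) with `p_hac`,
#'   `gly_hac`, `phb_hac`, `phv_hac`.
#' @return A list of class `end_members`.
#' @export
end_members <- function(s_pao = NULL, s_gao = NULL) {
  ref <- clade_iic_reference()
  pick <- function(row) as.list(row[.ratio_cols])
  if (is.null(s_gao)) s_gao <- pick(ref[1, ])
  if (is.null(s_pao)) s_pao <- pick(ref[nrow(ref), ])
  s_pao <- lapply(as.list(s_pao)[.ratio_cols], as.numeric)
  s_gao <- lapply(as.list(s_gao)[.ratio_cols], as.numeric)
  if (anyNA(unlist(s_pao)) || anyNA(unlist(s_gao))) {
    stop("end members must provide ", paste(.ratio_cols, collapse = ", "),
         call. = FALSE)
  }
  if (s_pao$p_hac <= s_gao$p_hac) {
    stop("s_pao must release more P per HAc than s_gao", call. = FALSE)
  }
  structure(list(s_pao = s_pao, s_gao = s_gao), class = "end_members")
}

#' Fraction of anaerobic ATP supplied by poly-P
#'
#' `alpha = y_polyp * P/HAc / (y_polyp * P/HAc + y_gly * gly/HAc)`: the share
#' of the ATP for acetate uptake and activation that comes from poly-P
#' hydrolysis rather than glycolysis. Maintenance ATP is not counted.
#'
#' @param stoich A data frame with columns `p_hac` and `gly_hac` (e.g. from
#'   [compute_stoichiometry()]), or a single numeric `p_hac` if `gly_hac` is
#'   given.
#' @param gly_hac Glycogen consumed per acetate carbon, C-mol/C-mol (when
#'   `stoich` is given as a numeric `p_hac`).
#' @param params A [shift_params()].
#' @return Numeric vector of ATP fractions in `[0, 1]`; `NA` where both
#'   energy terms are zero (undefined).
#' @examples
#' atp_fraction_from_polyp(0.61, 0.66) # poly-P-dominated, ~0.65
#' @export
atp_fraction_from_polyp <- function(stoich, gly_hac = NULL,
                                    params = shift_params()) {
  if (is.data.frame(stoich)) {
    p <- stoich$p_hac
    g <- stoich$gly_hac
  } else {
    p <- stoich
    g <- gly_hac
  }
  stopifnot(is.numeric(p), is.numeric(g), length(p) == length(g))
  if (any(p < 0, na.rm = TRUE) || any(g < 0, na.rm = TRUE)) {
    stop("stoichiometric ratios must be >= 0", call. = FALSE)
  }
  num <- params$y_atp_polyp * p
  den <- num + params$y_atp_gly * g
  ifelse(den > 0, num / den, NA_real_)
}

#' Predict anaerobic stoichiometry from the mixing coefficient
#'
#' Convex combination of the end members:
#' `lam * s_pao + (1 - lam) * s_gao`. Inverse of [mixing_fit()].
#'
#' @param lam Mixing coefficient in `[0, 1]` (1 = fully poly-P-dominated).
#' @param ends An [end_members()] object.
#' @return A tibble with one row per `lam` and columns `lam`, `p_hac`,
#'   `gly_hac`, `phb_hac`, `phv_hac`, `phv_phb`.
#' @export
predict_stoichiometry <- function(lam, ends = end_members()) {
  stopifnot(is.numeric(lam))
  if (any(lam < 0 | lam > 1, na.rm = TRUE)) {
    stop("`lam` must lie in [0, 1]", call. = FALSE)
  }
  mix <- function(col) lam * ends$s_pao[[col]] + (1 - lam) * ends$s_gao[[col]]
  out <- tibble::tibble(
    lam = lam,
    p_hac = mix("p_hac"), gly_hac = mix("gly_hac"),
    phb_hac = mix("phb_hac"), phv_hac = mix("phv_hac")
  )
  dplyr::mutate(out, phv_phb = ifelse(.data$phb_hac > 0,
                                      .data$phv_hac / .data$phb_hac,
                                      NA_real_))
}

#' Fit the two-end-member mixing model to an observed stoichiometry
#'
#' Least-squares mixing coefficient `lam` in `[0, 1]` minimising
#' `sum(w * (observed - (lam * s_pao + (1 - lam) * s_gao))^2)` over the four
#' ratios (P/HAc, gly/HAc, PHB/HAc, PHV/HAc). The unconstrained optimum is
#' closed-form and is clipped to `[0, 1]`.
#'
#' @param observed A one-row data frame (or named list) with `p_hac`,
#'   `gly_hac`, `phb_hac`, `phv_hac`.
#' @param ends An [end_members()] object.
#' @param weights Non-negative weights for the four ratios (default equal).
#' @param params A [shift_params()] used to attach the ATP partition of the
#'   observed stoichiometry.
#' @return An object of class `shift_fit`: `lam`, per-ratio `residuals`
#'   (observed - fitted), `fitted`, `observed`, `alpha` (ATP fraction from
#'   poly-P of the observed stoichiometry), `rss`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' mixing_fit(list(p_hac = 0.19, gly_hac = 1.22, phb_hac = 1.35,
#'                 phv_hac = 0.26))
#' @export
mixing_fit <- function(observed, ends = end_members(),
                       weights = c(1, 1, 1, 1), params = shift_params()) {
  obs <- lapply(as.list(observed)[.ratio_cols], as.numeric)
  if (anyNA(unlist(obs))) {
    stop("observed stoichiometry must provide ",
         paste(.ratio_cols, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.numeric(weights), length(weights) == 4L, all(weights >= 0),
            sum(weights) > 0)

  o <- unlist(obs)
  p <- unlist(ends$s_pao[.ratio_cols])
  g <- unlist(ends$s_gao[.ratio_cols])
  d <- p - g
  denom <- sum(weights * d^2)
  if (denom <= .Machine$double.eps) {
    stop("degenerate fit: end members are identical in every ratio",
         call. = FALSE)
  }
  lam <- sum(weights * (o - g) * d) / denom
  lam <- min(max(lam, 0), 1)

  fitted <- g + lam * d
  resid <- o - fitted
  structure(list(
    lam = lam,
    fitted = tibble::as_tibble(as.list(fitted)),
    observed = tibble::as_tibble(obs),
    residuals = tibble::as_tibble(as.list(resid)),
    rss = sum(weights * resid^2),
    weights = weights,
    alpha = atp_fraction_from_polyp(obs$p_hac, obs$gly_hac, params),
    ends = ends
  ), class = "shift_fit")
}

#' @export
print.shift_fit <- function(x, ...) {
  cat("<shift_fit>  lam =", signif(x$lam, 4),
      " (0 = glycogen-only, 1 = poly-P end member)\n")
  cat("ATP fraction from poly-P (alpha):", signif(x$alpha, 4), "\n")
  cat("Residuals (observed - fitted):\n")
  print(x$residuals)
  invisible(x)
}

#' Carbon and electron closure of an anaerobic stoichiometry
#'
#' The anaerobic conversion is HAc + poly-P + glycogen -> PHB/PHV + CO2 +
#' ortho-P. Carbon closure infers the CO2 production per C-mol HAc,
#' `co2_hac = (1 + gly_hac) - (phb_hac + phv_hac)`, which must be
#' non-negative for a feasible stoichiometry. Electron closure evaluates the
#' degree-of-reduction balance per C-mol HAc,
#' `gamma_HAc + gamma_gly * gly_hac - gamma_PHB * phb_hac - gamma_PHV *
#' phv_hac`; measured stoichiometries generally do not close exactly and the
#' residual is reported, not raised.
#'
#' @param stoich A data frame with columns `gly_hac`, `phb_hac`, `phv_hac`
#'   (rows are processed independently).
#' @param params A [shift_params()].
#' @return A tibble: `co2_hac`, `electron_residual` (e-eq per C-mol HAc) and
#'   `flag` (`"carbon_infeasible"` where the inferred CO2 is negative).
#' @export
balance_residuals <- function(stoich, params = shift_params()) {
  stoich <- tibble::as_tibble(as.list(stoich)[c("gly_hac", "phb_hac", "phv_hac")])
  if (anyNA(stoich)) {
    stop("stoich must provide gly_hac, phb_hac, phv_hac", call. = FALSE)
  }
  if (any(unlist(stoich) < 0)) {
    stop("stoichiometric ratios must be >= 0", call. = FALSE)
  }
  gam <- params$gamma
  dplyr::mutate(
    stoich,
    co2_hac = (1 + .data$gly_hac) - (.data$phb_hac + .data$phv_hac),
    electron_residual = gam[["hac"]] + gam[["glycogen"]] * .data$gly_hac -
      gam[["phb"]] * .data$phb_hac - gam[["phv"]] * .data$phv_hac,
    flag = ifelse(.data$co2_hac < 0, "carbon_infeasible", NA_character_)
  )
}
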