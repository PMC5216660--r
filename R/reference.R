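# Published reference measurements for an enriched "Candidatus Accumulibacter
# phosphatis" clade IIC culture across a range of biomass P contents. The
# first row is the poly-P-depleted condition (glycogen-only, GAO-like
# metabolism); the last row the highest-P condition (poly-P-dominated
# metabolism). These rows anchor the mixing model's end members and serve as
# internal-consistency fixtures for the stoichiometric identities.

#' Reference anaerobic stoichiometry and kinetics for clade IIC PAO
#'
#' Anaerobic kinetic and stoichiometric parameters measured on a highly
#' enriched Accumulibacter clade IIC culture at six biomass P contents,
#' obtained by varying the influent P/C ratio (SRT 8 d, HRT 12 h, pH 7,
#' 20 degrees C, acetate feed). The depleted row (`pc_influent = 0`) was
#' obtained after poly-P depletion in a batch experiment.
#'
#' @return A tibble with one row per condition and columns:
#' \describe{
#'   \item{pc_influent}{influent P/C ratio, P-mol/C-mol (0 = depleted batch)}
#'   \item{iss_tss}{initial inorganic/total suspended solids ratio, mg/mg}
#'   \item{polyp_per_x}{poly-P per active biomass, P-mol/C-mol}
#'   \item{pns_tss}{non-soluble P per TSS, mg/mg (NA where below detection)}
#'   \item{phv_phb, phv_hac, phb_hac, gly_hac}{anaerobic ratios, C-mol/C-mol}
#'   \item{p_hac}{P released per acetate carbon taken up, P-mol/C-mol}
#'   \item{qsa_gvss, qp_gvss}{maximum acetate-uptake / P-release rates,
#'     C-mmol/(gVSS h) and P-mmol/(gVSS h)}
#'   \item{qsa_cmol, qp_cmol}{the same rates per C-mol of active biomass}
#' }
#' @examples
#' clade_iic_reference()
#' @export
clade_iic_reference <- function() {
  tibble::tibble(
    pc_influent = c(0,     0.038, 0.038, 0.051, 0.077, 0.110),
    iss_tss     = c(0.07,  0.27,  0.29,  0.31,  0.40,  0.53),
    polyp_per_x = c(0.01,  0.09,  0.11,  0.12,  0.16,  0.29),
    pns_tss     = c(NA,    0.069, 0.072, 0.095, 0.130, 0.171),
    phv_phb     = c(0.27,  0.19,  0.16,  0.15,  0.14,  0.12),
    phv_hac     = c(0.32,  0.26,  0.19,  0.16,  0.14,  0.12),
    phb_hac     = c(1.22,  1.35,  1.17,  1.07,  1.00,  0.97),
    p_hac       = c(0.01,  0.19,  0.30,  0.33,  0.50,  0.61),
    gly_hac     = c(1.01,  1.22,  0.86,  1.02,  0.89,  0.66),
    qsa_gvss    = c(2.3,   3.5,   5.5,   6.0,   5.8,   4.9),
    qp_gvss     = c(NA,    0.9,   1.7,   1.9,   3.1,   3.2),
    qsa_cmol    = c(81,    121,   188,   198,   177,   157),
    qp_cmol     = c(0,     31,    56,    64,    95,    103)
  )
}
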