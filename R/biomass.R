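# Active-biomass accounting: VSS minus storage polymers, expressed per gVSS
# or per C-mol of biomass with the elemental composition CH2.09O0.54N0.20P0.015.

# Monomer basis for C-mol conversions. Glycogen uses the anhydroglucose unit
# (C6H10O5 per 6 C, ~27.02 g/C-mol), not free glucose (30 g/C-mol): the
# polymerised glucan is what the biomass assay hydrolyses, and the choice
# moves every glycogen ratio by ~11%.
.monomers <- list(
  active_biomass = list(formula = "CH2.09O0.54N0.2P0.015", c_atoms = 1),
  glycogen       = list(formula = "C6H10O5",               c_atoms = 6),
  phb            = list(formula = "C4H6O2",                c_atoms = 4),
  phv            = list(formula = "C5H8O2",                c_atoms = 5),
  acetate        = list(formula = "C2H4O2",                c_atoms = 2)
)

#' Mass of one C-mol of a supported monomer
#'
#' @param monomer One of `"active_biomass"` (CH2.09O0.54N0.20P0.015, ~26.0
#'   g/C-mol), `"glycogen"` (anhydroglucose, ~27.02), `"phb"` (~21.52),
#'   `"phv"` (~20.02) or `"acetate"` (~30.03).
#' @return g per C-mol.
#' @examples
#' monomer_cmol_mass("active_biomass")
#' @export
monomer_cmol_mass <- function(monomer) {
  vapply(monomer, function(m) {
    if (!m %in% names(.monomers)) {
      stop("unknown monomer '", m, "'; supported: ",
           paste(names(.monomers), collapse = ", "), call. = FALSE)
    }
    spec <- .monomers[[m]]
    molar_mass(spec$formula) / spec$c_atoms
  }, numeric(1), USE.NAMES = FALSE)
}

#' Convert mass concentration to carbon molarity
#'
#' @param mass_g_l Concentration in g/L.
#' @param monomer Monomer key, see [monomer_cmol_mass()].
#' @return Concentration in C-mol/L.
#' @examples
#' mass_to_cmol(27.02, "glycogen") # ~1 C-mol/L
#' @export
mass_to_cmol <- function(mass_g_l, monomer = "active_biomass") {
  stopifnot(is.numeric(mass_g_l), all(mass_g_l >= 0, na.rm = TRUE))
  mass_g_l / monomer_cmol_mass(monomer)
}

#' @rdname mass_to_cmol
#' @param cmol_l Concentration in C-mol/L.
#' @export
cmol_to_mass <- function(cmol_l, monomer = "active_biomass") {
  stopifnot(is.numeric(cmol_l), all(cmol_l >= 0, na.rm = TRUE))
  cmol_l * monomer_cmol_mass(monomer)
}

#' Degree of reduction of an organic compound
#'
#' Available electron equivalents per C-mol on full oxidation to CO2 and H2O
#' with NH3 as the nitrogen reference: acetate and glycogen 4.0, PHB 4.5,
#' PHV 4.8 e-eq/C-mol. Computed from the formula, never hard-coded.
#'
#' @param formula Formula string or a monomer key from [monomer_cmol_mass()].
#' @return Electron equivalents per C-mol.
#' @examples
#' degree_of_reduction("phb") # 4.5
#' @export
degree_of_reduction <- function(formula) {
  vapply(formula, function(f) {
    if (f %in% names(.monomers)) f <- .monomers[[f]]$formula
    counts <- count_atoms(f)
    get0 <- function(el) if (el %in% names(counts)) counts[[el]] else 0
    if (get0("C") <= 0) stop("'", f, "' has no carbon", call. = FALSE)
    (4 * get0("C") + get0("H") - 2 * get0("O") - 3 * get0("N")) / get0("C")
  }, numeric(1), USE.NAMES = FALSE)
}

#' Active biomass concentration
#'
#' Active biomass is the volatile suspended solids minus the storage polymers:
#' `VSS - PHB - PHV - glycogen`. Unbiodegradable endogenous residue is
#' neglected (a no-op in these highly enriched cultures); the `residue_g_l`
#' hook is kept in the interface for completeness.
#'
#' @param vss_g_l Volatile suspended solids, g/L.
#' @param phb_g_l,phv_g_l,gly_g_l Storage polymer concentrations, g/L.
#' @param residue_g_l Endogenous residue, g/L (default 0).
#' @return Active biomass, g/L.
#' @examples
#' active_biomass(3.0, 0.3, 0.1, 0.4) # 2.2 g/L
#' @export
active_biomass <- function(vss_g_l, phb_g_l = 0, phv_g_l = 0, gly_g_l = 0,
                           residue_g_l = 0) {
  stopifnot(is.numeric(vss_g_l), all(vss_g_l >= 0, na.rm = TRUE),
            all(phb_g_l >= 0, na.rm = TRUE), all(phv_g_l >= 0, na.rm = TRUE),
            all(gly_g_l >= 0, na.rm = TRUE))
  x <- vss_g_l - phb_g_l - phv_g_l - gly_g_l - residue_g_l
  if (any(x < 0, na.rm = TRUE)) {
    stop("inconsistent panel: storage polymers exceed VSS", call. = FALSE)
  }
  x
}

#' @rdname active_biomass
#' @return `active_biomass_cmol()`: active biomass in C-mol/L.
#' @export
active_biomass_cmol <- function(vss_g_l, phb_g_l = 0, phv_g_l = 0,
                                gly_g_l = 0, residue_g_l = 0) {
  mass_to_cmol(active_biomass(vss_g_l, phb_g_l, phv_g_l, gly_g_l, residue_g_l),
               "active_biomass")
}

#' Storage-polymer ratios of a biomass state
#'
#' Poly-P/active-biomass (P-mol/C-mol), glycogen/active-biomass
#' (C-mol/C-mol) and poly-P/glycogen (P-mol/C-mol). Ratios with a zero
#' denominator are reported as `NA` (undefined), not 0.
#'
#' @param x_cmol Active biomass, C-mol/L.
#' @param polyp_pmol Poly-P, P-mol/L (any consistent molar unit works as long
#'   as all three arguments share it, e.g. mmol/L).
#' @param gly_cmol Glycogen, C-mol/L.
#' @return A tibble: `polyp_per_x`, `gly_per_x`, `polyp_per_gly`.
#' @examples
#' storage_ratios(x_cmol = 1, polyp_pmol = 0.30, gly_cmol = 1.0)
#' @export
storage_ratios <- function(x_cmol, polyp_pmol, gly_cmol) {
  stopifnot(is.numeric(x_cmol), is.numeric(polyp_pmol), is.numeric(gly_cmol))
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(
    polyp_per_x = safe_div(polyp_pmol, x_cmol),
    gly_per_x = safe_div(gly_cmol, x_cmol),
    polyp_per_gly = safe_div(polyp_pmol, gly_cmol)
  )
}
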