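# Influent chemistry: chemical formulas, molarities, theoretical COD and the
# influent P/C ratio that indexes an EBPR experiment.

# Conventional standard atomic weights (IUPAC), 3 decimals. Kept as a single
# table so every derived quantity in the package is bit-stable.
.atomic_masses <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.060,
  Cl = 35.450, K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.380, Se = 78.971,
  Br = 79.904, Mo = 95.950, I = 126.904
)

# Charge contributed by common spectator cations when the rest of the formula
# is an organic anion (used in the electron balance behind theoretical COD).
.cation_charge <- c(Na = 1, K = 1, Li = 1, Mg = 2, Ca = 2)

#' Count atoms in a chemical formula
#'
#' Parses a formula such as `"NH4Cl"`, `"NaC2H3O2.3H2O"` or `"(PO3)3MgK"`
#' into element counts. Supported syntax: element symbols with optional
#' (possibly fractional) counts, single-level parenthesised groups with a
#' multiplier, and a single trailing hydrate suffix (`.nH2O` or the typographic
#' middle dot). Fractional counts allow average compositions such as the
#' elemental biomass formula `CH2.09O0.54N0.2P0.015`. Nested parentheses are
#' rejected.
#'
#' @param formula A single formula string.
#' @return A named numeric vector of atom counts per formula unit.
#' @examples
#' count_atoms("NaC2H3O2.3H2O")
#' count_atoms("(PO3)3MgK")
#' @export
count_atoms <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(trimws(formula))) {
    stop("`formula` must be a single non-empty string", call. = FALSE)
  }
  f <- gsub("·", ".", trimws(formula))

  n_h2o <- 0
  hyd <- regmatches(f, regexec("\\.([0-9]*)H2O$", f))[[1]]
  if (length(hyd) == 2L) {
    n_h2o <- if (nzchar(hyd[2])) as.numeric(hyd[2]) else 1
    f <- sub("\\.[0-9]*H2O$", "", f)
  }

  counts <- .scan_formula(f, formula)
  if (n_h2o > 0) {
    counts <- .add_counts(counts, c(H = 2 * n_h2o, O = n_h2o))
  }
  if (!length(counts) || sum(counts) <= 0) {
    stop("formula '", formula, "' contains no atoms", call. = FALSE)
  }
  counts
}

.add_counts <- function(a, b) {
  for (el in names(b)) a[el] <- (if (el %in% names(a)) a[[el]] else 0) + b[[el]]
  a
}

.scan_formula <- function(s, original) {
  counts <- numeric(0)
  while (nzchar(s)) {
    if (startsWith(s, "(")) {
      m <- regmatches(s, regexec("^\\(([A-Za-z0-9.]+)\\)([0-9]*\\.?[0-9]*)", s))[[1]]
      if (!length(m)) {
        stop("malformed or nested group near '", s, "' in formula '",
             original, "'", call. = FALSE)
      }
      mult <- if (nzchar(m[3])) as.numeric(m[3]) else 1
      inner <- .scan_elements(m[2], original)
      counts <- .add_counts(counts, inner * mult)
      s <- substr(s, nchar(m[1]) + 1L, nchar(s))
    } else {
      m <- regmatches(s, regexec("^([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", s))[[1]]
      if (!length(m) || !nzchar(m[1])) {
        stop("malformed formula near '", s, "' in '", original, "'",
             call. = FALSE)
      }
      counts <- .add_counts(counts, .element_count(m[2], m[3], original))
      s <- substr(s, nchar(m[1]) + 1L, nchar(s))
    }
  }
  counts
}

.scan_elements <- function(s, original) {
  counts <- numeric(0)
  while (nzchar(s)) {
    m <- regmatches(s, regexec("^([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", s))[[1]]
    if (!length(m) || !nzchar(m[1])) {
      stop("malformed group content near '", s, "' in formula '", original,
           "'", call. = FALSE)
    }
    counts <- .add_counts(counts, .element_count(m[2], m[3], original))
    s <- substr(s, nchar(m[1]) + 1L, nchar(s))
  }
  counts
}

.element_count <- function(el, num, original) {
  if (!el %in% names(.atomic_masses)) {
    stop("unknown element symbol '", el, "' in formula '", original, "'",
         call. = FALSE)
  }
  n <- if (nzchar(num)) as.numeric(num) else 1
  if (is.na(n) || n < 0) {
    stop("invalid count '", num, "' for element '", el, "' in formula '",
         original, "'", call. = FALSE)
  }
  stats::setNames(n, el)
}

#' Molar mass of a chemical formula
#'
#' @inheritParams count_atoms
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("H2O")           # 18.015
#' molar_mass("NaC2H3O2.3H2O") # sodium acetate trihydrate, 136.08
#' @export
molar_mass <- function(formula) {
  counts <- count_atoms(formula)
  sum(counts * .atomic_masses[names(counts)])
}

#' Carbon molarity of a medium component
#'
#' @param formula Component formula string.
#' @param mass_mg_per_l Mass concentration, mg/L.
#' @return Carbon concentration, C-mmol/L.
#' @examples
#' component_cmolarity("NaC2H3O2.3H2O", 860) # ~12.6 C-mmol/L
#' @export
component_cmolarity <- function(formula, mass_mg_per_l) {
  .atom_molarity(formula, mass_mg_per_l, "C")
}

#' Nitrogen molarity of a medium component
#'
#' @inheritParams component_cmolarity
#' @return Nitrogen concentration, N-mmol/L.
#' @examples
#' nitrogen_mmolarity("NH4Cl", 107) # ~2 N-mmol/L
#' @export
nitrogen_mmolarity <- function(formula, mass_mg_per_l) {
  .atom_molarity(formula, mass_mg_per_l, "N")
}

.atom_molarity <- function(formula, mass_mg_per_l, element) {
  stopifnot(is.numeric(mass_mg_per_l), all(mass_mg_per_l >= 0))
  vapply(seq_along(formula), function(i) {
    counts <- count_atoms(formula[[i]])
    mm <- sum(counts * .atomic_masses[names(counts)])
    if (mm <= 0) stop("formula '", formula[[i]], "' has zero molar mass", call. = FALSE)
    n <- if (element %in% names(counts)) counts[[element]] else 0
    mass_mg_per_l[[i]] / mm * n
  }, numeric(1))
}

# Electrons transferred on full oxidation to CO2/H2O (NH3 as nitrogen
# reference); spectator alkali/alkaline-earth cations contribute their charge,
# i.e. the organic anion carries the extra electrons.
.oxidation_electrons <- function(counts) {
  get0 <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  e <- 4 * get0("C") + get0("H") - 2 * get0("O") - 3 * get0("N")
  for (el in names(.cation_charge)) e <- e + .cation_charge[[el]] * get0(el)
  e
}

#' Theoretical chemical oxygen demand of a medium component
#'
#' Computes the oxygen demand of complete oxidation from the electron balance
#' of the formula (8 g O2 per mol of transferred electrons); for acetate this
#' is the familiar 2 mol O2 per mol of acetate, i.e. 64 mg COD per mmol.
#'
#' @inheritParams component_cmolarity
#' @return Theoretical COD, mg O2/L.
#' @examples
#' theoretical_cod("NaC2H3O2.3H2O", 860) # ~404.5 mg COD/L
#' @export
theoretical_cod <- function(formula, mass_mg_per_l) {
  stopifnot(is.numeric(mass_mg_per_l), all(mass_mg_per_l >= 0))
  vapply(seq_along(formula), function(i) {
    counts <- count_atoms(formula[[i]])
    c_atoms <- if ("C" %in% names(counts)) counts[["C"]] else 0
    e <- .oxidation_electrons(counts)
    if (c_atoms <= 0 || e <= 0) {
      stop("'", formula[[i]], "' has no defined oxidation stoichiometry ",
           "(not an organic carbon source)", call. = FALSE)
    }
    mm <- sum(counts * .atomic_masses[names(counts)])
    mmol <- mass_mg_per_l[[i]] / mm
    mmol * e * (2 * .atomic_masses[["O"]] / 4)
  }, numeric(1))
}

#' Influent phosphorus-to-carbon molar ratio
#'
#' @param tp Total orthophosphate, P-mmol/L.
#' @param hac Acetate carbon, C-mmol/L. Must be > 0.
#' @return P/C ratio, P-mol/C-mol, at full precision (round to 3 decimals for
#'   reporting, the convention used for influent schedules).
#' @examples
#' influent_pc_ratio(0.64, 12.6) # ~0.051
#' @export
influent_pc_ratio <- function(tp, hac) {
  stopifnot(is.numeric(tp), is.numeric(hac), all(tp >= 0))
  if (any(hac <= 0)) {
    stop("`hac` must be > 0 to form a P/C ratio (no carbon in influent)",
         call. = FALSE)
  }
  tp / hac
}

#' Reference SBR medium recipe
#'
#' The synthetic acetate medium used for PAO enrichment: per litre of diluted
#' influent, 860 mg sodium acetate trihydrate (carbon source), 107 mg NH4Cl,
#' 120 mg MgSO4.7H2O, 14 mg CaCl2.2H2O, 48 mg KCl, and sodium dihydrogen
#' phosphate monohydrate dosed to the requested orthophosphate molarity.
#' Trace elements and the nitrification inhibitor (ATU, 2 mg/L) are omitted:
#' they carry negligible C/N/P.
#'
#' @param phosphate_pmmol Influent orthophosphate, P-mmol/L (default 0.64, the
#'   enrichment condition).
#' @return A tibble with columns `formula`, `mass_mg_per_l`, `role`.
#' @examples
#' sbr_medium(0.96)
#' @export
sbr_medium <- function(phosphate_pmmol = 0.64) {
  stopifnot(is.numeric(phosphate_pmmol), length(phosphate_pmmol) == 1L,
            phosphate_pmmol >= 0)
  p_salt <- "NaH2PO4.H2O"
  tibble::tibble(
    formula = c("NaC2H3O2.3H2O", "NH4Cl", "MgSO4.7H2O", "CaCl2.2H2O", "KCl",
                p_salt),
    mass_mg_per_l = c(860, 107, 120, 14, 48,
                      phosphate_pmmol * molar_mass(p_salt)),
    role = c("carbon_source", "nitrogen_source", "mineral", "mineral",
             "mineral", "phosphorus_source")
  )
}

#' Influent phase schedule
#'
#' The six-phase influent orthophosphate schedule applied to the enrichment
#' culture (same medium throughout, only the phosphate dose changes). The
#' schedule spans influent P/C ratios of roughly 0.038-0.114 P-mol/C-mol at
#' 12.6 C-mmol/L of acetate carbon.
#'
#' @return A tibble with columns `phase` (0-5) and `tp_pmmol` (influent
#'   orthophosphate, P-mmol/L).
#' @examples
#' dplyr::mutate(influent_phases(),
#'               pc = influent_pc_ratio(tp_pmmol, 12.6))
#' @export
influent_phases <- function() {
  tibble::tibble(
    phase = 0:5,
    tp_pmmol = c(0.64, 0.48, 0.96, 1.44, 0.48, 0.64)
  )
}

#' Characterize an influent medium
#'
#' Converts a medium recipe (component masses per litre) into its molar
#' characterization: acetate carbon, theoretical COD, total phosphorus, total
#' ammonium nitrogen, and the influent P/C ratio.
#'
#' @param recipe A data frame with columns `formula` and `mass_mg_per_l`
#'   (extra columns are ignored), e.g. [sbr_medium()].
#' @param phosphate_pmmol Optional override of the influent orthophosphate,
#'   P-mmol/L; replaces the phosphorus source in the recipe (adding
#'   `NaH2PO4.H2O` if the recipe has none).
#' @return A one-row tibble: `hac_cmmol`, `cod_mg`, `tp_pmmol`, `tn_nmmol`,
#'   `pc_ratio`.
#' @examples
#' characterize_influent(sbr_medium(), phosphate_pmmol = 1.44)
#' @export
characterize_influent <- function(recipe, phosphate_pmmol = NULL) {
  stopifnot(is.data.frame(recipe),
            all(c("formula", "mass_mg_per_l") %in% names(recipe)))
  if (any(recipe$mass_mg_per_l < 0)) {
    stop("component masses must be >= 0", call. = FALSE)
  }
  if (!is.null(phosphate_pmmol)) {
    stopifnot(is.numeric(phosphate_pmmol), length(phosphate_pmmol) == 1L,
              phosphate_pmmol >= 0)
    has_p <- purrr::map_lgl(recipe$formula,
                            ~ "P" %in% names(count_atoms(.x)))
    recipe <- recipe[!has_p, , drop = FALSE]
    recipe <- dplyr::bind_rows(
      recipe,
      tibble::tibble(formula = "NaH2PO4.H2O",
                     mass_mg_per_l = phosphate_pmmol * molar_mass("NaH2PO4.H2O"))
    )
  }

  per_component <- purrr::map2(recipe$formula, recipe$mass_mg_per_l, function(f, m) {
    counts <- count_atoms(f)
    mm <- sum(counts * .atomic_masses[names(counts)])
    mmol <- m / mm
    get0 <- function(el) if (el %in% names(counts)) counts[[el]] else 0
    # COD only defined for organic carbon sources; ammonium N is the N pool.
    cod <- if (get0("C") > 0 && .oxidation_electrons(counts) > 0) {
      theoretical_cod(f, m)
    } else 0
    tibble::tibble(
      c_mmol = mmol * get0("C"),
      n_mmol = mmol * get0("N"),
      p_mmol = mmol * get0("P"),
      cod_mg = cod
    )
  })
  totals <- dplyr::summarise(dplyr::bind_rows(per_component),
                             dplyr::across(dplyr::everything(), sum))

  tibble::tibble(
    hac_cmmol = totals$c_mmol,
    cod_mg = totals$cod_mg,
    tp_pmmol = totals$p_mmol,
    tn_nmmol = totals$n_mmol,
    pc_ratio = if (totals$c_mmol > 0) totals$p_mmol / totals$c_mmol else NA_real_
  )
}
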