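---
title: "Methods: poly-P accounting, anaerobic cycle analysis and the metabolic shift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly-P accounting, anaerobic cycle analysis and the metabolic shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paoshift)
```

This vignette documents the models behind `paoshift`, the assumptions they
make, the tunable parameters and their defaults, and the design choices
taken where the methodology was genuinely open. The package targets
laboratory EBPR enrichment cultures of polyphosphate-accumulating organisms
(PAO) grown on acetate in sequencing batch reactors (SBR), where the
quantities of interest are the anaerobic kinetic rates, the stoichiometry of
the anaerobic conversions, and how both shift with the biomass
polyphosphate content.

## Influent chemistry

Medium recipes are given as component masses per litre. The formula parser
supports element counts (including fractional ones, for average elemental
compositions such as biomass CH~2.09~O~0.54~N~0.20~P~0.015~), one level of
parenthesised groups (for poly-P counterion units such as (PO~3~)~3~MgK) and
a single hydrate suffix; arbitrary nesting is rejected because no medium
component needs it and silent misparses are worse than errors. Atomic masses
are the conventional IUPAC standard atomic weights carried at three
decimals: two-decimal weights would shift simple checks (water at 18.015
g/mol) in the third decimal, while more digits buy nothing at the precision
of a medium recipe. All arithmetic is carried at full double precision;
rounding (2–3 significant figures, matching reporting conventions in this
field) happens only where a function's contract is explicitly a reported
ratio, and tests compare rounded values rather than forcing rounding into
the computation — this keeps properties such as exact linearity of
molarities in component mass true to machine precision.

Theoretical COD comes from the electron balance of complete oxidation
(8 g O~2~ per mol of transferred electrons; NH~3~ is the nitrogen
reference), with alkali and alkaline-earth counterions contributing their
charge so that organic anions carry the correct electron count: sodium
acetate yields the familiar 2 mol O~2~ per mol of acetate. The recipe
arithmetic gives 404.5 mg COD/L for 860 mg/L sodium acetate trihydrate;
reported values of ~405 reflect rounding at the mmol step.

## Poly-P by two independent routes

The ash route attributes inorganic suspended solids (ISS) in excess of a
non-EBPR baseline to poly-P:

$$\text{poly-P} = \Big(\mathrm{ISS} - \tfrac{f_{ISSb}}{1-f_{ISSb}}\,\mathrm{VSS}\Big)\, f_{P,ppISS}$$

with `f_issb_tss = 0.025` mg ISS/mg TSS (the ash ratio of poly-P-depleted
biomass) and `f_p_ppiss = 0.31` mg P/mg ISS, the phosphorus content of a
(PO~3~)~3~MgK repeating unit (recomputed from the formula: 0.309; the
parameter object enforces consistency within 0.005). The estimate is
clamped to zero and flagged when the ash ratio falls below the baseline —
such panels are legitimate (depleted cultures) and should not raise.

The mass-balance route assumes steady state, negligible effluent solids and
no chemical P precipitation:

$$\text{poly-P} = \tfrac{SRT}{HRT}(T_{P,in}-T_{P,eff})\,M_P - f_{P,bVSS}\,\mathrm{VSS}$$

with `f_p_bvss = 0.023` mg P/mg VSS, the P content of non-EBPR biomass.
Negative results are clamped and flagged rather than raised because
transient panels occur during start-up. `cross_validate_polyp()` compares
the two routes (relative discrepancy against the mean) and, on failure,
names the assumptions that are the usual culprits. No precipitation term is
modelled; whether `f_p_ppiss` should vary with the counterion mix is left
as a configuration constant, since no data constrain it.

## Biomass accounting

Active biomass is VSS minus the storage polymers (PHB, PHV, glycogen);
unbiodegradable endogenous residue is a no-op hook, negligible in highly
enriched cultures. C-mol conversions use monomer masses recomputed from
formulas: biomass 26.0 g/C-mol, PHB (C~4~H~6~O~2~) 21.5, PHV (C~5~H~8~O~2~)
20.0 — the PHA monomer formulas are standard polymer chemistry, configured
rather than measured. Glycogen deliberately uses the anhydroglucose unit
(27.02 g/C-mol), not free glucose (30 g/C-mol): the glucan is what the
assay hydrolyses, and the choice moves every glycogen ratio by ~11%, so it
is documented here and fixed package-wide. Ratios with zero denominators
are reported `NA` (undefined), never 0.

## Cycle-test analysis

Maximum rates are slopes of the initial linear segment of the anaerobic
concentration series divided by active biomass. The linear-window rule is
not uniquely fixed by practice in this field, so it is an explicit,
configurable policy (`window_policy()`): the longest initial window with
OLS R² ≥ 0.98 in which acetate stays above 10% of its initial value
(avoiding contamination of the zero-order regime by substrate limitation),
minimum three samples, ties broken toward the longer window. A flat series
is a perfect fit with slope zero. Endogenous (maintenance) P release is the
slope over the substrate-free window (acetate below 2% of initial);
glycogen consumption for maintenance is deliberately not estimated — its
magnitude sits below the resolution of routine glycogen assays.

Two conventions deserve emphasis:

- `qp_max` is the **gross** release rate during acetate uptake; the
  endogenous component `m_p` is reported separately, not subtracted.
- The P/HAc stoichiometry is the **ratio of the fitted release and uptake
  slopes** over the acetate-present window, which excludes the endogenous
  release that continues after exhaustion. Polymer ratios use begin/end
  anaerobic panel deltas (end values are the last anaerobic sample, not an
  extrapolation), with acetate uptake as the begin-to-end drop of the
  series. Negative polymer formation is flagged and reported as measured.

Rates are returned on both unit bases — per gVSS and per C-mol active
biomass — connected by `convert_rate_basis()` through the active-biomass
content of the solids.

## The metabolic shift

The shift between glycogen-dominated and poly-P-dominated anaerobic
metabolism is formalized two ways, deliberately avoiding a full biochemical
flux model (which would import many parameters this data cannot
constrain):

1. **ATP-source partition.**
   $\alpha = y_{pp}\,(P/HAc) \,/\, (y_{pp}\,(P/HAc) + y_{gly}\,(gly/HAc))$
   with `y_atp_polyp = 1.0` mol ATP/P-mol and `y_atp_gly = 0.5` mol
   ATP/C-mol. The glycogen yield depends on the glycolytic route (EMP vs
   ED), which is unresolved for these organisms; 0.5 is the conventional
   net value and is configurable. Maintenance ATP is excluded from α: it is
   measured in a different (substrate-free) regime and would mix two
   energy budgets.

2. **Two-end-member mixing model.** The observed stoichiometry is fitted as
   $\lambda\,s_{PAO} + (1-\lambda)\,s_{GAO}$ over the four ratios (P/HAc,
   gly/HAc, PHB/HAc, PHV/HAc), least squares with equal weights (a weight
   vector is exposed), closed form clipped to [0, 1]. The end members
   default to the two extreme conditions of the reference measurement set
   (`clade_iic_reference()`): a poly-P-depleted, glycogen-only culture and
   the highest-P culture. The fit is cross-checked in the test suite
   against an independent grid-search oracle. With the default end members
   gly/HAc never reaches zero for any λ — glycogen remains essential for
   reducing equivalents in every mix.

Carbon closure infers CO~2~/HAc from the carbon balance (flagged if
negative); electron closure evaluates the degree-of-reduction balance
(acetate and glycogen 4.0, PHB 4.5, PHV 4.8 e-eq/C-mol, recomputed from
the monomer formulas, never hard-coded). Measured stoichiometries do not
generally close — the depleted reference condition leaves ~1 e-eq per
C-mol HAc — so the residual is a reported diagnostic, not an error.

## The synthetic SBR generator

The generator exists to give every estimator a ground truth. It emulates a
2.5 L SBR with 1.25 L exchange, 6-h cycles (2.25 h anaerobic including
5-min sparge and 5-min feed, 2.25 h aerobic, 1.5 h settle) and SRT 8 d; the
12-h HRT is asserted to *emerge* from geometry, never set. The influent is
the built-in acetate medium with the six-phase phosphate schedule
(P/C 0.038–0.114 P-mol/C-mol).

Anaerobically, acetate uptake is zero-order at the configured
`qsa_max = 198` C-mmol/(C-mol·h) — the magnitude of the fastest reference
condition; profiles in cycle tests are linear, which is what zero-order
produces. (A Monod option with configurable K~s~ exists but is off by
default; substrate-limited regimes are plausible but unparameterized.) The
stoichiometry during uptake is the mixing model's prediction at the state's
current mix λ, which is tied to the poly-P/glycogen ratio r by the
saturating map λ = r/(r + 0.3): only the trend is known empirically, and
0.3 P-mol/C-mol is the observed optimum ratio, used as the half-saturation
anchor. If poly-P runs out mid-uptake the stoichiometry re-evaluates at
λ = 0 (the depletion experiment's phenotype); if glycogen runs out, uptake
stalls. Endogenous P release (`m_p = 2` P-mmol/(C-mol·h), a realistic
small value — no reference magnitude is fixed) operates only after
exhaustion, which is also where it is measured.

The aerobic phase is a balance closure, not mechanistic kinetics — only the
anaerobic analysis is in scope. PHA is consumed to (i) replenish glycogen
to a target `(0.55 − 0.30·λ)` C-mol per C-mol biomass (poly-P-poor
phenotypes hold more glycogen, giving the observed opposing trends of the
two reserves), (ii) grow biomass with net yield `y_growth = 0.70` on the
remaining PHA carbon, the balance going to CO~2~. Soluble P is taken up
first into organic biomass P and then into poly-P up to a capacity of
`polyp_max = 0.35` P-mol/C-mol; at the highest P loading this capacity
binds and an effluent ortho-P residual of ~0.2 P-mmol/L emerges. Wastage
removes the SRT-implied fraction of all particulate pools each cycle
(mixed-liquor wastage before settling); emitted end-of-aerobic panels are
pre-wastage, which is exactly the state the steady-state P balance
describes.

Two bookkeeping choices make the estimators exact on noiseless data, which
is what a ground-truth generator is for:

- ISS is reconstructed as baseline ash plus poly-P ash — the inverse of the
  ash-based estimator.
- Organically bound biomass P is carried as `f_p_bvss × VSS` (the same
  constant the mass-balance estimator subtracts) and is adjusted only at
  the aerobic closure, so the anaerobic ortho-P trace is driven purely by
  poly-P conversion and the steady-state balance closes exactly. The
  biomass composition formula (P~0.015~, ~0.018 mg P/mg) is used for molar
  mass only; carrying it as the P pool instead would make the VSS-based
  balance correction systematically wrong by design, obscuring real
  estimator error.

Measurement noise is multiplicative Gaussian truncated at zero
(default 2% relative SD per analyte), applied only to emitted profiles and
panels; the true state is exact, and a single seeded generator makes
fixture bundles byte-reproducible.

### What the generator does and does not emulate

It reproduces the statistical and mass-balance structure the analysis
assumes: linear anaerobic profiles, panel-based polymer deltas, SRT/HRT
steady-state relations, the monotone and reversible response of ash
fraction and storage ratios to influent P/C, and P/C conservation to 1e-9.
It does not emulate settling hydraulics, nitrification (suppressed by ATU
in the reference system), GAO invasion, pH or temperature effects, aerobic
kinetics, or community change — so passing recovery tests demonstrates the
estimators are correct and noise-robust, not that real cultures obey the
model. Aerobic closure coefficients (`y_growth`, glycogen targets,
`polyp_max`) are plausible configuration, not measured values.

## Validation problem sizes

The test suite and the acceptance script validate at desk scale, chosen so
the statistics are stable: six-phase trajectories run to a per-cycle
relative pool change below 1e-8 (about 2,700 cycles in total, under a
second of compute); noise-robustness statistics use 50 noise realizations
of a steady-state cycle test at 2% relative noise with 5-min sampling. At
those conditions the median recovery error is ~1% for the maximum rates
(tolerance 5%), the two poly-P routes agree to well under 1% noiselessly,
and the generating λ is recovered within ~0.03 (tolerance 0.05)
end-to-end. Maintenance-rate recovery is tested at 0.5% noise: the
endogenous slope is an order of magnitude smaller than the uptake-phase
signals, so at 2% analytical noise its single-cycle estimate scatters by
~15% — a realistic limitation of short maintenance windows, and the reason
prolonged tests would be needed for maintenance stoichiometry.

## Known limitations

- The stoichiometric λ-map and aerobic closure are phenomenological; the
  generator is an oracle for the estimators, not a predictive reactor
  model.
- The gly/PHB ratio is computed but has no reference value to compare
  against; it is excluded from validation.
- The mixing model assumes the end members span the observed behaviour;
  cultures with e.g. propionate feed or different clades need their own
  end members (both are plain arguments).
- Chemical P precipitation, cation co-transport stoichiometry and poly-P
  chain-length effects are out of scope throughout.
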