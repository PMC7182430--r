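---
title: "Periprotein lipidomics with smalpomics: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periprotein lipidomics with smalpomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smalpomics)
```

## The problem

Styrene–maleic-acid (SMA) polymers excise membrane proteins from their
native bilayer as ~9 nm discs (SMALPs) that retain the lipids
immediately surrounding the protein — the *periprotein lipidome*, one to
two concentric lipid shells, broader than the annular lipids in direct
transmembrane contact. Profiling those lipids by reversed-phase
HPLC-ESI-QToF yields feature tables in which genuine periprotein lipids
are buried among polymer background, solvent ions, inorganic salt
clusters and redundant detections of the same molecule (isotopologues,
alternate adducts, dimers). `smalpomics` implements the full desk-side
analysis: library-based identification, the filtering cascade,
quantification, domain-comparison statistics, and the membrane-geometry
estimates that connect lipid counts to protein conformational cycles.

## The theoretical library

Species are addressed as class plus X:Y — total acyl carbons and total
double bonds summed over chains, the resolution at which class-level
lipidomics reports. Neutral formulas derive from the phosphatidic-acid
backbone PA(c,d) = C(c+3)H(2c−2d+5)O8P by head-group addition; DAG and
cardiolipin have their own rules; IPC is modelled as a
tetra-hydroxylated phosphoinositol ceramide C(c+6)H(2c+12)NO13P and MIPC
as its mannoside (+C6H10O5). The IPC/MIPC hydroxylation state is an
inference from accurate mass alone — only the m/z of the detected ions
constrains it — and is exposed through the `hydroxyls` argument of
`species_formula()`. Likewise the cardiolipin acyl distribution is not
resolvable at this level; only the total composition (e.g. 68:4) enters
the formula.

Atomic masses are pinned in the package source (NIST most-abundant
isotopes); nothing is looked up at run time. One adduct per class is
documented for identification: the anionic classes as [M−H]⁻, the
zwitterionic PC and neutral DAG as [M+HCOO]⁻ (an ammonium-formate mobile
phase makes the formate ion the only negative-mode species for them),
ergosterol only as protonated [M+H]⁺. With these choices every printed
lead-ion mass for this chemistry is reproduced within 5 ppm, which is
also the default matching tolerance (`mz_tol_ppm = 5`; the observed
offsets between measured and theoretical lead ions span 0.2–4.3 ppm).

Default enumeration ranges: 26–44 carbons and 0–6 double bonds for the
diacyl classes (19 × 7 = 133 species per class); 60–76 carbons, 0–8
double bonds for the tetra-acyl cardiolipin; 40–46 carbons, saturated,
for IPC/MIPC. Ranges are configuration, not chemistry: widen them in
`library_config()` if your organism requires it.

### An unavoidable isobar

PC(c,d) [M+HCOO]⁻ and PS(c+3,d−1) [M−H]⁻ have *identical* ion
compositions, so no mass accuracy can separate them. `identify_species()`
therefore reports such events as `ambiguous`, listing every candidate
(ordered PC > PE > PS > PI > PG > PA > CL > DAG > IPC > MIPC, i.e.
descending typical abundance); resolving them requires retention-time
standards or CID fragmentation, both outside this package's scope by
design — it carries no fragment spectra. Tie detection uses a 0.01 ppm
window so that floating-point noise in two computation paths to the same
exact mass never decides an identification.

## The synthetic-data generator: a stated world

`simulate_experiment()` emulates the triplicate SMALP-versus-polymer
design: 3 sample and 3 control channels, a 20-minute gradient, and by
default 50 true species drawn with class weights mirroring the reported
periprotein composition (PC ~37%, PI ~19%, PE ~17%, PS ~15%, ergosterol
4%, minor PG/PA/CL/DAG and small IPC/MIPC fractions). Choices the
experiment record does not fix were made once, on typical-instrument
grounds, and are not tuned:

* **Replicate noise**: multiplicative log-normal, CV 10% — typical QToF
  peak-area scatter.
* **Enrichment**: each true species is 50–500-fold brighter in sample
  than control before noise, comfortably above the 10-fold decision
  threshold; background ions sit at sample/control ratios within
  [0.7, 1.4].
* **Retention**: linear in composition, RT ∝ offset(class) + 0.25·C −
  0.6·DB mapped into the gradient — the reversed-phase C18 trend;
  coefficients arbitrary but fixed.
* **Redundant forms**: M+1 isotopologues at +1.0033548 Da with the
  first-order ¹³C fraction 0.0108 × nC; a co-eluting formate adduct for
  the anionic classes; [2M−H]⁻ dimers for the brightest intensity
  decile; sodium-formate ladders (exact 67.98742 Da spacing, ≥3 ions,
  co-eluting) and solvent ions present in both channels.

What the generator does **not** model: chromatographic peak shapes, ion
suppression, M+2 and finer isotope structure, sodiated/potassiated
adducts, multiply charged ions, or missing values. A green recovery test
therefore establishes that the cascade's decision rules are implemented
correctly against their own stated world — not that the defaults are
optimal for any particular instrument.

Two consequences of this stated world are worth knowing. First, the
linear isotope fraction crosses the 0.6 collapse ceiling near nC ≈ 56,
so cardiolipin and the heaviest MIPC isotopologues are *not* merged —
they survive as a percent-level artifact floor (observed leakage ~1–2%,
within the ≤5% acceptance bound). Second, the linear mass-defect floor
(fractional mass < 0.00045·m/z) is meaningful only while true lipid
defects stay below 1 Da; beyond m/z ≈ 1450 a cardiolipin's defect wraps
past 1.0 and the rule can mis-censor it. Both behaviors follow from
pinned parameters and are documented rather than patched.

## The filtering cascade

Stages run in a fixed order — enrichment, censoring, isotope collapse,
adduct/dimer collapse — with an audit recording each population so the
log always mirrors the four-stage narrative of a real run
(input → enriched → censored → unique molecular events).

* **Enrichment** keeps a feature when mean(sample) / (mean(control) + 1)
  ≥ 10. The threshold is inclusive ("at least 10-fold"); the pseudo-count
  handles features absent from the control; replicate means are compared
  (whether each replicate had to pass individually is not recorded in the
  source protocol — means are the less brittle reading).
* **Censoring** applies within 250–1600 m/z (outside, features pass
  untouched): the mass-defect floor plus a salt-ladder detector. The
  ladder detector demands co-elution of chain members in addition to the
  spacing match — a salt-cluster family derives from one background
  species and elutes together, whereas true lipids coincidentally spaced
  ~67.99 Da apart elute according to their chain length. Without the RT
  gate, 5 ppm spacing matches at m/z > 800 start censoring genuine
  lipids.
* **Collapse** is greedy in descending mean intensity (ties to lower
  m/z), which makes the result independent of input row order; the test
  suite holds it equal to an exhaustive brute-force fixpoint merger on
  small instances. When adduct forms merge, the [M−H]⁻ ion is the
  canonical representative.

Defaults: `enrichment_fold = 10`, `pseudo_count = 1` intensity unit,
`mz_tol_ppm = 5`, `rt_tol_min = 0.1` (co-elution on a 20-min gradient),
`isotope_ratio_max = 0.6`, `defect_slope = 0.00045` per Da,
`salt_unit_masses = 67.98742`, `min_ladder_len = 3`. All are exposed in
`filter_config()`; the defect cutoff and solvent behavior of a specific
instrument are exactly the kind of thing to re-measure locally.

## Annotation

Homolog series are grouped by mass ladders k·14.015650 + j·2.015650
(k ≤ 10, |j| ≤ 6) with retention order required to be consistent with
the chain-length difference; connected components are the series. The
Kendrick transform KM = m/z × 14/14.015650 is provided for plotting —
CH2 homologs share a Kendrick mass defect exactly, and an H2 step shifts
it by 0.013399.

Identification is accurate-mass plus ionization mode only. A targeted
rescue mode (`targeted_search()`) scans features for user-supplied
target masses regardless of intensity filters, the equivalent of
manually examining ion chromatograms for low-intensity species such as
IPC and MIPC that automated peak picking can miss.

## Quantification

External curves are ordinary least squares of area on concentration,
*not* forced through the origin — a constant background belongs in the
intercept, and a fit with R² < 0.98 is flagged rather than rejected.
Standard addition fits the spiked response line and reports the
x-intercept magnitude (intercept/slope) with a first-order
error-propagated SE including the coefficient covariance; the estimate
is scale-invariant in the areas. Where both methods are run on the same
analyte, `conversion_factor()` carries the standard-addition calibration
onto external-curve results per class.

Sphingolipids have no synthetic standards, so IPC and MIPC are reported
strictly as peak-area ratios to ergosterol (the internal control),
never as mol%; `class_composition()` excludes `relative_only` species
from the mol% denominator. Domain comparisons use the pooled
equal-variance two-tailed Student's t (the named test; a Welch variant
is available via `welch = TRUE` since the equal-variance assumption was
not recorded), with the significance label `**` at p < 0.005.
Lipids-per-SMALP assumes 1:1 SMALP:protein stoichiometry and reports
the rounded integer ratio; injections are normalized to 1 µM input
protein by default (`protein_um`).

## Membrane geometry

`smalp_lipid_capacity()` estimates how many lipids one disc holds:
round((π(d/2 − rim)² − A_protein) · 2 / A_lipid) with defaults d = 9 nm,
rim = 1 nm, A_protein = 20 nm², A_lipid = 0.471 nm², giving 78 — inside
the predicted 60–120 stoichiometry envelope. Note an internal tension in
the source quantities: a 9 nm disc minus a 1 nm rim encloses 38.5 nm²,
not the "~50 nm²" quoted alongside; the package uses the formulaic
radius-minus-rim value. At the +1 nm diameter bound the same formula
gives 129, marginally past the envelope's 120 ceiling — the capacity is
an order-of-magnitude consistency device, not a measurement.

Leaflet cross-sections integrate an 80-wedge polar fan (θ = 4.5°): per
wedge the most distant in-plane atom sets rᵢ and the area is
Σ rᵢ² tan(θ/2). For a uniform circular footprint this overshoots πr² by
exactly (n/π)·tan(π/n) — 1.000514 at n = 80 — and converges to 1 as the
fan refines; the acceptance suite holds the implementation to that
analytic factor. Numerical choices, all config-exposed in
`geometry_params()`:

* **Slab half-width 2 Å** around each leaflet plane selects the atoms
  "at the water–membrane interface"; the alternative of projecting the
  whole transmembrane domain would inflate areas at kinked helices.
* **Atom centers without van-der-Waals radii**, matching a
  most-distant-atom construction.
* **Protein center = slab centroid per leaflet** by default; a fixed
  `center` can be supplied (and is what the single-atom degenerate case
  requires — with a centroid center a lone atom spans zero area).
* **Counts are rounded to integers**, as lipid counts are reported.

Leaflet planes come from OPM-style DUM pseudo-atom layers in the PDB
file, or explicit overrides (which win). Conformational lipid
displacement subtracts per-leaflet counts between two conformations
computed with identical parameters; applying it to a real transporter
pair requires OPM-positioned coordinates supplied by the user — no
structure accessions ship with the package.

## Known limitations

* Accurate-mass-only identification cannot split exact isobars (PC
  formate vs PS) nor sn-position or acyl-chain isomers; X:Y class sums
  are the ceiling of what it asserts.
* The mass-defect censor's linear floor degrades above m/z ≈ 1450
  (defect wrap), and the isotope-collapse ceiling of 0.6 leaves
  very-high-carbon isotopologues unmerged.
* Absolute quantification is only as good as the standards; sphingolipid
  results are relative by construction.
* The geometry module assumes the structure is already membrane-
  positioned; it does not position proteins in bilayers itself.
* Dataset-specific absolute ion counts from any particular instrument
  run (how many ions enter, survive enrichment, and collapse) depend on
  acquisition settings and cannot be predicted by the package; the audit
  structure, not its absolute values, is the tested contract.
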