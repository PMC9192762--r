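---
title: "Isotope-based trophic and nitrogen-source inference: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-based trophic and nitrogen-source inference: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthiso)
```

This vignette explains the models behind `benthiso`, the assumptions they
make, the tunable parameters, and the design decisions taken where the
methodology left room.

## The setting

Organic-rich diatom mud on an upwelling shelf hosts an oxygen minimum
zone (OMZ) with periodic hydrogen sulfide in the sediment. Three mollusc
taxa reach remarkable biomass there: a lucinid bivalve hosting
sulfur-oxidizing chemoautotrophic gill symbionts, a deposit-feeding
nuculanid bivalve, and a nassariid gastropod. The package implements the
inference chain used to ask, from per-mil isotope values alone: what do
these animals eat, and which inorganic nitrogen pool feeds the symbiosis?

All values are carried as decimal per-mil (δ) numbers versus PDB (carbon)
or atmospheric N₂ (nitrogen); nothing is ever converted to fractional
isotope ratios internally.

## Trophic position from amino acids

Glutamic acid (a "trophic" amino acid) is enriched by Δ_Glu−Phe = 7.6‰
per trophic transfer; phenylalanine (a "source" amino acid) is nearly
conserved, carrying the δ¹⁵N of the dietary baseline. `compute_tp()`
implements

$$\mathrm{TP} = 1 + \frac{\delta^{15}N_{Glu} - \delta^{15}N_{Phe} + \beta}{\Delta_{Glu-Phe}}$$

with β = 3.4‰. Both parameters live in `study_constants()` and can be
overridden by argument or YAML config; β and Δ are treated as exact in
the error budget because the reported uncertainty of such estimates is
attributed to analytical error in the two amino-acid determinations
only. `propagate_tp_se()` therefore uses first-order propagation,
√(sd²_Glu + sd²_Phe)/Δ, which at the typical 1.0‰ amino-acid precision
gives 0.186 TP — consistent with the conventional "at most 0.2 TP"
resolution of the method. Missing analytical SDs default to 1.0‰
(amino-acid) and 0.2‰ (bulk), the typical instrument precisions.

### Classification

Point anchors (1 = autotrophy, 2 = herbivory, 3 = first carnivory) and
open ranges (mixotrophy between 1 and 2, omnivory between 2 and 3) are
made total and deterministic with half-open intervals: [1, 2) mixotrophy
with exactly 1 = autotrophy, [2, 3) omnivory with exactly 2 = herbivory,
≥ 3 carnivory. Values below 1 have no meaning in the model; they are
reported as autotrophy with a warning (a 10⁻⁸ tolerance absorbs
floating-point dust from exact algebraic inversions). Mixotroph
sublabels mirror the nutritional extremes documented in kleptoplastic
gastropods: `mainly_autotrophy` for TP in [1.2, 1.4] (the "≈1.3"
starved-autotrophic phase) and `mainly_herbivory` for [1.8, 2.0) (the
"≈1.9" algivorous phase); the band widths are a package choice around
those anchors.

`estimate_tp()` defaults to estimating one TP per specimen and averaging
afterwards (`summary()`), because specimens are the independent units;
`method = "pooled"` instead averages the amino-acid values first and
computes one TP per group. Both are supported because reported group
means can be produced either way; the two differ only through
non-linearity of grouping, and for these data the equation is linear in
both amino acids so the difference is nil at equal weights.

## Nitrogen-source attribution

Each candidate inorganic nitrogen source is an interval pair: the source
pool's δ¹⁵N range and the fractionation range ε of the assimilation
process. The sign convention — stated once and applied everywhere — is
that positive ε depletes the product: biomass = source − ε, and excreted
ammonium = tissue − ε_excretion. `expected_pon_window()` is then exact
interval arithmetic:

$$[\delta_{min} - \varepsilon_{max},\; \delta_{max} - \varepsilon_{min}]$$

whose width is the sum of the two input widths (a tested identity, also
checked against a brute-force grid oracle).

The default end-members (`default_end_members()`):

* **dinitrogen**: degenerate interval [0.6, 0.6]‰, fixation ε ∈ [0, 2.5]‰,
  giving a window of (−1.9, 0.6)‰. The commonly quoted minimum of −2.1‰
  does not follow from these same inputs (0.6 − 2.5 = −1.9); the package
  computes −1.9 and treats the −2.1 figure as a data note.
* **pelagic nitrate** (upwelled central water): [5.7, 6.7]‰ with
  photoautotroph ε ∈ [4, 10]‰ → (−4.3, 2.7)‰.
* **benthic nitrate** (sediment-overlying water): [5.9, 14.3]‰ with
  prokaryote ε ∈ [0.4, 5]‰ → (0.9, 13.9)‰.
* **ammonium**: δ¹⁵N inherited unchanged from sediment PON
  (ammonification in organic-rich sediments fractionates negligibly;
  `ammonium_delta_from_sediment_pon()` is the identity), 4.3–5.6‰ across
  the study stations, with microbial assimilation ε ∈ [5, 20]‰ →
  (−15.7, 0.6)‰. The ε range is tied to ambient ammonium around 4 µM;
  concentration dependence of ε is not modelled.

`attribute_nitrogen_source()` compares the measured tissue mean ± k·SD
(default k = 1) against each window; closed intervals, touching counts
as overlap. The exclusion logic is qualitative in origin ("remains lower
than expected"), and one SD is the least-assumptive quantitative
reading; `k_sd` is exposed in the configuration for sensitivity
analysis. Note the logic is exclusion, not mixing — the package
deliberately provides no Bayesian mixing-model apportionment.

One honest caveat the verdict table makes visible: at the measured gill
value of −4.9 ± 0.7‰, the *pelagic*-nitrate window (−4.3, 2.7)‰ is
touched marginally by the upper end of the measurement interval. Its
exclusion as a symbiont nitrogen source rests on habitat — it is a
surface-water pool fuelling pelagic phytoplankton, not available to
chemoautotrophs in reducing sediment — rather than on isotopes alone.
The isotopic exclusions proper are dinitrogen and benthic nitrate.

### Ammonium recycling

`excreted_ammonium_delta()` applies δ_tissue − ε_excretion (2.7‰ by
default): a non-symbiotic tissue at −2.5‰ excretes ammonium at −5.2‰.
`recycling_consistency()` then checks |gill − excreted| ≤ tolerance,
because a closed recycling loop whose assimilation goes to completion
expresses no net fractionation. With the gill SD (0.7‰) as tolerance,
−4.9 vs −5.2 passes.

## Carbon-fixation discrimination

Dissolved CO₂ is isotopically lighter than the DIC pool by a
temperature-dependent equilibrium offset. The package adopts the
classical law for CO₂(aq) versus bicarbonate (the dominant DIC species
at seawater pH),

$$\varepsilon(T) = 24.12 - \frac{9866}{T_K},$$

because it reproduces the reference value of −10.8‰ at DIC −0.27‰ and
11.9 °C within display rounding. The law is a pluggable function
argument, so an alternative formulation can be configured. At the second
station (−0.37‰, 11.7 °C) this law gives −10.9‰ where −11.0‰ is
sometimes quoted; the exact equation and rounding behind that figure are
not recoverable, so only the −10.8 value is treated as an anchor.
Display rounding is half-away-from-zero at one decimal
(`display_permil()`), matching how isotope values are printed; internal
values are never rounded.

`apparent_discrimination_window()` reports discrimination as a positive
magnitude, δ¹³C_CO₂ − δ¹³C_biomass, enumerating *all* corner
combinations of the gill interval, the CO₂ interval and the 10–20‰
POC-versus-theory offset — cross-station pairings included, which is
what reproduces both printed bounds of the 28.0–40.0‰ window from gills
(−30.8, −29.0)‰ and CO₂ (−11.0, −10.8)‰. `enzyme_consistency()` ranks
candidate carboxylases by interval overlap with that window; with the
default RuBisCO ranges, form I (22–29‰) overlaps by 1.0‰ and form II
(17.8–23‰) not at all. DIC is treated as a single pool; full
carbonate-system speciation is out of scope.

## Closed-chamber fluxes

`net_rate()` implements blank-corrected, biomass-normalised net rates.
The flux equation's grouping is read as

$$P = \frac{\Delta C_{animal} - \Delta C_{blank}}{\Delta t} \cdot V,
\qquad \mathrm{rate} = P / \mathrm{AFDW}$$

using first-versus-last concentrations per vial. Endpoint differencing
is the default because nutrient concentrations in this protocol are
measured only at the end of the incubation against a blank; a
`"regression"` mode (difference of per-vial least-squares slopes) is
provided for continuously logged oxygen. Negative rates are net
consumption. Oxygen keeps ml units (ml h⁻¹ g⁻¹ AFDW); no µmol
conversion or temperature correction is applied, and no
respiratory-quotient modelling is attempted. A vial whose final oxygen
concentration is zero went anoxic: the rate is computed over the full
interval and flagged with a warning, since its magnitude is then a lower
bound.

Biomass conversion: wet weight from shell length uses the allometric
model W = a·L^b with user-supplied coefficients — none are shipped,
because the underlying length-weight models are laboratory-internal and
were never published. AFDW = factor × wet weight with the congeneric
proxy factors 0.091 (*Lucinoma*), 0.084 (*Ennucula* for *Lembulus*) and
0.081 (*Nassarius*), which `species_conversions()` records.

## The synthetic-data generator

The generators exist so every stage — and the pipeline end-to-end — can
be exercised under known truth:

* `gen_bulk_specimens()` draws Gaussian values around the study's group
  means and SDs (gill δ¹³C −29.8 ± 0.9, gill δ¹⁵N −4.9 ± 0.7, body
  −28.8 ± 0.8 and −2.5 ± 0.6, deposit feeder −16.7 ± 0.4 and 5.0 ± 0.3
  at n = 13, gastropod −17.5 ± 0.1 and 10.4 ± 0.4 at n = 6).
* `gen_aa_profiles()` inverts the TP equation: true Phe = baseline, true
  Glu = baseline − β + (TP_true − 1)·Δ, plus *independent* Gaussian
  noise on each amino acid. Independence matters: it makes the spread of
  estimated TPs match the propagated SE (√2/7.6 at 1.0‰ noise), which
  the tests verify, and noiseless profiles round-trip to the true TP
  exactly.
* `gen_incubation_series()` builds a drifting blank and an animal vial
  offset by the concentration change a true rate implies
  ((rate·AFDW/V)·t), with Gaussian measurement noise; concentrations are
  floored at zero with a warning, mirroring vials that go anoxic.
  Defaults emulate the study protocol: 20 ml vials, a 52 h horizon, and
  benthic-boundary-layer starting concentrations (nitrate 21.8 µM,
  ammonium 0.86 µM, oxygen 0.73 ml l⁻¹).

Gaussian noise is used throughout because the study conditions are given
as means ± SDs; no heavier-tailed model is justified by the available
information. What passing tests show is that the *estimators* recover
known truth under Gaussian sampling at the study's means, sample sizes
and precisions; they do not show robustness to features real data may
have (non-normal tails, within-individual correlation between amino
acids, nonlinear incubation kinetics near exhaustion, inter-vial volume
variation).

## Problem sizes, numerics, reproducibility

The test suite uses the study's own sample sizes for realism (n = 3–13
per group), n = 400 profiles for TP-recovery checks, 100 replicate
incubations for flux-recovery checks, 10⁴ draws for generator-mean
checks, and 50 random interval pairs against 10⁴-point brute-force grid
oracles for the window algebra — sizes chosen so each statistical check
has comfortable power while the whole suite stays quick. All generators
take an integer seed and are bit-reproducible under it. Interval
operations are exact floating-point arithmetic with no tolerance;
touching intervals count as overlapping by convention. Group summaries
use sample SD (n − 1) with SD = 0 for singletons — a convention, since
reported ± values of the form "± 0.4 (n = 13)" do not state whether they
are SD or SE; their scale is consistent with SD, which is what the
package assumes throughout.

## Known limitations

* Only the Glu/Phe pair is supported; multi-amino-acid TP estimators are
  out of scope.
* Source attribution is exclusion-based; it yields verdicts, not source
  proportions.
* The acidification correction (−0.3‰ on acidified bulk δ¹⁵N) is a
  single empirical offset from one mollusc group; the provenance flag
  prevents double correction but the offset itself is not
  species-specific.
* Sequencing-derived evidence (symbiont genome content) that corroborates
  the isotopic conclusions is entirely outside this package.
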