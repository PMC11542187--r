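---
title: "Screening nanocage gas sensors: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening nanocage gas sensors: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagesense)
library(dplyr)
```

`cagesense` evaluates fullerene-like X₁₂Y₁₂ nanocages — pristine or
modified with a transition metal — as gas sensors, from tabulated
electronic-structure results.  This vignette explains the models the
package implements, the conventions and numerical choices behind them,
what the synthetic-data generator does and does not emulate, and the known
limitations.

## Scope: post-processing, not electronic structure

Everything upstream of a table of numbers is out of scope: geometry
optimisation, DFT/TD-DFT single points, molecular dynamics and population
analysis belong to the quantum-chemistry code.  `cagesense` consumes one
row per (species, spin channel) — label, role, formula, total and Gibbs
energy, multiplicity, HOMO/LUMO levels, dipole, tagged partial charges —
plus a pairs table linking host, guest and complex with a counterpoise
(BSSE) term, and an optional list of TD-DFT transitions.  Energies are
carried in eV; hartree (×27.2114) and kJ/mol (÷96.485) are converted on
input when declared.

## Reactivity descriptors

Descriptors use the Koopmans-style frontier approximation throughout:
chemical potential $\mu = (E_H + E_L)/2$, hardness
$\eta = (E_L - E_H)/2$, electrophilicity $\omega = \mu^2/2\eta$ and work
function $\Phi = -\mu$.  No ΔSCF ionisation energies are used — the
derived tables of the reference dataset are reproducible from frontier
orbitals alone, which fixes this choice.  A degenerate frontier
($\eta = 0$) reports $\omega$ as `NA`, an explicit "undefined" sentinel,
so a metallic record never aborts a bulk screen.

Open-shell species carry `alpha` and `beta` channels; singlets carry one
`restricted` channel that stands for both spins.  When a host and its
complex share channels, the *reporting channel* is the one with the larger
relative gap change $|\Delta E_{gap}|/E_{gap}$ — the channel selection
rule used by `select_channel()` and applied inside every pair-level table.

## Sensing model

Transport is modelled by activated conduction,
$\sigma = A\,T^{3/2} e^{-E_{gap}/2k_BT}$, and thermionic emission by the
Richardson–Dushman law, $j = A\,T^2 e^{-\Phi/k_BT}$.  The reported
responses are relative changes of resistance and current density:

$$S = e^{|\Delta E_{gap}|/2k_BT} - 1, \qquad
  S_j = e^{|\Delta\Phi|/k_BT} - 1.$$

Three conventions deserve justification:

* **The “− 1”.**  $S$ is exactly $|R_{after}-R_{before}|/\min(R)$ under
  the conductivity law (a property the tests verify against a brute-force
  resistance oracle), so an unchanged gap gives $S = 0$, not 1.  The
  reference dataset's CO record — no work-function change, response
  printed as zero and selectivity as undefined — fixes this form.
* **Absolute exponents.**  Gap opening and closing (and Φ rising or
  falling) of equal size give equal response; the signed changes are kept
  on the adsorption report (`d_gap_signed`) so directionality is not lost.
* **Prefactor independence.**  $A$ cancels from every response and
  selectivity coefficient (asserted over six orders of magnitude in the
  tests).  The stored Richardson constant (120.1 A m⁻² K⁻²) follows the
  reference dataset even though the conventional value is 1.20×10⁶; it
  never reaches a reported metric, and absolute `conductivity()` /
  `current_density()` values are documented as prefactor-dependent.

Selectivity is $\kappa = S_{target}/S_{interferent}$ (likewise
$\kappa_j$); a zero interferent response yields the `NA` sentinel.
Recovery follows transition-state theory,
$\tau = \nu_0^{-1} e^{-E_{ads}/k_BT}$; `recovery_scan()` evaluates the
Arrhenius family over a temperature × attempt-frequency grid
(default 350–650 K).

**Parameters and defaults.**  T = 298.15 K (room temperature),
k_B = 8.62×10⁻⁵ eV/K, ν₀ = 5.2×10¹⁴ s⁻¹ — the attempt frequency
associated with yellow-light illumination, the only one stated with the
reference data.  Scans over other illumination bands require the caller to
supply those frequencies explicitly; the package draws no conclusions
about them.  All constants live in one `sensor_conditions()` object that
prints as a run header.

## UV–vis post-processing

Transitions are broadened with unit-area Gaussians *in energy space*
(line shapes are symmetric in eV, not nm), each line weighted by its
oscillator strength, then sampled on a wavelength grid (default 150–650 nm
at 0.5 nm — the window the reference spectra cover; default FWHM 0.33 eV,
a conventional TD-DFT visualisation width, since none is stated with the
data).  The energy-domain integral of the curve equals Σf independent of
the width, which the tests assert.  Peak shifts are signed λ_max
differences, positive toward longer wavelength; interpretation ("toward
blue") is left to the caller.

## The packaged reference dataset and its flags

`paper_fixtures()` returns the twelve pure/Cu-modified B₁₂N₁₂ and
Al₁₂N₁₂ hosts, cadaverine and eight interferents, all adsorption pairs,
and the published derived tables.  Two reconstruction decisions matter:

* **Orbitals from (gap, Φ).**  The published HOMO/LUMO values were rounded
  independently of the published gaps and work functions and disagree with
  them by up to one unit in the last digit (e.g. orbitals −4.78/−1.73
  alongside gap 3.04 and Φ 3.25).  Because the response model
  exponentiates $\Delta E_{gap}/2k_BT \approx 20\,\Delta E_{gap}$, a
  0.01 eV inconsistency changes $S$ by a factor ≈ 1.2.  The species
  records therefore reconstruct $E_H = -(\Phi + E_{gap}/2)$,
  $E_L = -(\Phi - E_{gap}/2)$ from the per-channel gap and work function —
  the quantities the derived tables are actually built from — while the
  literal published orbitals are kept, unchanged, in the `sensitivity`
  table for descriptor-level checks.
* **Synthetic anchors.**  Absolute total energies, Gibbs anchors, guest
  orbital levels and atomic reference energies were never published.  The
  dataset carries synthetic anchors (marked as such in file names and
  documentation) constructed so that every *difference* reproduces the
  published adsorption energies, Gibbs energies and cohesion energies
  exactly.

Rows whose printed derived values cannot be recomputed from their printed
inputs within one unit in the last printed digit carry a non-empty
`flag` and are excluded from exact checks but never dropped from reports:
four electrophilicities consistent with input rounding
(`omega_rounding`), one electrophilicity and one work-function modulation
inconsistent beyond any rounding explanation (`omega_inconsistent`,
`dphi_inconsistent`; suspected transcription errors), the COCl₂ complex
reported on a β channel whose host baseline is unavailable
(`baseline_unprinted`), and one transition energy that disagrees with
hc/λ (`energy_mismatch`).

## Numerical choices

* Energy differences below 10⁻⁹ eV are treated as exactly zero in the
  response functions: with 2-decimal tabulated inputs such residuals are
  floating-point cancellation noise, and snapping them preserves the exact
  zero-response/undefined-selectivity behaviour of an unchanged work
  function.
* `gap_sensitivity()` and `workfunction_modulation()` reject a
  non-positive baseline rather than reporting infinite sensitivity.
* Reported eV columns of the descriptor table round to 2 decimals for
  display; every computation runs at full precision.
* Ties in channel selection resolve to the first channel in storage order
  (`alpha` before `beta`), which only matters for exactly equal relative
  changes.

## The synthetic generator

`generate_campaign()` emulates the *statistical shape* of a screening
campaign, not quantum mechanics: host gaps uniform on 1.9–6.9 eV,
adsorption-induced gap and work-function shifts sampled symmetrically
(both signs, so the absolute-value conventions are exercised) with
magnitudes up to 1.2 and 0.8 eV, adsorption energies uniform on
−1.9 … −0.05 eV — all ranges mirroring the reference dataset.  Hosts
alternate restricted/open-shell so channel selection is exercised; every
metric is stored analytically from the sampled parameters as ground
truth.  A single seeded RNG (via `withr::with_seed`) threads all sampling;
identical seeds give identical campaigns.

At `noise_sd = 0` the pipeline recovers the stored truth to 10⁻¹⁰
relative — this validates the *plumbing* (joins, channel selection,
formula evaluation), and with Gaussian orbital noise the mean
gap-sensitivity error grows monotonically (asserted at 100 hosts over
several seeds).  What passing these tests does **not** show: anything
about real electronic structure — correlation between gap and Φ shifts,
basis-set or functional sensitivity, anharmonic recovery kinetics, or
device-level effects.

## Problem sizes

The shipped test suite runs the full reference screen (12 hosts, 9
analytes), synthetic campaigns up to 100 hosts × several seeds × three
noise levels, and spectral grids of 10³ points — sizes chosen so the
entire validation is a desk-scale computation reproducible in minutes on
one core.

## Known limitations

* Koopmans-level descriptors inherit the limitations of frontier-orbital
  theory; no ΔSCF or GW corrections.
* The conductivity and Richardson–Dushman laws are material-agnostic
  idealisations; real devices add contact resistance, film morphology and
  crystal-structure effects the model cannot see.
* BSSE corrections are inputs, not computed; no interaction-energy
  decomposition.
* The β-channel baseline of the reference host is unavailable, so the
  COCl₂ record cannot be reproduced, only flagged.
* UV–vis broadening is phenomenological: no vibronic structure, solvent
  shifts or intensity borrowing.
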