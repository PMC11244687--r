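---
title: "The tg51mc uncertainty model: chains, budgets and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tg51mc uncertainty model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tg51mc)
```

## The measurement model

TG-51 turns an ionization chamber reading into absorbed dose to water through
a product of corrections and conversion factors,

$$D_w^Q \;=\; M_{raw}\,P_{TP}\,P_{ion}\,P_{pol}\,P_{elec}\; k_Q\; N_{D,w},$$

with $k_Q \to k'_{R50}\,k_{ecal}$ for electron beams. `tg51mc` treats each
quantity a physicist sets or reads — SSD, chamber depth, field size, water
temperature, pressure, the beam-quality specifier, every charge reading,
every tabulated factor — as a random variable with a declared sampling law,
replays the complete worksheet once per Monte Carlo iteration, and reports
the distribution of the relative dose $D_i / D_{nominal}$. Because only the
ratio is reported, all absolute scales (monitor units, electrometer gain,
the numeric values of $N_{D,w}$ and $k_{ecal}$) cancel identically; what
survives is exactly the propagated uncertainty.

Two features make the simulation preferable to first-order quadrature here:

* **Correlation.** One set-up (depth, SSD, field size) feeds *all four*
  charge readings of an iteration ($M_{raw}$, $M^+$, $M_H$, $M_L$), so
  $P_{ion}$ and $P_{pol}$ are not independent of $M_{raw}$. In the electron
  chain a single R50 draw both displaces the reference depth and perturbs
  $k'_{R50}$; the two pathways partially cancel, and the simulation keeps
  that cancellation (a property test asserts the combined spread is below
  either pathway's independent quadrature).
* **Nonlinearity and constraints.** The two-voltage recombination value is
  $P_{ion} = -1/(M_H/M_L - 2)$ and is physically clamped at 1.000, which
  piles a point mass at exactly 1 whose weight the simulation reproduces
  (checked against the analytic normal tail). $R50$ enters $k'_{R50}$
  through an exponential.

For near-linear sub-chains the Gaussian quadrature oracle
(`quadrature_total()` of the per-source contributions) must agree with the
Monte Carlo total, and the test suite asserts that it does — this is the
internal consistency check between the two propagation methods.

## Sampling laws and random streams

Each source is either an untruncated normal or a bounded uniform; a uniform
with half width $a$ has $\sigma = a/\sqrt 3$, and draws never exceed the
bounds (instrument specifications are read as hard limits). Temperature is
the sum of a Type A normal (0.25 °C, repeated thermometer comparisons) and a
Type B uniform (σ 0.23 °C, from the ±0.4 °C manufacturer specification).

Every source draws from its own stream, seeded from the run seed plus a text
label (`"photon/pressure"`, `"photon/repeatability/2"`, ...). Consequences
worth having: identical `(seed, label)` pairs are bit-identical; adding,
removing or zeroing a source never perturbs any other source's draws (so
contribution runs decompose the *same* run, and regression tests are
stable); and in a sensitivity sweep the swept source's draws scale
continuously with the half width, giving smooth, exactly coupled curves.
Repeatability uses three sub-streams, one per charge reading, because repeat
scatter is independent across readings while the set-up error is shared.

## The default budgets

`default_budget()` encodes the study conditions: a careful clinical user,
standard instrumentation, mechanical QA already within tolerance. The
user-controlled rows (SSD, depths, temperature, pressure, field size, I50)
are the quantities a user could improve; the rest (calibration factors,
formula accuracies, stability, repeatability, extracameral current,
humidity) are not realistically improvable. `zero_sources(budget)` gives the
corresponding uncertainty floor. All values are in the source's natural
unit: cm for lengths, mbar for pressure, °C for temperature, relative
fractions for everything dimensionless; the loader refuses a physical
source without a declared unit.

One budget entry deserves its own paragraph. The two-voltage *formula* error
is represented as a **normal with σ = 0.002, clamped with
$P_{ion} \ge 1$**, not as the uniform ±0.002 that the formula-accuracy bound
might suggest. The published budget tables state the normal law, and only
the normal reproduces both the tabulated contribution of this row (≈ 0.18 %:
a normal censored 1.5 σ below its 1.003 nominal keeps ≈ 94 % of its σ) and
the quoted total σ(P_ion) ≈ 0.2 %; with the uniform reading the same
pipeline yields ≈ 0.13 %. We follow the tables and document the sensitivity:
the clamp weight, and hence this row, moves with the configurable
`P_ion_nominal` (default 1.003, a typical Farmer value — the protocol only
constrains $1.00 \le P_{ion} < 1.05$). First-order theory is also exposed
directly: `pion_first_order_sigma(0.0023)` gives the 0.33 % that equal
independent 0.23 % reading uncertainties imply — notably larger than
budget-table treatments that assign 0.1 % to this correction.

## Beam models and sensitivity coefficients

**Photons.** %dd(10) responds linearly to set-up errors with coefficients
(per cm) −0.032 for depth (the depth-of-maximum error is taken equal to the
reference-depth error), 0.0015 for SSD and 0.010 for field size; these are
the 6 MV defaults and can be refitted from any depth-dose curve
(`fit_photon_coefficients()`). The Farmer *reading* at 10 cm keeps the full
inverse-square terms that cancel in the scan ratio: its depth coefficient is
$-0.032 - 2/(SSD+d_m) \approx -0.0517\ \mathrm{cm^{-1}}$ and its SSD
coefficient $-2/(SSD+d) \approx -0.0182\ \mathrm{cm^{-1}}$. This split —
scan curve versus measurement — uses *independent* depth draws (different
chamber, different set-up), while SSD and field-size draws are shared within
an iteration. The field-size response of the reading reuses the scan value
(no separate head-scatter term is available to fit); off-axis and gantry
effects are taken as exactly 1 for flattened beams. Above 10 MV the interim
formula with its uniform ±2 percentage-point error maps %dd(10) to %dd(10)x;
the 18 MV scenario also raises the intrinsic $k_Q$ σ to 0.45 %. No 18 MV
response coefficients are published, so the 18 MV manifest reuses the 6 MV
values — an approximation that matters little because the depth pathway
contributes a few hundredths of a percent to $k_Q$.

**Electrons.** $R50 = 1.029\,I50 - 0.06$, $d_{ref} = 0.6\,R50 - 0.1$. The
sign convention is literal: an iteration that *overestimates* R50 intends a
deeper $d_{ref}$, so the chamber ends up effectively shallow by
$0.6\,(R50_i - R50_{nom})$, on top of the depth-setting error. Displacement
becomes a reading error through the local relative gradient of the shifted
depth-ionization curve, obtained by least-squares cubic fit on a ±0.8 cm
window and analytic differentiation (on an exact cubic this recovers the
derivative to machine precision; a flat curve gives exactly zero, so with a
zero gradient the depth source cannot move the dose at all — also a test).
The gradient is evaluated at $d_{ref}$, where the curve-derivative term is
defined; the charge itself is modelled as measured once at
$d_{ref} + 0.5\,r_{cav}$, which makes the gradient correction $P_{gr}$
cancel exactly and is why no $P_{gr}$ source exists in the model. The SSD
response is −0.02 cm⁻¹ through the virtual source distance. Nominal I50
values are not part of the published record; the manifests use 2.40 cm
(6 MeV-like) and 7.50 cm (18 MeV-like), both configurable.

## Synthetic curves: what they are and are not

`synth_curves()` exists so that every test and the acceptance script run
with no external data. Photon profiles are inverse-square × exponential
attenuation (with a quadratic-in-depth exponent) solved so the curve passes
through the nominal %dd(10) *and* its fitted depth coefficient equals
−0.032 cm⁻¹; electron profiles are single-Gaussian fall-offs whose two
parameters are calibrated by a deterministic Nelder-Mead at generation time
so the curve's I50 and its *fitted* gradient at $d_{ref}$ (−0.08 cm⁻¹ for
6 MeV-like, −0.04 for 18 MeV-like, the published factor-of-two energy drop)
hit their targets exactly as the chain will consume them. These are
emulators of local properties, not beam transport: build-up regions,
bremsstrahlung tails, surface dose and profile shape are schematic. Passing
tests therefore validate the *propagation machinery* under the stated local
sensitivities; they do not validate a beam model against measured data. A
clinic's own curves enter through `read_di_curve()` (CSV,
`depth_cm,value`) and replace nothing else in the pipeline.

## Numerical choices and degenerate inputs

* Zero-sigma sources return their center exactly; an all-zero budget returns
  every $D_i = 1$ bit-exactly.
* $P_{ion} < 1$ clamps to 1 and is counted; $P_{ion} > 1.05$ (protocol
  forbids the chamber) is counted but *not* altered; %dd(10)x outside the
  $k_Q$ fit validity (63, 86) and R50 outside [2, 9] cm are likewise
  flagged, never discarded — discarding would bias the tails.
* $M_H/M_L = 2$ is a hard singularity of the two-voltage formula and errors.
* The expanded interval is defined as exactly $2\sigma$ (the conventional
  k = 2 arithmetic); the 1.96 σ value and the empirical 2.5–97.5 percentile
  half width are reported alongside for comparison.
* The cubic-fit window needs ≥ 4 points; the generator grids use 0.05 cm
  steps so defaults have ~30.
* Uniform specs may be given by σ or half width; supplying both requires
  consistency to within rounding (1e-9), which protects YAML round-trips.

## Problem sizes

The chains are fully vectorised; one $10^6$-iteration run takes on the order
of a second, and all four scenario runs at $10^6$ complete within the
30-second budget asserted in the test suite. Unit tests use $5\times10^4$ to
$5\times10^5$ iterations (Monte Carlo standard error of a ~1.2 % σ at
$n = 4\times10^5$ is ~0.0013 percentage points, far below the tolerances
tested); the acceptance script uses $10^6$ throughout, where repeat
computations are stable in the leading two significant digits.

## Known limitations

* FFF beams (profile-gradient and lateral-offset terms), plane-parallel
  chambers, cross-calibration transfer and other protocols (TRS-398,
  DIN 6800-2) are out of scope.
* Only random uncertainties are modelled: systematic effects (e.g. the
  alternative 0.38 $r_{cav}$ effective-point shift, lead-foil %dd(10)
  measurement, erroneous procedure) are not sampled; the model assumes
  mechanical QA left no out-of-tolerance systematic error.
* The electron "formula for R50" row propagates its stated 0.023 cm σ
  through the implemented pathways (d_ref displacement and $k'_{R50}$) and
  lands near 0.09 %; published budget tables list 0.27 % for this row
  without a derivation that this pipeline reproduces. The package reports
  the computed value rather than forcing agreement.
* Humidity is a flat multiplicative ±0.15 % band; no physical humidity
  model is attempted.
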