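---
title: "From PAMPA plate to skin permeability: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From PAMPA plate to skin permeability: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinpampa)
```

## The assay and what is computed from it

A skin-PAMPA sandwich is a donor well (volume $V_D$), an acceptor well
($V_A$), and a filter-supported artificial lipid membrane between them
(here modelled after the 70% silicone oil / 30% isopropyl myristate
membrane used for stratum-corneum mimicry). A compound is dosed into the
donor at nominal concentration $C_D(0)$ and, after incubation time $t$,
HPLC measures three concentrations per well: the time-zero donor
reference, the residual donor concentration $C_D(t)$, and the transferred
acceptor concentration $C_A(t)$. Quantitation is single-point: each
concentration is the nominal donor concentration scaled by the ratio of
its peak area to the time-zero peak area. Because donor and acceptor
share one analyte and one chromatographic method, the response factor
cancels in the ratio and no calibration curve is needed.

Three derived quantities summarise a well:

* the **retention factor**
  $R = 1 - \dfrac{C_D(t)}{C_D(0)} - \dfrac{V_A}{V_D}\dfrac{C_A(t)}{C_D(0)}$,
  the mole fraction trapped in the membrane, filter and plate materials;
* the **permeation parameter** $p = C_A(t)/C_D(0)$, the fraction of the
  dose that crossed; and
* the **effective permeability coefficient** $P_e$ (cm/s), obtained by
  inverting the two-compartment first-order transport model below.

Predicted human skin permeability is then
$\log K_p = 1.34\,\log P_e + 0.28$ (standard errors 0.12 and 0.56), a
published regression over 31 reference compounds that this package treats
as a fixed constant of the method — its training data are not available
here and the line is never refitted.

## The two-compartment transport model

After a lag time $\tau_{\mathrm{LAG}}$ — the time for the transmembrane
gradient to stabilise, about 20 min for unstirred plates — acceptor
accumulation follows first-order relaxation towards the equilibrium
partition of the *unretained* material:

$$C_A(t) = C_{eq}\left(1 - e^{-k\,(t-\tau_{\mathrm{LAG}})}\right),
\qquad
C_{eq} = (1-R)\,C_D(0)\,\frac{V_D}{V_A+V_D},
\qquad
k = P_e A_{\mathrm{eff}}\left(\frac{1}{V_A}+\frac{1}{V_D}\right),$$

with $A_{\mathrm{eff}} = A_{\mathrm{filter}} \times \mathrm{porosity}$
and the donor following from exact mass balance. Retention is modelled as
an instantaneous mole-fraction sink at the lag boundary, not as a third
kinetic compartment: the reduction formulas treat $R$ as a static
correction to the equilibrium concentration, and a kinetic membrane
compartment would introduce parameters that endpoint-only plate data
cannot constrain.

Solving for $P_e$ at the incubation endpoint, with
$t' = t - \tau_{\mathrm{LAG}}$:

$$P_e = -\frac{V_A V_D}{(V_A+V_D)\,A_{\mathrm{eff}}\,t'}
\ln\!\left(1 - \frac{V_A+V_D}{(1-R)\,V_D}\,p\right)$$

This is `volume_mode = "actual"`, the package default, and it is the
exact inverse of the simulator's forward model — which is why the
noise-free round trip recovers $(P_e, R)$ to machine precision and is
tested at $10^{-9}$ relative error over a grid of
$P_e \in [10^{-7}, 10^{-4}]$ cm/s $\times$ $R \in [0, 0.9]$.
`volume_mode = "equal"` is the form usually quoted in the assay
literature, $P_e = -\frac{V}{2 A_{\mathrm{eff}} t'}\ln(1 - 2p/(1-R))$
with $V = V_D$; it coincides with `"actual"` when $V_A = V_D$ (bitwise,
by construction) but is only approximate for the default 400/300 µL
sandwich. We default to the exact unequal-volume inversion because it is
the defensible physics, and keep `"equal"` for fidelity comparisons
against values computed under that convention.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `V_D`, `V_A` | 0.3, 0.4 | cm³ | donor / acceptor well volumes |
| `A_filter` | 0.28 | cm² | filter area |
| `porosity` | 0.7 | — | nominal filter porosity; multiplies the area |
| `t_incubation` | 25200 | s | 7 h incubation |
| `tau_lag` | 1200 | s | steady-state lag (≈20 min, unstirred) |
| `C_D0_nominal` | 1e-7 | mol·cm⁻³ | 100 µM donor solution |
| `slope`, `intercept` | 1.34, 0.28 | — / log₁₀ | skin-permeability regression |
| thresholds | 0.30, 0.30 | — | retention / permeation group cut |

The lag time is a single global constant: endpoint plate data contain no
per-compound lag information, so estimating it per compound is not
identifiable. Internally everything is cm/cm³/s/mol·cm⁻³; percentages
exist only in the reporting layer, which also renders a mean retention
below 1% as `"<1"` (the below-detection convention of the source table)
while retaining the numeric value alongside.

## Classification

Compounds are classified on the triplicate means (one point per
compound) by the retention/permeation relationship: both below 30% is
group I; low retention with permeation ≥ 30% is group II; retention ≥
30% with low permeation is group III, where the membrane acts as a trap
— the profile of interest for topically acting prodrugs. Values exactly
at a threshold count as "high". Two deliberate choices:

* **log Kp plays no part in assignment.** The −6 log Kp cutoff discussed
  alongside the groups would misplace compounds (e.g. a strongly
  retained ester with predicted log Kp = −7.33 belongs to group III by
  its retention/permeation profile); the predicted log Kp is reported as
  an annotation instead.
* **The high-retention/high-permeation cell is labelled `UNDEFINED`.**
  The taxonomy has no such group; the package never silently forces a
  compound into one.

On the packaged 26-compound corticosteroid panel this rule yields 12
group III esters and exactly one group III standard, and the group III
ester set is invariant to any retention threshold inside (0.173, 0.324)
because no ester mean retention falls in that band — both facts are
asserted in the test suite.

## The synthetic-data generator

`simulate_plate()` emulates the study conditions: 100 µM donor in the
300/400 µL sandwich, 0.28 cm² filter at 70% porosity, 7 h incubation
with a 20 min lag, triplicate wells, compound-specific retention, and
HPLC measurement read-out. Noise is multiplicative Gaussian on peak
areas, `area = response_factor · C · (1 + ε)` with `ε ~ N(0, cv)`
truncated at zero — area error scales with signal, and this is the
simplest model consistent with time-zero-ratio quantitation. The default
CV of 2% is a synthetic assumption representative of HPLC peak-area
repeatability; no experimentally derived value exists for this assay.
One pseudo-random stream per plate, drawn in row-major measurement
order, makes every table reproducible from its seed.

What the generator does **not** emulate — and hence what passing tests
do not certify about real plates: DMSO-cosolvent effects, ionisation/pH
gradients, unstirred-water-layer physics, evaporation, inter-well
crosstalk, chromatographic interferences, and any kinetic structure in
membrane retention. Round-trip recovery shows the *reduction* is exact
for the assumed transport model, not that the model captures every real
membrane.

Under the simulated conditions (2% CV, n = 3) the log Pe estimator's
bias at $P_e = 2\times10^{-5}$ cm/s, $R = 0.4$ stays below 0.05 log
units over 1000 simulated plates; the acceptance test computes this as
one seeded 1000-compound plate (statistically identical to 1000
single-compound plates and a single vectorised pass).

## Numerical conventions and degenerate inputs

* **Clamping.** Measurement noise can push the raw retention balance
  slightly outside $[0,1]$. Raw values within 0.05 of the interval are
  clamped and flagged; anything further out errors, since the
  concentration triplet is then internally inconsistent. Sub-$10^{-12}$
  excursions are treated as floating-point roundoff and clipped without
  a flag.
* **Equilibrium wells.** When $p \ge (1-R)V_D/(V_A+V_D)$ the log
  argument is ≤ 0 and $P_e$ is unidentifiable at this incubation time;
  such wells get a flagged `NA` (a warning, not an error) so a whole
  plate is never aborted by one saturated well. They are excluded from
  log Pe statistics but still counted and still contribute to the
  retention/permeation means.
* **Log-domain averaging.** Replicate permeabilities are averaged as
  log₁₀ Pe with sample SD (n−1), matching how the assay's results are
  reported (`log Pe ± sd`); log Kp is predicted from the mean log Pe.
  SDs are reported as `NA` below two usable replicates. The packaged
  reference table's `±` spreads are labelled SD; whether the source
  reported SD or SEM is not stated, and the package documents SD as its
  assumption.
* **Reporting rounding.** Printed log Kp values use half-up rounding to
  two decimals (`round_half_up()`), not banker's rounding — the raw
  regression output can differ from the printed value in the third
  decimal.
* **Below-detection retention.** Reference-panel entries printed `"<1"`
  carry `below_detection_R = TRUE` and the numeric stand-in 0.005
  (midpoint of the censoring interval $[0, 1)\%$) for computations that
  need a number; the flag is preserved through reporting.

## Scope and limitations

The packaged reference panel's measured columns (R, permeation, log Pe)
are wet-lab inputs, not outputs this package can re-derive: its log Pe
values cannot be regenerated from the printed mean R and permeation
columns under any single volume-mode/lag choice, presumably because they
were computed per well and averaged afterwards from unpublished per-well
data. The package therefore treats those columns as fixtures and
reproduces only what is downstream of them (log Kp prediction, group
classification, censuses). Problem sizes throughout the tests — a 10×10
recovery grid, a 1000-plate bias study, 26-compound panels — run in
seconds on a single CPU. The regression's uncertainty (slope ± 0.12,
intercept ± 0.56) is carried but not propagated into prediction
intervals; iso-pH passive diffusion is assumed throughout, so actively
transported or ionisation-sensitive compounds are out of scope.
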