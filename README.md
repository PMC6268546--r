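# skinpampa

Plate reduction and skin-permeability prediction for the PAMPA assay
(Parallel Artificial Membrane Permeability Assay), aimed at medicinal
chemists screening topically acting compounds — e.g. corticosteroid C-21
ester prodrugs — on a silicone oil / isopropyl myristate membrane that
mimics the stratum corneum.

From per-well HPLC measurements of a PAMPA sandwich (donor volume `V_D`,
acceptor volume `V_A`, filter area `A` at nominal porosity, incubation
time `t`, lag time `τ_LAG`), the package computes per replicate:

* the **membrane retention factor**
  `R = 1 − C_D(t)/C_D(0) − (V_A/V_D)·C_A(t)/C_D(0)` — the mole fraction
  trapped in membrane and plate materials;
* the **permeation parameter** `p = C_A(t)/C_D(0)`;
* the **effective permeability coefficient** (cm/s), by exact inversion
  of the two-compartment first-order transport model,
  `Pe = −[V_A·V_D/((V_A+V_D)·A_eff·t′)] · ln(1 − (V_A+V_D)/((1−R)·V_D)·p)`
  with `A_eff = A·porosity` and `t′ = t − τ_LAG` (the commonly quoted
  equal-volume form is available as `volume_mode = "equal"`);
* the predicted **human skin permeability**
  `log Kp = (1.34 ± 0.12)·log Pe + (0.28 ± 0.56)`.

Replicates are aggregated (log-domain means ± SD for log Pe) and each
compound is classified by its retention/permeation profile into permeate
**group I** (both < 30%), **group II** (low retention, permeation ≥ 30%)
or **group III** (retention ≥ 30%, low permeation — the membrane as a
trap, the profile sought in topical prodrugs). A two-compartment kinetic
simulator with lag time, instantaneous membrane retention and
multiplicative HPLC peak-area noise generates synthetic plates from
known ground truth, so the whole pipeline is testable without wet-lab
data; a 26-compound corticosteroid reference panel ships as a fixture.

## Worked example

Simulate a noisy triplicate plate for a strongly retained permeant and a
weakly permeating one, analyse it, and predict skin permeability:

```r
library(skinpampa)
plate <- simulate_plate(c("MF-like", "H-like"), Pe = c(7.9e-5, 5.9e-7),
                        R = c(0.81, 0.015), noise_cv = 0.02, seed = 7)
csv <- tempfile(fileext = ".csv"); write.csv(plate, csv, row.names = FALSE)
fit <- pampa(read_plate_table(csv, mode = "areas"))
fit
#> PAMPA permeability fit (volume mode: actual)
#>   2 compound(s), 6 well(s)
#>  compound n    R% perm% logPe logKp group
#>   MF-like 3 81.60 7.020 -4.10 -5.21   III
#>    H-like 3  4.74 0.675 -6.22 -8.05     I
predict(fit, rounded = TRUE)
#> MF-like  H-like
#>   -5.21   -8.05
```

The fit recovered the simulated truth through 2% measurement noise: the
"MF-like" compound shows 81.6% membrane retention with only 7% of the
dose permeating (group III — retained by the membrane, slowly released),
a log Pe of −4.10 and hence a predicted human-skin log Kp of −5.21; the
"H-like" compound permeates and retains almost nothing (group I) with
log Kp ≈ −8.05, five hundred times less skin-permeable. `summary()`,
`coef()`, `residuals()`, `simulate()` and `plot()` (a retention ×
permeation group map) give the other standard views of a fit.

The packaged reference panel works the same way downstream:

```r
tab <- table1_fixture()
subset(tab, compound == "MF",
       select = c(compound, R_pct, perm_pct, logPe, logKp_2dp, group))
#>    compound R_pct perm_pct logPe logKp_2dp group
#> 26       MF    81      7.7  -4.1     -5.21   III
summarize_groups(tab, tab$compound[tab$role == "ester"])
#>       group  n R_min R_max perm_min perm_max
#> 1         I  4 0.005 0.172    0.149    0.238
#> 2        II  4 0.005 0.135    0.316    0.381
#> 3       III 12 0.324 0.865    0.013    0.271
#> 4 UNDEFINED  0    NA    NA       NA       NA
```

Twelve of the twenty esters land in group III, with retention spanning
32.4–86.5% and permeation 1.3–27.1%.

A thin command-line wrapper covers batch use
(`simulate | analyze | classify | report`, plain CSV in and out, a JSON
run manifest next to every result):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pampa.R",package="skinpampa"))')" \
    analyze plate.csv --mode areas --out results/
```

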