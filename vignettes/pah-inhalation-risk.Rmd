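---
title: "Bioaccessibility-adjusted inhalation risk assessment of particle-bound PAHs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioaccessibility-adjusted inhalation risk assessment of particle-bound PAHs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahlung)
```

## The problem

When a PAH-laden particle is inhaled, only the fraction of the PAH that
desorbs into lung fluid is available for uptake. Carbonaceous sorbents
bind PAHs strongly: for biochar fine particles the bioaccessible
fraction of phenanthrene and pyrene stays below about 3% in Gamble's
solution (extracellular, near-neutral) and artificial lysosomal fluid
(intracellular, acidic), and for urban PM2.5 the 16 US-EPA priority
PAHs release roughly 2-40% in simulated epithelial lung fluid.
A risk model that assumes complete dissolution therefore overstates the
inhaled dose by the reciprocal of that fraction. `pahlung` runs the two
standard inhalation risk models in both conventions - total
concentration (`F_bioa = 1`) and measured bioaccessibility - so the
difference in verdict is explicit.

## Models and assumptions

**Bioaccessible fraction.** `F_bioa` is defined as the *total extent of
desorption*: the final (maximal) cumulative released mass over the total
particle-bound mass. No kinetic asymptote is fitted -
`fbioa_from_series()` simply takes the series maximum. This is a
deliberate design choice: an asymptote extrapolates beyond the
measurement, while the total extent is directly observed; a
fitted-asymptote mode is out of scope. Series whose cumulative release
momentarily decreases are rejected as inconsistent rather than
monotonized, because a decrease signals a measurement artefact that
should be surfaced, not smoothed over.

**Daily intake against acceptable daily intake.** For a particle matrix
with PAH mass fraction `q_PAH` (ng/g) suspended in air at `C_particle`
(g/m3), or a PAH at ambient concentration `C_PAH` (ng/m3):

$$DI = \frac{q_{PAH} \cdot F_{bioa} \cdot TR \cdot C_{particle} \cdot V_{resp}}{BW},
\qquad
DI = \frac{C_{PAH} \cdot F_{bioa} \cdot TR \cdot V_{resp}}{BW},
\qquad
ADI = \frac{CR}{IPF_{BaP} \cdot TEF}.$$

**BaP toxic equivalency.** Each analyte's concentration is weighted by
its toxic equivalency factor relative to benzo[a]pyrene and compared
with an acceptable concentration derived from the WHO unit risk:

$$ATEQ = \frac{CR}{UR}, \qquad AC = \frac{ATEQ}{TEF},
\qquad BC = TC \cdot F_{bioa}.$$

Classifying `TC > AC` per analyte and classifying `TC x TEF > ATEQ` in
BaP-equivalent space are algebraically identical; the package exposes
both and tests the identity property-wise on random inputs.

Assumptions worth keeping in view: TEF additivity (no mixture
interactions), a single adult receptor (no age stratification), the
inhalation route only, and the UR's lifetime-70-year exposure premise,
which enters as metadata only - no time integration is performed.

## Parameters, units, defaults

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `tr` | tracheobronchial retention | fraction | 0.75 |
| `v_resp` | adult inhalation rate | m3/day | 20 |
| `bw` | adult body weight | kg | 60 |
| `c_particle` | particle concentration in air | g/m3 | unset; 5.6e-3 in `extreme_biochar_scenario()` |
| `cr` | target lifetime cancer risk | - | 1e-6 (acceptable range 1e-6 to 1e-4) |
| `ipf_bap` | BaP inhalation potency factor | (ng/kg/day)^-1 | 3.9e-3 |
| `ur` | unit risk per BaP-eq concentration | (ng/m3)^-1 | 8.7e-5 |

The defaults give a unit intake factor `TR x V_resp / BW = 0.25`
day.kg^-1.m3, a maximum ADI of 0.26 ng/kg/day (TEF = 0.001) and an ATEQ
of 0.0115 ng/m3. The 5.6 mg/m3 biochar particle concentration is an
extreme-pollution scenario default, not a validated ambient level.

Internal canonical units are ng (PAH mass), g (particle mass), m3 (air),
kg (body mass), day (time), fractions of 1 for `F_bioa`. Percent,
ug/g loadings and mg/m3 particle concentrations exist only at the I/O
boundary, where loaders convert (x1000, /1000) and errors name the
offending column.

```{r defaults}
reg <- load_default_registry()
with(reg$exposure, tr * v_resp / bw)
compute_adi(reg$toxicity, 0.001)
compute_ateq(reg$toxicity)
```

## Risk classification and numerical choices

Risk is flagged when the dose or concentration strictly exceeds its
threshold; the boundary `DI == ADI` is classified *acceptable*. The
convention is configurable (`boundary_risky = TRUE`) and immaterial in
practice - no bundled value lands on a boundary - but a fixed,
documented tie-break keeps classifications reproducible.

All arithmetic runs at full double precision. Printed-table
reproduction happens only in tests and in the CLI's `--printed-digits`
option, using round-half-up (the convention of printed tables, unlike
base R's round-half-to-even) with a tolerance of one unit in the last
printed digit. That tolerance absorbs the reference tables' own
rounding: they print `F_bioa` to 4 decimals of percent and DI to 4
decimals, so recomputed DI can differ from a printed cell by up to one
last-digit unit (e.g. the WN/ALF/pyrene cell prints 0.0944 where full
precision gives 0.09435).

Two precisions of the PM2.5 bioaccessibility values circulate: a
3-significant-figure display form (e.g. 21.3%) and a higher-precision
form (21.28%). The package stores the higher-precision values as
canonical - the printed DI column (0.1224 for phenanthrene) is only
reproducible from them - and keeps the display values in a separate
fixture column marked as display-only.

Degenerate inputs are rejected with named errors rather than coerced:
non-positive total masses, released mass exceeding total, `TEF <= 0`
(ADI and AC are undefined), missing `c_particle` in the matrix route,
fractions outside [0, 1]. A missing bioaccessibility measurement
(naphthalene in the PM2.5 profile) propagates as "not assessed" - never
as zero - and is excluded from range summaries.

## The synthetic desorption generator

The bundled reference data contain only desorption *endpoints*, so the
package generates full time series synthetically for pipeline testing:

$$m(t) = M \cdot p \cdot (1 - e^{-kt})$$

with total mass $M$, plateau fraction $p$ and rate $k$ (default 0.5/h,
sampled at 24 evenly spaced points over 24 h - a realistic in-vitro
sampling design with a fully developed plateau, $kT = 12$).
Multiplicative Gaussian noise (relative s.d. `noise_sigma`) is applied
to the per-interval release *increments*, truncating negative noisy
increments to zero. This keeps the series monotone and below the total
by construction - noising the cumulative levels and taking a running
maximum instead would bias the recovered plateau upward. Identical
configurations (including `seed`) generate identical series.

The first-order single-compartment shape is a modelling convenience:
only the plateau carries meaning for the risk models, and no kinetic
claim is attached. Consequently, passing tests demonstrate that the
*reduction and assessment* machinery is correct, not that real
desorption follows first-order kinetics; real series exhibit biphasic
release, measurement noise that can break monotonicity, and
fluid-chemistry effects the generator does not emulate.

```{r generator}
cfg <- desorption_config(plateau_fraction = 0.196, noise_sigma = 0.02,
                         seed = 42)
s <- generate_desorption(cfg, total_mass = 10000)
fbioa_from_series(s)$f_bioa
```

Parameter recovery is tested over 200 seeded series with plateaus drawn
from [0.003, 0.45] (the biochar-to-PM2.5 range) and 2% increment noise:
at least 95% of recovered fractions fall within 5% relative error of the
generating plateau.

## What the bundled assessments show

```{r pm25}
pm <- load_fixture("pm25")
res <- assess_intake_table(pm, mode = "both", route = "ambient")
bio <- subset(res, mode == "bioaccessible")
tot <- subset(res, mode == "total")
sort(bio$analyte[bio$risky %in% TRUE])
sort(setdiff(tot$analyte[tot$risky], bio$analyte[bio$risky %in% TRUE]))
```

Eight analytes remain risky regardless of mode; phenanthrene and pyrene
are flagged only when bioaccessibility is ignored. (The registry keeps
the reference classification verbatim even where low-TEF analytes carry
a "risky" flag under a carcinogenic framework; re-litigating carcinogen
classification is out of scope.) Under the TEQ model:

```{r teq}
teq <- assess_teq_table(pm)
sort(teq$analyte[teq$risky_total & teq$risky_bioaccessible %in% FALSE])
```

these four analytes are rescued by bioaccessibility, while BaA,
BbF+BkF, BaP and DBahA stay risky in both modes. Because
`F_bioa <= 1`, bioaccessible-mode risk always implies total-mode risk;
the converse is where the two assessments diverge.

## Problem sizes and limitations

Every bundled computation is closed-form arithmetic over at most 48
measurements; the full regression suite (every table cell plus the
range and ratio summaries) and the 200-series recovery property run in
seconds. Known limitations: no probabilistic (Monte Carlo) exposure
modelling, no dermal or ingestion routes, no kinetic model fitting or
sorption isotherms, no alternative TEF schemes beyond the bundled table
(users can supply their own via the YAML registry config), and in-vitro
bioaccessibility stands in for in-vivo uptake - the assessments
demonstrate the *impact* of bioaccessibility on the verdict, not a
validated absolute risk.
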