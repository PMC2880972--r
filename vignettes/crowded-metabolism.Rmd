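---
title: "A reduced flux-balance model of ATP production under molecular crowding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced flux-balance model of ATP production under molecular crowding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdfba)
```

## The model

Rapidly proliferating mammalian cells excrete lactate even when oxygen is
plentiful (aerobic glycolysis, the Warburg effect), although lactate
fermentation yields only 2 mol ATP per mol glucose against 38 for full
oxidation. `crowdfba` implements a two-pathway flux-balance model that
resolves this: the glucose uptake flux $f_G$ is split into a component
$f_L$ ending in lactate excretion and a component $f_M$ oxidized in
mitochondria,

$$f_{ATP} = 2 f_L + 38 f_M = 2 f_G + 36 f_M, \qquad f_G = f_L + f_M,$$

and the cell maximizes $f_{ATP}$ subject to two capacities:

* **glucose uptake**: $f_G \le F_G$, the transport-limited maximum uptake;
* **solvent capacity**: the enzymes and organelles carrying each flux take
  up cytoplasmic volume, $a_G f_G + a_L f_L + a_M f_M \le \phi_{ATP}$,
  where each *crowding coefficient* $a = s\,v/r$ is the occupied volume
  fraction per unit of flux (specific volume $v$ in mL/g over the pathway
  rate per unit dry mass $r$ in mmol/min/g, times the stoichiometric
  multiplier $s$), and $\phi_{ATP}$ is the volume fraction available to
  the ATP machinery.

All internal fluxes are in mM/min (mmol per liter of cell volume per
minute); coefficients are in min/mM. Conversions from per-cell and
per-dry-mass reporting bases happen only at the I/O boundary
(`convert_rate()` and friends), never inside the model.

The optimum is piecewise linear in $F_G$. Respiration generates more ATP
per glucose, so below the threshold

$$f_1 = \frac{\phi_{ATP}}{a_G + a_M}$$

every molecule of glucose is oxidized ($f_M = f_G = F_G$, *glucose-limited
regime*). At $f_1$ mitochondria fill the entire available volume fraction;
beyond it, extra uptake can only be monetized through the much less bulky
glycolytic/LDH machinery ($a_M/a_L \approx 450$ with the default
coefficients), so lactate excretion switches on linearly while respiration
recedes slightly (*space-limited regime*):

$$f_M = \frac{\phi_{ATP} - (a_G + a_L) F_G}{a_M - a_L}, \qquad
  f_L = F_G - f_M .$$

The ATP rate keeps rising, but with slope
$2 - 36 (a_G + a_L)/(a_M - a_L) \approx 0.94$ instead of 38. The
respiratory flux reaches zero at $f_2 = \phi_{ATP}/(a_G + a_L)$; we treat
$f_2$ as plumbing (it lies far outside physiological uptakes — 24 mM/min
with the defaults) and cap glucose utilization there, flagging the
partition with `capped = TRUE`, because taking up glucose that cannot be
catabolized has no objective benefit in this model.

### When does the switch exist at all?

The mixed-regime formula is the true optimum only if aerobic glycolysis
beats respiration in ATP per unit of *occupied volume*:
$2/(a_G + a_L) > 38/(a_G + a_M)$, equivalently
$a_M - a_L > 18\,(a_G + a_L)$. This is the model's core trade-off stated
as an inequality, and measured mammalian coefficients satisfy it by more
than an order of magnitude. For hypothetical parameter sets that violate
it, lactate never pays and the optimum pins $(f_L, f_M) = (0, f_1)$ for
every $F_G \ge f_1$. `optimal_fluxes()` implements the exact maximizer in
both cases and `overflow_favorable()` exposes the predicate; the
two-regime shape properties are therefore tested on overflow-favorable
parameter draws, while agreement with the independent linear-programming
oracle is tested unconditionally.

### The LP oracle

`lp_solve_oracle()` is a deliberately independent check on the closed
form: it enumerates all pairwise intersections of the four constraint
boundaries of the 2-variable linear program, filters feasible vertices at
a $10^{-9}$ tolerance, and returns the objective-maximizing vertex, ties
broken toward larger $f_M$ (consistent with the analytic convention that
the degenerate equal-efficiency case stays with respiration). The test
suite asserts agreement with `optimal_fluxes()` to $10^{-7}$ absolute over
1000 random models drawn log-uniformly over $10^{-4}$–$1$ min/mM with
$\phi_{ATP} \in (0.01, 0.5)$ — a size chosen to cover the coefficient
space densely while keeping the default test run a few seconds. All
tolerances live in one table, `fba_tolerances()`.

## Parameter estimation

`estimate_crowding_parameters()` reproduces the chain from raw literature
measurements to coefficients, with an audit attribute recording each step:

* $r_G$: a 23 µmol/min/mL lactate flux over 40 mg/mL total glycolytic
  protein, divided by 2 to express it per glucose → 0.29 mmol/min/g;
* $r_L$: the same flux over 3.2 mg/mL LDH → 7 mmol/min/g;
* $r_M$: the top of the reported 0.1–1.0 mmol ATP/min/g range (1.0), a
  deliberate best-case choice for respiration;
* specific volumes 0.79 mL/g (globular proteins, used for both glycolytic
  enzymes and LDH) and 2.9 mL/g (mitochondria, the mean of liver 3.15 and
  muscle 2.6);
* $\phi_{ATP}$: 0.07–0.38, the span of reported mitochondrial volume
  fractions across cell types.

Two conventions ship as profiles. `crowding_profile("printed")` keeps each
coefficient at the two-significant-figure precision customarily reported
($a_G = 0.0027$, $a_L = 0.00023$, $a_M = 0.10$);
`crowding_profile("full_precision")` recomputes everything unrounded
($a_M = 0.1044$). The distinction matters at the last digit: the reported
$a_L = 0.00023$ arises only when the chain carries the rounded
intermediate $r_L = 7$ forward ($2 \times 0.79/7/1000$); the unrounded
$r_L = 7.1875$ gives 0.00022. Matching reported values is therefore always
done through one arbiter, `round_sig()` (half-to-even at $n$ significant
figures), with printed intermediates fed forward — the convention the
original derivation itself uses. With $\phi_{ATP} = 0.07$ the predicted
threshold is $f_1 = 0.07/0.1027 = 0.68 \approx 0.7$ mM/min; the upper
endpoint at $\phi_{ATP} = 0.38$ evaluates to 3.70 mM/min with these
coefficients (an $a_M$ of 0.17 would be needed to reach the sometimes-
quoted 3.8 — the two printed values are mutually inconsistent, so we
report what the coefficients actually give and treat only the lower
endpoint as reproducible).

Unit conversions are strict dimensional analysis. A per-cell rate is
divided by the total cell volume (count × single-cell volume,
1 µm³ = 10⁻¹⁵ L) and rescaled to minutes: 0.69 µmol per 10⁶ cells per day
at 600 µm³ gives 0.80 mM/min; 0.042 mmol per 10⁹ cells per hour at
1300 µm³ gives 0.54 mM/min. (The published hybridoma sentence prints the
basis as "per 10⁶ cells", but only the 10⁹ basis is consistent with both
the source dataset's units and the quoted 0.37–0.54 mM/min result, so the
implementation uses 10⁹.) A per-dry-mass rate is multiplied by the cell
density: `convert_per_mass_rate(0.029, 0.34)` ≈ 0.16 mM/min. Note that
published compilations sometimes quote an order of magnitude more for
this last case; dry-mass-to-wet-volume conventions differ between sources
and no factor in the stated inputs bridges the gap, so the package
implements the plain dimensional-analysis result and leaves
reconciliation to the user's metadata.

## Empirical threshold fitting

The practical estimator of the switch is deliberately simple, matching how
such thresholds are read off chemostat flux plots: select the records with
"significant" lactate production, fit ordinary least squares of lactate
excretion on glucose uptake there, and report the x-intercept
$\hat f_1 = -\text{intercept}/\text{slope}$ (`fit_threshold()`).

Two open choices and how we fixed them:

* **The significance cutoff.** No published definition exists. The default
  is 15% of the maximum observed lactate excretion, exposed as
  `cutoff_frac` / `cutoff_abs`. The choice is driven by a failure mode we
  measured: with noise at 5% of the maximum (the level used throughout the
  simulations), a cutoff equal to 1 noise-sd lets ~16% of true-baseline
  points leak into the active set, biasing the x-intercept left by ~25% on
  median; at 3 noise-sd (15%) the median recovery error drops to ~6% and
  is flat for cutoffs between 10% and 25%. Records exactly at the cutoff
  are included.
* **The estimator.** Plain OLS on the active region is the default because
  it mirrors the graphical procedure being reproduced. A joint two-segment
  hinge fit over *all* records (`method = "hinge"`, Nelder–Mead on
  breakpoint and slope) is provided as a cross-check; it is slightly more
  accurate in simulation but is not the default since it answers a
  different question than "the line through the overflow points".

`detect_active_region()` returns a no-overflow *outcome* (not an error)
when nothing passes the cutoff, so purely respiratory datasets are
representable. When the oxidized-glucose rate is measured,
`derive_respiration_and_atp()` converts records to respiration and ATP
rates through the flux-balance identity $f_{ATP} = 2 f_G + 36 f_M$, and
`compare_to_model()` puts data and model on one table: pointwise lactate
residuals against the regime curve plus fitted-versus-predicted overflow
slope, the predicted slope being
$2\,(1 + (a_G + a_L)/(a_M - a_L)) \approx 2.06$ with the printed profile.

## What the synthetic data do and do not emulate

`generate_flux_dataset()` produces the hinge structure the estimator
assumes: uptake as the controlled variable on a grid (as a chemostat's
dilution rate effectively sets it), additive Gaussian noise on the lactate
measurement only, truncation at zero, and an optional model-consistent
oxidized-glucose column $(2 f_G - \text{lactate})/2$.
`generate_model_consistent_dataset()` samples around `atp_curve()`
instead, with independent noise on lactate and oxidized glucose. Each
generator takes a single integer seed scoping a local random stream
(`withr::with_seed`); global RNG state is never touched.

Real flux datasets differ in ways the generator does not model:
uptake itself is measured with error (an errors-in-variables effect that
attenuates fitted slopes), noise is typically heteroscedastic and
sometimes multiplicative, replicate counts are small and unevenly spaced,
and the true lactate onset may be smooth rather than an exact hinge.
Passing the recovery tests therefore shows the pipeline is correct and
well-calibrated *under its own assumptions*, not that real thresholds
carry 6% errors.

Default simulation conditions (used by `analysis/03_simulate_and_fit.R`
and the test suite): breakpoint at its LS-cell-like value, slope 2.06
(the model-predicted value), n = 20 points spanning three breakpoints,
noise sd 5% of the maximum lactate excretion, 100 replicate seeds —
realistic for a chemostat series and large enough that the median recovery
error is stable.

## Numerical choices, degenerate inputs, limitations

* Feasibility tolerance $10^{-9}$ (LP oracle), analytic/oracle agreement
  $10^{-7}$, flux-balance identity $10^{-9}$ relative, equality of the two
  ATP-rate forms $10^{-12}$ relative (`fba_tolerances()`).
* $a_M \le a_L$ is rejected at validation — the mixed-regime split divides
  by $a_M - a_L$, and a bulk-per-flux ordering the other way is
  biologically implausible — rather than special-cased.
* At $F_G = f_1$ both branches give identical fluxes (continuity is
  property-tested); exactly at the overflow-favorability boundary the tie
  goes to respiration, matching the LP tie-break toward larger $f_M$.
* The model is steady-state and two-pathway by design: no kinetics, no
  genome-scale stoichiometry, and the precursor-biosynthesis flux is held
  constant outside the optimization. $\phi_{ATP}$, $r_G$, $r_L$, $r_M$
  are constants, though real cells regulate them.
* The package ships no experimental flux tables; published supplementary
  datasets can be read with `read_flux_tsv()` once exported to the
  documented TSV dialect.

## The analysis workflow

The `analysis/` directory strings the package into the full study:
`01_estimate_parameters.R` (literature chain → coefficients, predicted and
empirical thresholds), `02_regime_curve.R` (the two-regime flux curve and
figure), `03_simulate_and_fit.R` (threshold recovery under noise),
`04_compare_to_model.R` (model-consistent data through the fitting
pipeline). Each writes plain TSV/JSON under `results/`. These scripts,
together with the exported functions, are the package's command surface;
there is no separate CLI binary.

```{r example}
m <- crowding_profile("printed", phi_ATP = 0.07)
threshold_f1(m)
optimal_fluxes(2 * threshold_f1(m), m)[c("f_L", "f_M", "regime")]
predicted_lactate_slope(m)
```
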