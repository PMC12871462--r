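---
title: "Simulating and analysing 13CH4 microcosm incubations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing 13CH4 microcosm incubations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karstCH4)
```

## Scope

karstCH4 implements the quantitative chain used to characterize atmospheric
methane oxidation in methanotroph-dominated sediments from closed-bottle
incubations: a forward simulator of ^13^CH~4~/^12^CH~4~ microcosms, initial
oxidation-rate estimation from headspace draw-down, Michaelis–Menten
kinetics with headspace-to-aqueous conversion, a ^13^C mass balance yielding
carbon-assimilation efficiency, the PLFA/FAME methylation correction, and
regional sink upscaling. This vignette explains the models behind each
stage, the defaults and why they were chosen, and what the synthetic data
can and cannot tell you about real incubations.

## The microcosm model

Each bottle holds `sediment_dry_mass` (default 20 g) of sediment under a
`headspace_volume` (0.105 L, a 125-ml serum bottle minus sediment) at 20 °C
and 1 atm. Methane is consumed by Michaelis–Menten kinetics acting on the
*aqueous* CH~4~ concentration, with headspace–water equilibrium assumed
instantaneous through the Bunsen solubility coefficient β (0.034 at 20 °C):

$$ C_{aq}\,[\mathrm{nM}] = \beta \cdot \frac{x\,[\mathrm{ppmv}]\times
10^{-6} \cdot P}{V_m(T)}, \qquad
v = \frac{V_{max}\, C_{aq}}{K_m^{aq} + C_{aq}} $$

with the molar volume $V_m$ evaluated at the incubation temperature
(24.055 L mol^−1^ at 20 °C), not at STP — the convention under which a
half-saturation constant of 138.8 ppmv corresponds to 196 nM dissolved
CH~4~. The dissolved pool itself is negligible as a reservoir (≈0.1% of the
headspace inventory at 20% moisture), so consumption is drawn from the
headspace.

Oxidized carbon is split three ways: a fraction `f_assim` enters the
sediment organic carbon (TOC) pool, `plfa_yield` of that flux is tagged into
PLFA compounds by a fixed allocation, and the remainder leaves as CO~2~,
where it mixes with unlabelled background respiration. All pools are
tracked in moles of ^12^C and ^13^C separately; an optional kinetic
fractionation `epsilon_ox` shifts the isotope ratio of the instantaneously
oxidized carbon (default 0‰: the incubations showed no detectable rate
difference between the isotopologues, and a zero default makes labelled and
unlabelled bottles exactly comparable).

Events follow the incubation protocol: CH~4~ is topped back up to the
target every 72 h; on day 15 the entire headspace is vented (the removed
^13^C is logged) and refilled; ambient-air controls get a full headspace
exchange at every replenishment; autoclaved sterile controls have both
oxidation and respiration disabled. Observation rows at event times record
the *pre-event* sample, matching the practice of sampling gas before each
addition, so vented pools are directly observable.

Integration is a fixed-step (≤0.5 h, default 0.25 h) explicit update; the
per-step consumption uses a classical Runge–Kutta evaluation of the
Michaelis–Menten draw-down because a first-order Euler step at these rate
constants (k·Δt ≈ 0.06) systematically inflates apparent decay constants by
about k·Δt/2 ≈ 3%, which is larger than the recovery tolerances the test
suite holds the chain to.

### Generative defaults

The default `true_state()` is calibrated to the operating point of a
methanotroph-dominated cave sediment: `km_aq_true` = 196 nM (138.8 ppmv headspace) and `vmax_true` =
115.9 ng g^−1^ h^−1^, so that the oxidation rate at 500 ppmv equals
90.7 ng g^−1^ h^−1^; 60% of oxidized carbon is assimilated (`f_assim`,
within the 52.6–73.2% range such incubations report). Quantities a real
incubation measures but the kinetic model does not constrain are given
field-realistic values: TOC 1.5% at
δ^13^C −25‰, background respiration 8 ng C g^−1^ h^−1^ at −25‰ (a
synthetic-only device that gives unlabelled and ambient bottles a realistic
δ^13^C-CO~2~ baseline; real sediments' heterotrophy is not otherwise
modelled), PLFA background stocks of ~1.6 µg g^−1^ across 16:0, 16:1ω7c
and a pooled remainder (low standing biomass, as expected for oligotrophic
subsurface sediment), and a PLFA yield of 3% of assimilated carbon.

### Measurement model

Noise is applied to observations only — the latent state stays exact, so
the generative truth remains recoverable. Concentration-type readings
(CH~4~, CO~2~, TOC, PLFA concentrations) receive mean-one multiplicative
lognormal noise with `measurement_cv` = 0.02, typical GC-FID repeatability;
isotope readings receive additive noise of `delta_sd` = 0.3‰ on the δ scale
(continuous-flow IRMS). The ^13^C atom fraction of CH~4~ is perturbed on
the ratio scale so it stays inside (0, 1). One master seed drives
deterministic per-bottle substreams; identical configuration and seed give
byte-identical outputs.

## Rate estimation

`estimate_oxidation_rate()` reports the oxidation rate at the start of an
observation window in ng CH~4~ g^−1^ dry h^−1^ (ideal-gas headspace moles,
molar mass 16.04). Three methods are available. The ln-linear
`first_order` estimator (rate = k·C₀) is exact on exponential decay, i.e.
when C₀ ≪ K~m~, but at C₀ ≈ 3.6·K~m~ (500 ppmv) the effective first-order
constant grows as the bottle draws down and the fitted k overestimates the
initial rate by >10% over any usable window. The default `log_quadratic`
method therefore fits a quadratic in time to ln C and reports the *initial*
slope; it degenerates to the first-order answer on exponential data and
stays nearly unbiased in the saturated regime. A plain `linear` method
(−slope of C vs t) is kept for zero-order stretches and as the fallback
when a window contains non-positive readings.

Two further choices control the bias–variance trade-off. The default
window runs from the series start to the first event, truncated once CH~4~
falls below 85% of its initial value, keeping the estimate local to the
initial rate. And when the fill concentration is known by design (bottles
are injected to a target), passing it as `c0` anchors the fit through that
point with no free intercept, which markedly stabilizes short noisy
windows; `kinetics_from_dataset()` does this automatically. Even so,
initial rates from 2%-CV series over a few early points carry sampling
error of order 10–20% per bottle — replication, not window depth, is the
honest remedy, and the per-bottle standard errors propagate the regression
slope uncertainty so downstream users can see it.

## Kinetics

`fit_michaelis_menten()` fits v = V~max~·S/(K~m~+S) by unweighted
Levenberg–Marquardt least squares (rate ladders of this kind are
conventionally fitted unweighted), multi-started from 8 log-spaced K~m~ values spanning the
concentration range to avoid the flat-valley local optima this model is
known for; the best of the converged starts is kept and total failure is
reported as `converged = FALSE` rather than an error. K~m~ is fitted on
the measured headspace axis (ppmv) and converted to nM afterwards, matching
the dual reporting convention. Standard errors come from the Jacobian at
the optimum. `specific_affinity()` converts V~max~ to a per-cell clearance
(L cell^−1^ h^−1^) given a pmoA-derived cell density; the density is an
explicit input because it cannot be derived from the incubation data.

## The ^13^C mass balance

Atom percent and δ^13^C interconvert through
$AT = 100\,(\delta/1000+1)R_{st} / (1+(\delta/1000+1)R_{st})$ with
R~st~ = 0.0111802 (VPDB) by default. The sediment excess
$^{13}C_{SOC} = 10 \times TOC(\%) \times (AT_{labeled}-AT_{unlabeled})
\times 10$ (mg kg^−1^) is provided exactly in this printed form by
`excess_13c_soc()`.

Per-bottle budgets, however, are computed on the mole scale: excess ^13^C
atoms (above the paired unlabelled control) × 13.003 g mol^−1^, for all
four terms — supplied label, SOC, CO~2~ (vented pools plus final
headspace), residual CH~4~. Two conventions make the budget exact:
supplied label is counted as *excess over natural abundance*
(moles × (AT~label~ − AT~nat~)), and the baseline is the paired unlabelled
control rather than a constant, which cancels both the initial TOC
signature and the natural-abundance carbon the control itself assimilates.
Under these conventions a noiseless run closes at exactly 100% recovery and
the recovered efficiency equals the generative `f_assim`; the printed-form
mg kg^−1^ quantity, which omits the ^13^C/^12^C mass ratio (≈8%), is
reported alongside but not used as the budget numerator. All injected
label is counted, including label consumed before the day-15 swap —
consistent with complete consumption between replenishments. Negative
excesses (possible under noise) are flagged, never clamped.

At the lowest doses (≤10 ppm) the total supplied ^13^C shifts δ^13^C-TOC by
only a few tenths of a permil — the same order as IRMS precision — so
per-bottle efficiencies there are noise-limited. This is a property of the
experiment, not the estimator; the simulator reproduces it faithfully.

## PLFA correction and dose–response

Transesterification adds one methanol-derived carbon to each fatty acid;
`correct_fame_delta()` removes it by mass balance,
$\delta_{PLFA} = ((n+1)\delta_{FAME} - \delta_{methanol})/n$, where *n*
counts carbons in the *free* fatty acid (the methyl ester has n+1 — the
only reading under which the balance is exact). The methanol δ^13^C is a
required input with no default, since it must be measured per batch.
`dose_response()` regresses treatment-mean PLFA concentration and corrected
δ^13^C against total CH~4~ added (means, unweighted, as such dose–response
panels are conventionally drawn) and flags compounds whose concentration
slope is not positive.

## Upscaling

`regional_sink()` evaluates sink = area × reactive sediment mass per area ×
rate × active fraction × hours per year (ng → Tg, 10^−21^), with seeded
Monte-Carlo propagation (2.5/97.5 percentiles) for parameters given as
distribution specs. The field-survey parameters behind regional sink
estimates for southwest China's karst (0.56–0.93 Tg yr^−1^) are not
distributed with the package, so the defaults are labelled illustrative;
they reproduce the conservative 0.56 Tg yr^−1^ magnitude as a worked
example, and the emission offsets (5.7% of rice-cultivation methane,
2.4% of total agricultural methane in China) follow from that sink and the
published emission inventories alone. `habitat_summary()` compares potential oxidation rates
across habitats within half-open initial-CH~4~ bins ((0, 5], (5, 60] ppm),
using Kruskal–Wallis-style rank-based all-pairs Wilcoxon tests with
Benjamini–Hochberg adjustment at 0.05 and compact-letter assignment —
rank-based because literature-compiled rate data are heavy-tailed, and no
specific post-hoc is implied by the source figures.

## Numerical and design notes

* Tie-breaks and degenerate inputs: all-zero rate ladders return
  `converged = FALSE`; windows containing events are rejected; series with
  fewer than 3 points raise an estimation error; δ below −1000‰ and atom
  percent at the bounds raise domain errors.
* The day-15 swap time must fall on the sampling grid; replenishment
  intervals must be multiples of the sampling interval (validated).
* A constant carbon mass fraction of 0.75 is used to express PLFA pools as
  ng of fatty acid; compound-specific formulas would change concentrations
  by <2% and no downstream quantity depends on the absolute scale.
* Headspace pressure is held at 1 atm throughout; the small pressure
  excursions of real repeated injections are not modelled.
* `TrueState` carries three fields beyond the measured quantities —
  background PLFA stocks, their δ^13^C, and the methanol δ^13^C — because
  endpoint FAME observations cannot be generated without them.

## What the synthetic data do and do not show

The generator reproduces the statistical and isotopic *structure* the
analysis assumes: Michaelis–Menten draw-down between replenishments, label
conservation, dose-dependent δ^13^C enrichment of TOC, CO~2~ and PLFA, and
instrument-level noise. It deliberately omits microbial community
dynamics, growth and induction lags, moisture/temperature dependence of
kinetics, diffusion-limited mass transfer, and pressure effects. Passing
recovery tests on these data therefore demonstrates that the analysis chain
is mathematically faithful (it inverts its own generative model at the
stated tolerances), not that the biological assumptions hold in any
particular sediment.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` simulate the full 42-bottle SIP
design at 12-h sampling and a 36-bottle, 24-h rate assay at 0.5-h sampling;
the test suite and acceptance script use the same designs, with shortened
(2–3 replenishment cycles) single-replicate variants where a property does
not depend on the full schedule. Monte-Carlo sizes are 200 replicate
datasets for K~m~ recovery and 5000 draws for scenario intervals.
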