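# karstCH4

Simulation and analysis of **¹³CH₄/¹²CH₄ microcosm incubations** for
quantifying atmospheric methane oxidation by sediment methanotrophs — the
kind of closed-bottle, stable-isotope-probing (SIP) experiment used to show
that subsurface karst sediments act as a methane sink. The package is
aimed at biogeochemists and microbial ecologists who run (or review)
headspace incubations and want every step of the quantitative chain —
rates, kinetics, isotope mass balance, PLFA correction, upscaling — as
tested, reproducible code.

## What it computes

* **Synthetic microcosms** (`simulate_experiment()`): seeded forward
  simulation of triplicate 125-ml bottles with 20 g sediment, CH₄ targets
  2–500 ppmv, 99 atom% ¹³CH₄ vs unlabelled controls, 3-day replenishment,
  a day-15 headspace swap, sterile and ambient controls, GC/IRMS-level
  measurement noise. All state is tracked in moles of ¹²C/¹³C, so label is
  conserved exactly.
* **Oxidation rates** (`estimate_oxidation_rate()`): initial draw-down
  rates in ng CH₄ g⁻¹ h⁻¹ from headspace time series.
* **Michaelis–Menten kinetics** (`fit_michaelis_menten()`): multi-start
  nonlinear least squares of v = V·S/(Kₘ+S); Kₘ fitted in ppmv and
  converted to the aqueous scale with the Bunsen coefficient,

  C_aq [nM] = β · (x·10⁻⁶·P) / Vₘ(T),  β = 0.034 for CH₄ at 20 °C,

  plus per-cell specific affinity a⁰ₛ = V_max/Kₘ.
* **¹³C mass balance** (`isotope_budget()`): atom-percent conversion
  AT(%) = 100·(δ/1000+1)·Rst / (1+(δ/1000+1)·Rst), sediment ¹³C excess,
  CO₂ and residual-CH₄ inventories, carbon-assimilation efficiency,
  biomass/CO₂ partitioning, recovery.
* **PLFA tools** (`correct_fame_delta()`, `dose_response()`): the
  methylation correction δ_PLFA = ((n+1)·δ_FAME − δ_methanol)/n and
  per-compound dose–response against methane added.
* **Upscaling** (`regional_sink()`, `offset_fraction()`,
  `habitat_summary()`): scenario-based regional sink estimates with
  Monte-Carlo intervals, emission offsets, and rank-based habitat
  comparisons with compact letters.

## Worked example

```r
library(karstCH4)

# a fitted half-saturation constant of 138.8 ppmv, on the aqueous scale:
headspace_to_aqueous(138.8, temperature = 20, pressure = 1, bunsen = 0.034)
#> [1] 196.1825        # nM dissolved CH4

# simulate a noiseless rate assay and recover the kinetics
truth <- true_state()   # Vmax 115.9 ng/g/h, Km 196 nM, f_assim 0.6
assay <- simulate_experiment(
  rate_assay_config(sampling_interval = 0.5, replicates = 1,
                    measurement_cv = 0, delta_sd = 0), truth)
kin <- kinetics_from_dataset(assay)
kin$by_treatment
#>  target_ppm rate_ng_g_h
#>           2    1.647914
#>          10    7.797400
#>          50   30.719951
#>         100   48.553227
#>         250   74.487704
#>         500   90.600030   # the 500-ppm operating point, ~90.7 ng/g/h
round(c(vmax = kin$fit$vmax, km_ppm = kin$fit$km_ppm, km_aq = kin$fit$km_aq), 1)
#>   vmax km_ppm  km_aq
#>  115.6  138.2  195.3

# 13C mass balance of a 30-day SIP pair at 500 ppm (noiseless)
sip <- simulate_experiment(
  incubation_config(target_ch4 = 500, replicates = 1,
                    include_sterile_control = FALSE,
                    include_ambient_control = FALSE,
                    measurement_cv = 0, delta_sd = 0), truth)
round(isotope_budget(sip)[c("supplied_13c_ug", "soc_13c_ug",
                            "efficiency_pct", "recovery_pct")], 1)
#>  supplied_13c_ug soc_13c_ug efficiency_pct recovery_pct
#>            277.8      166.7             60          100
```

The recovered efficiency equals the generative assimilation fraction (60%)
and the budget closes at 100% — the chain inverts its own generator
exactly on clean data; with instrument noise the same quantities come back
within a few percentage points (see `analysis/03_mass_balance.R`).

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full study-style analysis on synthetic data, writing tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the 42-bottle SIP dataset and a 36-bottle rate assay |
| `02_kinetics.R` | per-bottle rates, Michaelis–Menten fit, aqueous Kₘ, specific affinity |
| `03_mass_balance.R` | per-bottle ¹³C budgets, efficiencies, recovery |
| `04_plfa.R` | FAME methylation correction, PLFA dose–response |
| `05_upscaling.R` | regional sink scenarios, emission offsets, habitat letters |

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

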