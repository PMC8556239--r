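# nbudgetr

Soil-surface nitrogen (N) budgets for cropland, computed from country-year
panel statistics.

Cropland N budgets compare the N removed in harvested crops with the N
supplied to the soil surface by four inputs — synthetic fertilizer, manure,
symbiotic fixation by legumes, and atmospheric deposition. Assembling them
over decades of national statistics is mostly an exercise in careful data
plumbing: crop areas and harvests are scattered across incompatible
nomenclatures, fodder crops are reported on varying water ("humidity")
bases or lumped into historical "hay" aggregates, fertilizer use on
grassland is known only from sparse surveys, and manure must be traced from
excretion through housing and storage losses to the field. `nbudgetr`
implements that pipeline as composable, tested tidyverse-style functions,
for researchers building or auditing national nutrient accounts.

## The accounting in brief

For each country and year:

* **Harvest.** Crops are aggregated into categories. Per category,
  `A_sum` and `H_sum` are the sums of available crop areas and N harvests,
  the ratio-of-sums yield is `Y_est = Σ H / Σ A` over crops reporting both,
  and the category area estimate is `A_est = H_sum / Y_est`, which treats
  crops with missing areas as yielding like the rest of their category.
  Fodder-crop harvests are areas × modeled dry-matter yields × N contents;
  yields follow a line through 75% of the 2010 reference value in 1961,
  with temporary-grassland yields inflated 20% for grazing intake.
* **Fertilizer allocation.** The share of synthetic N applied to cropland
  is `(1 + (R_PG/R_C) · (A_PG/A_C))⁻¹`, where `R_PG/R_C` is the
  grassland/cropland application-rate ratio recovered from surveys
  (directly, via the total-grassland disaggregation with a TG/PG rate
  multiplier `k`, or as a last resort from consumption totals), then
  gap-filled by linear interpolation and constant extrapolation.
* **Manure.** Excreted N per livestock class is split into grazing and
  housed by management-system shares, reduced by housing/storage loss
  fractions, allocated to grass/non-grass by survey shares, and
  grassland-destined N is divided between permanent and temporary
  grassland by area — the temporary part belongs to cropland. Every
  partition is a product plus its exact complement, so the chain conserves
  N at machine precision.
* **Fixation and deposition.** `BNF = Y · Ndfa · BGN / NHI` applied to the
  harvested legume N (legume dry-matter shares of mixed stands: 25% for
  temporary grassland, 90% for green legumes, 25% for other green-harvested
  plants; 100% for pulses). Deposition is rate × cropland in use.
* **Budget.** `surplus = (fertilizer + manure + BNF + deposition) − harvest`,
  with per-hectare rates over cropland in use
  (`min(crop-area sum, reported cropland)`).

A seeded synthetic-data generator (`nb_generate()`) emulates the
statistical structure of the real inputs — masked areas, pre-1987 hay
lumping, mixed humidity bases, five-yearly fertilizer surveys — so the
whole pipeline is testable without downloading anything.

## Worked example

```r
library(nbudgetr)

g   <- nb_generate(synth_config(seed = 1))   # scenario + ground truth
res <- nb_build(g$observables, g$build_config)
res
#> <nbudget_build>
#>   countries: AA, BB, CC, DD
#>   years:     1961-2019
#>   budget rows:236
#>   validation: 12/12 checks pass

glance(res)
#>   country n_years harvest_n input_total surplus input_rate    nue
#> 1      AA      59     414.9       812.6  397.72      293.3 0.5164
#> 2      BB      59     450.3       571.9  121.62      181.4 0.7918
#> 3      CC      59     377.7       401.2   23.54      133.0 0.9356
#> 4      DD      59     373.8       788.9  415.14      277.4 0.4808
```

`glance()` gives per-country means over 1961–2019: `harvest_n` is crop N
removal and `input_total` the summed N inputs (Gg N/yr), `surplus` their
difference, `input_rate` the input per hectare of cropland in use
(kg N/ha/yr), and `nue` the nitrogen use efficiency (harvest/input).
Country `AA` is an intensive system recovering about half of its inputs in
harvest; `CC` runs near balance. `tidy(res)` returns the budget in long
form, `autoplot(res)` draws the stacked input/harvest time series, and
`nb_validate(res)` re-checks every conservation identity. Pipeline inputs
and outputs are tidy CSVs (`read_observables()`, `write_observables()`,
`nb_write()`).

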