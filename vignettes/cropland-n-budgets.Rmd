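---
title: "Cropland nitrogen budgets from country-year panels: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cropland nitrogen budgets from country-year panels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbudgetr)
```

`nbudgetr` assembles soil-surface nitrogen budgets for cropland: N removed
in harvest versus N supplied by synthetic fertilizer, manure, symbiotic
fixation, and atmospheric deposition, per country and year. This vignette
documents the model choices, the tunable parameters, the numerical
conventions, and what the synthetic test bed does and does not demonstrate.

## Data model

Everything travels as tidy country-year panels (`country, year, variable,
unit, value`). Missing is an explicit empty value, never zero or a
sentinel. Units are fixed: areas in kha, N quantities in Gg N/yr, rates in
kg N/ha/yr; the single conversion rule (1 Gg over 1 kha = 1000 kg/ha) lives
in `kg_per_ha()`. The year grid defaults to 1961–2019 and is configurable
per country, since some national records begin in 1992. Composite regions
(e.g. a union of two present-day countries) are ordinary region codes with
a declared constituent list, so merges can be excretion- or area-weighted.

## Crop categories

Individual crops aggregate into output categories through a registry that
maps each code to exactly one category. For a category with incomplete crop
records, the consistent estimators are

* `A_sum`, `H_sum`: sums of available areas and N harvests;
* `Y_est = Σ H / Σ A` over the crops reporting both — the ratio of sums,
  which equals the area-weighted mean of crop yields;
* `A_est = H_sum / Y_est`: the category area implied by assuming crops with
  missing areas yield like the observed remainder.

When no crop reports both (yield undefined), `A_est` falls back to `A_sum`
and the row is flagged rather than silently patched. `Y_est` is computed
per year; pooling across years would hide genuine yield trends, so sparse
years are flagged instead. Crop N contents are fresh-basis percentages held
constant over countries and years — N contents certainly drift with
breeding, weather, and fertilization, but a panel this long offers no
defensible way to vary them, and a constant factor keeps harvests
comparable across the panel.

## Gap filling

All series editing is done by a declarative rule list applied in order
(`apply_edit_rules()`), with a log of what each rule filled. The two
implicit conventions mirror uniform statistical practice: interior gaps are
filled only by linear interpolation, edges only by constant extrapolation.
Anything else — discarding a suspect run of years, replacing a series from
an external source, scaling, merging two codes, deriving a residual
(`parent − Σ children`, clipped at zero with a warning, since areas cannot
be negative), or splitting a lumped aggregate — must be an explicit rule.
Country-specific narratives ship as example YAML configs
(`inst/extdata/`), not as hard-coded behavior.

`proportional_split()` divides a lumped historical total (a "hay"
aggregate covering several green-fodder codes, say) using fixed shares or
shares read off a reference year; the last-listed component takes the
rounding residual so the components sum to the total exactly.

## Fodder crops

Green-harvest statistics mix water bases: national humidity (0–88% water),
the standard 65% water basis for plants harvested green, dry matter, hay
(assumed 85% DM), and fodder roots (no humidity reported; 16% DM assumed).
`to_dry_matter()` normalizes them; `flag_yield_anomalies()` screens for the
classic reporting errors (identical values across bases that declare
different water contents, year-to-year steps that match a dry-matter
factor, implausible DM levels) but only advises — the selection of trusted
observations is a config list, because these judgments are irreducibly
case-by-case.

Yields are modeled as a line through the 2010 reference value: the 1961
yield is 75% of the 2010 yield (`anchor`), with the same slope continued to
2019. The 2010 reference is the unweighted mean of the selected DM-converted
observations (default: the dry-matter observations of 2010). Countries
without usable observations borrow the reference from configured donor
neighbours (copy or unweighted mean). Temporary-grassland yields are
inflated by 20% (`inflation`), uniformly across countries, to account for
grazing intake on top of the mowed harvest recorded by statistics; a config
switch (`inflate_grazing`) exists for sensitivity analyses, since the
uniform application to rarely-grazed systems is debatable. The correction
is applied multiplicatively after DM conversion; order is immaterial for a
product, this is just the documented convention. N harvest is
`area × DM yield × N content / 100`, with the mixed-stand N contents being
share-weighted means of component contents (e.g. temporary grassland: 75%
grass at 2.0% N + 25% clover at 3.3% N → 2.3% N of DM, carried at the one
decimal of the source tables).

## Land

Cropland in use is `min(crop-area sum, reported cropland)`: the crop-area
sum can double-count multicropped land (hence the cap), while reported
cropland can include fallow (hence not using it directly). A fallow
cross-check flags country-years where the crop-area sum differs from
reported-minus-fallow by more than 5%. Temporary grassland is the
gap-filled temporary-grassland crop area; when permanent plus temporary
grassland is zero, downstream grassland splits are defined as all-zero
flows with a flag rather than 0/0.

## Fertilizer allocation

The share of synthetic N applied to cropland is
`share_C = (1 + (R_PG/R_C) · (A_PG/A_C))⁻¹`, which needs only the rate
ratio and the area ratio — never the noisy consumption totals. Rate ratios
come from survey observations by three routes, in order of preference:

1. direct cropland and permanent-grassland rates;
2. total-grassland vs non-grass-cropland rates, disaggregated assuming the
   temporary-grassland rate is `k` times the permanent rate (default
   `k = 1`, per-country overrides in config);
3. a single rate plus the consumption total (`rate_ratio_last_resort()`),
   used only when no second rate exists.

Multiple estimates in one year are averaged as ratios (they arrive as
ratios; averaging the underlying rates would require areas the sources do
not give). The ratio series is interpolated/extrapolated over the grid with
per-year provenance, a configured list of countries applies no N to
permanent grassland (share 1 throughout), and quantities are allocated as
`Q_C = share · Q_tot`, `Q_PG = Q_tot − Q_C` — exact conservation by
construction. Observations carrying rate, quantity, and area must satisfy
`Q = R·A/1000` within 0.5% (configurable) or they are excluded with a
logged reason.

## Manure

Excretion totals per livestock class are inputs (per-head estimation is a
separate problem). Detailed inventory systems and classes collapse to
{grazing, solid, liquid, other} × {ruminants & equines, pigs, poultry &
rabbits}, with excretion-weighted aggregation. Shares observed from ~1990
are extrapolated constant backward to 1961 and forward one year at the
grid's end. The chain per country-year-class is: grazing/housed split →
housing & storage loss fraction → grass/non-grass allocation → area split
of grassland-destined N between permanent and temporary grassland (the
temporary part is cropland input). Grass/non-grass shares for ruminants and
pigs are liquid/solid-specific, weighted by the mean liquid/solid division
over 1997–2001 (the vintage of the allocation surveys; window
configurable), and held constant over the whole period on the assumption
that the destination of manure has been more stable than the management
systems. The binary liquid/solid assumption tolerates an "other" system
share up to 20%; beyond that, exogenous liquid/solid data are required and
the error names the offending country/class. Grazing excretion is assigned
entirely to grassland areas; stubble grazing on non-grass cropland exists
in reality but cannot be separated with these inputs, so the tension is
noted rather than modeled.

## Fixation and deposition

Symbiotic fixation is linear in harvested legume N:
`BNF = Y · Ndfa · BGN/NHI` with Ndfa the atmospheric fraction of plant N,
BGN ≥ 1 the total-to-aboveground N ratio, NHI ≤ 1 the N harvest index —
so `BNF ≥ Y · Ndfa` always. `Y` is the legume fraction of the harvest:
`DM harvest × legume DM share × legume N content / 100` (the alternative
pairing — category N harvest × DM share — is deliberately not the default:
legume fractions are richer in N than their grassy companions, and pairing
the share with the legume N content keeps the two assumptions explicit).
Ndfa/BGN/NHI values are an input table; `bnf_params_default()` ships
plausible placeholders for testing, clearly labeled synthetic, not a
published parameter set. Deposition is rate × cropland in use, with rate
series ending early held constant to the end of the grid.

## Numerical conventions

* Every partition is computed as *product + exact complement* (grazing =
  total × share, housed = total − grazing, and so on down the manure
  chain, including the final permanent/temporary split). The conservation
  identities therefore hold at machine precision in the telescoped
  subtraction form in which they are constructed, and `nb_validate()`
  checks exactly that form. The naive sum form `a·s + (a − a·s) == a` is
  *not* an IEEE identity for arbitrary doubles (it fails at the last ulp
  about 1% of the time), which is why the redundant columns are defined by
  construction rather than re-derived.
* Tidy CSVs are written with shortest round-trippable doubles and parsed
  with the C library's correctly-rounded reader, so
  `read → write → read` is the identity bit for bit.
* Interpolation never modifies observed values; extrapolation never
  invents interior values; an all-missing series is an error, not a guess.
* Rate-of-zero-area and division-by-zero cases yield explicit missing
  values with flags, never silent zeros.

## The synthetic test bed

`nb_generate()` draws a four-country, 1961–2019 scenario: smooth crop-area
and yield trends, fodder codes with a derived residual root-crop code and a
merged green-harvest code, management-system series starting in 1990,
deposition rates ending in 2013, and fertilizer surveys. The four countries
exercise the main code paths: one with a smoothly decaying grassland rate
ratio, one applying no N to permanent grassland, one whose green-fodder
statistics are lumped into a single "hay" aggregate before 1987 (and whose
manure allocation comes from a donor country), and one reporting only
total-grassland surveys so the `k`-disaggregation is used. Ground truth is
defined as the pipeline output on the fully observed inputs — internally
conservation-consistent by construction — and degradation only removes or
lumps values (30% area masking, five-yearly surveys, optional lognormal
rate noise, defaulting to none, because rates are positive). Problem sizes
are kept small (4 countries × 59 years × ~13 crop codes) so the full suite
runs in about a minute.

Passing the recovery tests shows the estimators invert the degradations the
generator models: masking of smooth series, lumping with stable composition,
sparse sampling of smooth ratio trajectories. Real statistics break all
three smoothness assumptions — classification changes mid-series,
composition shifts inside lumped aggregates, and abrupt policy-driven rate
changes between survey years — so recovery there depends on the analyst's
edit rules, not only on this machinery. The pre-1987 component areas of the
hay-lumped country are deliberately flat, which is what makes
reference-year shares recover them; the tests demonstrate consistency of
the method, not robustness to composition drift.

## Known limitations

* No crop-level disaggregation of fertilizer inputs; the data do not
  support it.
* Losses are a single housing/storage fraction; no emission speciation or
  process-based management modeling.
* Free-living (non-symbiotic) fixation, soil stock changes, leaching, and
  field gaseous losses are outside the budget definition.
* The fixation parameter table must be supplied for real analyses; the
  shipped defaults are placeholders for testing.
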