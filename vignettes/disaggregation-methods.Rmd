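---
title: "Population-weighted disaggregation of crop statistics: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-weighted disaggregation of crop statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasycrop)
```

## The problem

Agricultural censuses in much of sub-Saharan Africa report crop production
and harvested area per administrative unit, with census years varying by a
decade or more between countries, while applications (epidemic models for
crop pathogens, intervention planning) need a consistent fine-resolution
surface. For a subsistence root crop like cassava — grown in smallholder
plots too small and too heterogeneous for satellite classification — the
distribution of the *rural* population is the best available proxy for
where the crop sits in the landscape. `dasycrop` implements the resulting
dasymetric scheme: zonal totals are harmonised to one reference year and
spread over a ~1 km population grid in proportion to rural population,
under per-pixel capacity caps.

## Model and assumptions

The pipeline in `disaggregate()` is deterministic and runs per quantity
kind (production and harvested area are two fully independent layers over
the same machinery):

1. **Urban mask** (`mask_urban()`): pixels with population strictly above
   `urban_threshold` get weight 0. The inequality is strict — a pixel at
   exactly the threshold is rural. Masked pixels are kept at 0 rather than
   dropped, so outputs stay full-extent. The underlying assumption is that
   dense urban populations do not farm the crop.
2. **Rasterisation** (`rasterize_admin()`): a pixel belongs to the unit
   containing its centre. Centre containment (rather than "all touched")
   makes the assignment an exact partition, which the conservation
   guarantees below need. Two units claiming one centre is an error, not a
   tie-break: same-country units must not overlap.
3. **Standardisation** (`standardize_to_national()`): unit values are
   rescaled proportionally so country sums match the reference-year
   national totals. Raw sums run over non-missing records only, so missing
   units take none of the national total at this stage; they are filled
   later on the per-capita scale. The alternative ordering — imputing raw
   values before scaling — would make each imputation shift every other
   unit's adjusted value; scaling first keeps the two concerns independent.
4. **Per-capita rates** (`per_capita_rates()`): adjusted totals divided by
   rural zonal population. A unit with zero rural population but positive
   total yields an explicit "undefined" status rather than an infinity;
   the allocator's `zero_population_policy` decides its fate.
5. **Imputation** (`impute_all_rates()`): a missing rate becomes the
   unweighted arithmetic mean of donor rates. "Unweighted" because the
   quantity being averaged is already per-capita; population weighting
   would re-introduce size effects the per-capita transform removed. Donor
   preference: an explicit unit-group map (the user's hook for curated
   "same agro-ecological zone" choices, which cannot be automated), then
   same-country adjacent units with data, then all same-country units with
   data. Adjacency requires a shared boundary of positive length —
   corner-touching does not count. All imputations draw donors from the
   pre-imputation rate table, so the result is independent of processing
   order.
6. **Allocation** (`allocate_linear()` + `redistribute_capped()`): pixel
   allocations are `rate × population`, then clipped by the per-pixel cap
   with the excess redistributed among uncapped pixels proportionally to
   population, iterating to the fixed point. Each iteration caps at least
   one new pixel, so at most `n` iterations run.
7. **Gap fill** (`fill_bbox_gaps()`): declared bounding boxes (e.g. known
   slivers between misaligned national boundary files) have their
   no-unit, populated pixels filled at `constant_rate × population`. This
   mass lies outside every unit, so it is deliberately excluded from
   conservation and reported separately.

### The capped redistribution fixed point

The loop's fixed point has the closed form `alloc_i = min(cap, λ·pop_i)`
with λ solving `Σ min(cap, λ·pop_i) = total` — a water-filling solution.
The package also ships this closed form as `water_level_alloc()`, solved
by bisection, and uses it (not the loop) to build synthetic truth grids
and as the oracle in tests, so the two routes check each other. The
formulation is order-independent: it does not matter whether deduction and
redistribution interleave, which the loop description alone leaves open.
Redistribution weights are proportional to population among uncapped
pixels, consistent with the linearity assumption; an equal-split variant
would change intermediate states but was rejected because it would break
the monotonicity property (a more populous pixel never receives less).

**Infeasible units.** If `total > n_populated_pixels × cap`, the cap and
conservation cannot both hold. The default (`cap-and-report`) sets every
populated pixel to the cap and reports the unallocatable remainder as
`residual` in the per-unit report rather than erroring or silently
dropping mass; `infeasible_policy = "error"` makes it fatal.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `urban_threshold` | 5000 | people/pixel | strict cutoff above which a pixel is urban |
| `cap_harvested_area` | 50 | ha/pixel | half of a ~100 ha pixel can be harvested |
| `cap_production` | 1000 | t/pixel | `implied_max_yield × cap_harvested_area` |
| `implied_max_yield` | 20 | t/ha | enforced only through the cap ratio, not per pixel |
| `convergence_tol` | 1e-9 | quantity | cap-violation and residual tolerance |
| gap-fill `constant_rate` | 0.02 | quantity/person | default per-capita rate for declared bbox holes |

The yield bound is implicit: production and harvested area are allocated
independently (as two layers), so 20 t/ha constrains the *caps*, not each
pixel's ratio of the two layers. Every pixel is treated as approximately
1 km² regardless of latitude; no equal-area correction is applied, and
inputs must already share one geographic frame (no reprojection).

Conservation checks use relative tolerance 1e-9 (absolute 1e-6 in native
units); these are numerical-noise allowances, not model slack.

## The synthetic generator

`make_landscape()` emulates the features of real inputs the pipeline is
sensitive to: a lognormal rural background (mean 120 people/pixel,
sdlog 0.8 — a plausibly right-skewed rural density), Gaussian urban
hotspots whose peaks (9,000 people/pixel) exceed the urban threshold so
masking always binds somewhere, and a rectangular nested admin partition
(chosen over Voronoi so adjacency fixtures are exactly reproducible).
`make_census()` multiplies true zonal sums by a per-country jitter factor
(0.8–1.25) so raw country sums disagree with the reference totals and
standardisation is exercised non-trivially. The jitter is drawn once per
country rather than per unit: standardisation is scale-equivariant within
a country, so a common factor cancels exactly and the generator's truth
grids remain the unique correct answer; per-unit jitter would make truth
unrecoverable by construction. A `missing_fraction` of units is blanked
(seeded, never the whole of a country's units), and reference totals are
the true country sums.

What the generator does **not** emulate: real geography (coastlines,
enclaves, multi-part units with holes are supported by the geometry code
but not generated), spatial autocorrelation of rates between neighbouring
units, census measurement error beyond the multiplicative factor, and any
weighting-scheme structure in the population surface. Passing tests
therefore demonstrate the *algebra* of the pipeline — conservation, cap
compliance, imputation and recovery — not the realism of its outputs on
real data, whose accuracy is bounded by the population model and census
quality.

Default problem sizes (40 × 40 pixels, 2 countries × 4 units) keep the
whole suite fast while leaving ~200 pixels per unit, enough for masking,
capping and imputation to all bind in the same landscape.

## Numerical choices and degenerate inputs

- Pixel centres are compared to polygon edges by ray casting (even-odd
  rule over all rings, so holes need no special handling). Generated and
  fixture geometry aligns unit boundaries with pixel edges, keeping
  centres off boundaries; points exactly on an edge are assigned
  quasi-arbitrarily and flagged as a known limitation for hand-built
  inputs.
- Adjacency uses exact segment-overlap with a 1e-9 degree tolerance;
  shared boundaries shorter than that count as point contact.
- The bisection in `water_level_alloc()` runs to a 1e-12 relative
  tolerance on the allocated total (at most 200 halvings).
- Degenerate cases with defined behaviour: empty admin layer (all pixels
  outside), units covering no pixel centre (warned, zero population, then
  treated like any zero-population unit), all-pixels-masked units
  (zero-population policy), countries whose raw sum is zero against a
  positive reference total (fatal: there is no defensible way to spread a
  national total over units with no information), nodata population
  pixels (contribute 0 to zonal sums, written back as nodata).

## File formats

Rasters are single-band plain-text Esri ASCII grids with full
double-precision values, so write→read round trips are exact; the format
is directly readable by GDAL, QGIS and R spatial stacks. Vector layers are
GeoJSON with `unit_id`, `country`, `level` properties (Polygon and
MultiPolygon). Census, totals, group-map and bbox tables are plain CSV
(UTF-8, "." decimal, empty field = missing). The per-unit report CSV ships
with a `legend.csv` describing every column, and each run writes an
imputation log recording, per imputed unit, the donor list and the
function applied ("mean").

## Known limitations

- One coordinate frame: no reprojection, no latitude-dependent pixel
  areas.
- The production and harvested-area layers are not jointly constrained, so
  an individual pixel's implied yield can exceed the nominal bound when
  one layer is capped and the other is not — faithful to the method, but
  worth knowing before computing per-pixel yields.
- Imputed units add mass on top of the national reference total (their
  rate is a neighbour mean, not a share of the national total); the report
  and `validate_outputs()` account for this explicitly.
- Rasterisation cost is O(pixels × units × vertices); fine for country
  workloads with simple polygons, but the package makes no claim of
  handling continental vertex-heavy boundary files quickly.
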