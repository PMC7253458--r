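# dasycrop

Dasymetric disaggregation of administrative crop statistics onto a ~1 km
population grid.

Sub-national crop statistics (production in tonnes, harvested area in
hectares) are usually published per administrative unit, from censuses taken
in different years. `dasycrop` turns such zonal totals into per-pixel
surfaces under the assumption that the **rural population** is the main
driver of where a subsistence crop is grown, with a linear
population–production relationship up to a per-pixel capacity. The method
was developed for mapping cassava in sub-Saharan Africa; the package
implements it generically, for anyone who needs population-weighted,
capacity-capped downscaling of zonal counts.

## The model

For each administrative unit *u* in country *c* with raw census value
`raw_u` and national reference-year total `ref_c`:

1. **Urban masking.** Pixels with population density strictly above 5,000
   people per ~1 km² pixel are treated as urban and get allocation weight 0
   (pixels exactly at the threshold remain rural).
2. **Standardisation.** `adj_u = raw_u / Σ_{v∈c} raw_v × ref_c`, so each
   country's unit values sum to its reference-year national total.
3. **Per-capita rate.** `rate_u = adj_u / pop_u`, where `pop_u` is the
   unit's rural population summed over its pixels.
4. **Linear allocation.** Each pixel *i* in *u* receives
   `alloc_i = rate_u × pop_i`.
5. **Capped redistribution ("water-filling").** No pixel may exceed 50 ha of
   harvested area (half the pixel) or 1,000 t of production (20 t/ha on
   50 ha). Pixels above the cap are clipped and the excess is redistributed
   among still-uncapped pixels proportionally to population, iterating until
   no pixel exceeds the cap. The fixed point is
   `alloc_i = min(cap, λ·pop_i)` with the water level λ chosen so the unit
   total is conserved.
6. **Missing data.** Units without a census value get the unweighted mean
   per-capita rate of their same-country adjacent units (or of a
   user-declared unit group); declared bounding boxes covered by no unit can
   be gap-filled at a constant per-capita rate (default 0.02).

A seeded synthetic-landscape generator (`make_landscape()`,
`make_census()`, `simulate_bundle()`) produces population surfaces, admin
hierarchies and census tables with known per-pixel truth, so every stage is
testable without proprietary population or census data.

## Worked example

The `analysis/` scripts run the whole study on a synthetic landscape:

```sh
Rscript analysis/01_simulate.R      # build the input bundle + truth grids
Rscript analysis/02_disaggregate.R  # run both layers
Rscript analysis/03_validate.R      # check caps and conservation
```

`01_simulate.R` builds a 40 × 40 pixel, two-country, eight-unit landscape
(total population 909,468; 51 urban pixels masked; unit `C1_U3` blanked in
the census; per-country census jitter 1.154 and 0.914, so raw country sums
disagree with the reference totals and step 2 is exercised). `02` then
prints, for the production layer:

```
disaggregation (production): 8 units, total allocated 233745
  imputed: 1; infeasible: 0; zero-population: 0; bbox-added: 0
```

and `03_validate.R` summarises:

```
 quantity_kind  cap max_pixel allocated_total reference_total n_units n_imputed valid
    production 1000      1000       233744.75       226701.61       8         1  TRUE
harvested_area   50        50        18990.66        18233.68       8         1  TRUE
```

Reading the numbers: the maximum pixel sits exactly at the cap (some pixels
saturated and their excess was redistributed); the allocated total exceeds
the reference total by exactly the mass of the one imputed unit, whose rate
came from its neighbours rather than from the national total; `valid = TRUE`
means every pixel respects the cap and country sums reconcile with the
reference totals after accounting for imputation.

In code, the core primitive looks like this:

```r
library(dasycrop)
pops <- c(1000, rep(100, 9))                    # one crowded pixel
lin  <- allocate_linear(400 / sum(pops), pops)  # 400 ha over 1,900 people
redistribute_capped(lin, pops, cap = 50)$alloc
#>  [1] 50.00000 38.88889 38.88889 ... (max exactly 50, total still 400)
```

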