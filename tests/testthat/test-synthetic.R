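test_that("the generator is bit-reproducible and exercises the urban mask", {
  p <- synth_params(seed = 9, missing_fraction = 0.2)
  a <- make_landscape(p)
  b <- make_landscape(p)
  expect_identical(a$pop$values, b$pop$values)
  expect_identical(a$true_rates, b$true_rates)
  expect_identical(a$truth$production$values, b$truth$production$values)
  expect_identical(make_census(a)$census, make_census(b)$census)
  # hotspot peak above the threshold guarantees masked pixels exist
  rural <- mask_urban(a$pop, p$urban_threshold)
  expect_gt(sum(a$pop$values > p$urban_threshold), 0)
  expect_true(all(rural$values[a$pop$values > p$urban_threshold] == 0))
  expect_error(synth_params(hotspot_peak = 100, urban_threshold = 5000))
  expect_error(make_landscape(synth_params(n_rows = 2, n_cols = 2,
                                           units_per_country = 9)),
               "too small|too narrow")
})

test_that("truth grids are conserved against generated reference totals", {
  p <- synth_params(seed = 13, census_scale_jitter = c(1, 1))
  ls <- make_landscape(p)
  cz <- make_census(ls)
  ctry <- vapply(ls$layer$units, `[[`, "", "country")
  ids <- vapply(ls$layer$units, `[[`, "", "unit_id")
  for (k in c("production", "harvested_area")) {
    for (cc in unique(ctry)) {
      tsum <- sum(ls$truth[[k]]$values[ls$zones$values %in% ids[ctry == cc]],
                  na.rm = TRUE)
      ref <- cz$totals$reference_value[cz$totals$country == cc &
                                         cz$totals$quantity_kind == k]
      expect_equal(tsum, ref, tolerance = 1e-9)
      # jitter 1: raw census sums equal reference totals too
      raw <- sum(cz$census$value[cz$census$country == cc &
                                   cz$census$quantity_kind == k])
      expect_equal(raw, ref, tolerance = 1e-9)
    }
  }
})

test_that("census jitter rescales raw values; standardisation undoes it", {
  p <- synth_params(seed = 17, census_scale_jitter = c(2, 2))
  ls <- make_landscape(p)
  cz <- make_census(ls)
  adj <- standardize_to_national(cz$census, cz$totals)
  # jitter 2 doubles every raw value, so adjusted = raw / 2
  expect_equal(adj$adjusted_value, cz$census$value / 2, tolerance = 1e-9)
})

test_that("missing_fraction blanks a seeded count, never a whole country", {
  p <- synth_params(seed = 23, n_countries = 2, units_per_country = 5,
                    missing_fraction = 0.2)
  ls <- make_landscape(p)
  cz <- make_census(ls)
  expect_length(cz$missing_units, 2)  # 0.2 of 10 units
  prod <- cz$census[cz$census$quantity_kind == "production", ]
  expect_equal(sort(prod$unit_id[is.na(prod$value)]), sort(cz$missing_units))
  for (cc in unique(prod$country))
    expect_gt(sum(!is.na(prod$value[prod$country == cc])), 0)
})

test_that("the pipeline recovers synthetic per-pixel truth", {
  for (seed in c(3, 31)) {
    p <- synth_params(seed = seed)
    ls <- make_landscape(p)
    cz <- make_census(ls)
    for (k in c("production", "harvested_area")) {
      res <- disaggregate(ls$pop, ls$layer, cz$census, cz$totals, kind = k,
                          config = p$config)
      expect_identical(is.na(res$grid$values), is.na(ls$truth[[k]]$values))
      expect_lt(max(abs(res$grid$values - ls$truth[[k]]$values),
                    na.rm = TRUE), 1e-6)
    }
  }
})

test_that("imputed units stay within donor-rate bounds times population", {
  p <- synth_params(seed = 29, missing_fraction = 0.25)
  ls <- make_landscape(p)
  cz <- make_census(ls)
  res <- disaggregate(ls$pop, ls$layer, cz$census, cz$totals,
                      kind = "production", config = p$config)
  for (i in seq_len(nrow(res$imputation_log))) {
    uid <- res$imputation_log$unit_id[i]
    donors <- strsplit(res$imputation_log$donors[i], ";")[[1]]
    dr <- res$report$rate[match(donors, res$report$unit_id)]
    upix <- sum(res$grid$values[ls$zones$values == uid], na.rm = TRUE)
    upop <- ls$zonal[[uid]]
    expect_gte(upix, min(dr) * upop - 1e-6)
    expect_lte(upix, max(dr) * upop + 1e-6)
  }
})
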