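test_that("allocation config enforces the cap/yield relationship", {
  cfg <- allocation_config()
  expect_equal(cfg$urban_threshold, 5000)
  expect_equal(cfg$cap_harvested_area, 50)
  expect_equal(cfg$cap_production, 1000)
  expect_equal(cfg$implied_max_yield, 20)
  expect_equal(cfg$cap_production,
               cfg$implied_max_yield * cfg$cap_harvested_area)
  expect_error(allocation_config(cap_production = 900), "implied_max_yield")
  expect_error(allocation_config(cap_harvested_area = -1))
})

test_that("linear allocation multiplies population by the per-capita rate", {
  expect_equal(allocate_linear(0.2, c(10, 0, 90)), c(2, 0, 18))
  expect_equal(allocate_linear(0, c(5, 5)), c(0, 0))
  expect_equal(allocate_linear(1.2, c(10, 10, 80)), c(12, 12, 96))
  expect_equal(sum(allocate_linear(0.37, 1:20)), 0.37 * sum(1:20))
  expect_error(allocate_linear(-0.1, c(1, 2)), "non-negative")
  expect_error(allocate_linear(0.1, c(-1, 2)), "non-negative")
})

test_that("capped redistribution clips at the cap and conserves the total", {
  # one hand iteration: pixel 3 exceeds cap by 46, split between pixels
  # 1 and 2 in proportion to their (equal) populations
  r <- redistribute_capped(c(12, 12, 96), c(10, 10, 80), cap = 50)
  expect_equal(r$alloc, c(35, 35, 50))
  expect_equal(r$residual, 0)
  expect_equal(r$n_capped, 1)
  expect_equal(sum(r$alloc), 120)

  # feasible input is a fixed point: zero iterations, unchanged
  r0 <- redistribute_capped(c(10, 20, 30), c(1, 2, 3), cap = 50)
  expect_equal(r0$alloc, c(10, 20, 30))
  expect_equal(r0$iterations, 0)

  # infeasible: capacity 150 < total 200; every pixel at cap, residual 50
  ri <- redistribute_capped(c(100, 60, 40), c(5, 3, 2), cap = 50)
  expect_equal(ri$alloc, c(50, 50, 50))
  expect_equal(ri$residual, 50)
  expect_error(
    redistribute_capped(c(100, 60, 40), c(5, 3, 2), 50,
                        infeasible_policy = "error"), "infeasible")
  expect_error(redistribute_capped(c(1, 2), c(1, 1), cap = 0), "positive")
})

test_that("redistribution matches the water-level closed form (property)", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(1:12, 1)
    pops <- round(runif(n, 0, 2000))
    if (sum(pops) == 0) pops[1] <- 100
    cap <- runif(1, 10, 1000)
    rate <- runif(1, 0, 3 * cap / max(1, max(pops)))
    lin <- allocate_linear(rate, pops)
    red <- redistribute_capped(lin, pops, cap, tol = 1e-12)
    oracle <- water_level_alloc(sum(lin), pops, cap, tol = 1e-14)
    expect_equal(red$alloc, oracle, tolerance = 1e-8)
    expect_lte(max(red$alloc), cap + 1e-8)
    expect_lte(red$iterations, n)
    # monotonicity: larger population never receives less
    o <- order(pops)
    expect_true(all(diff(red$alloc[o]) >= -1e-9))
    # conservation or reported residual
    expect_equal(sum(red$alloc) + red$residual, sum(lin), tolerance = 1e-8)
    # redistribution is idempotent on its own output
    again <- redistribute_capped(red$alloc, pops, cap, tol = 1e-12)
    expect_equal(again$alloc, red$alloc, tolerance = 1e-10)
  }
})

test_that("equal pixel populations give the min(cap, total/n) closed form", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    total <- runif(1, 0, 2 * n * 50)
    feasible <- total <= n * 50
    red <- redistribute_capped(rep(total / n, n), rep(10, n), cap = 50)
    if (feasible)
      expect_equal(red$alloc, rep(min(50, total / n), n), tolerance = 1e-9)
    else
      expect_equal(red$alloc, rep(50, n))
  }
})

test_that("end-to-end disaggregation conserves national totals", {
  p <- synth_params(seed = 21, n_countries = 2, units_per_country = 4)
  ls <- make_landscape(p)
  cz <- make_census(ls)
  for (kind in c("production", "harvested_area")) {
    res <- disaggregate(ls$pop, ls$layer, cz$census, cz$totals, kind = kind)
    ctry <- vapply(ls$layer$units, `[[`, "", "country")
    for (cc in unique(ctry)) {
      uu <- vapply(ls$layer$units, `[[`, "", "unit_id")[ctry == cc]
      got <- sum(res$grid$values[ls$zones$values %in% uu], na.rm = TRUE)
      ref <- cz$totals$reference_value[cz$totals$country == cc &
                                         cz$totals$quantity_kind == kind]
      expect_equal(got, ref, tolerance = 1e-9)
    }
    # cap compliance everywhere
    cap <- if (kind == "production") 1000 else 50
    expect_lte(max(res$grid$values, na.rm = TRUE), cap + 1e-9)
  }
})

test_that("a missing unit receives its imputed rate times pixel population", {
  # 3-unit chain; middle unit has no census value, ends have data
  spec <- tiny_spec(3, 4)
  layer <- chain_layer(spec)
  set.seed(3)
  pop <- population_grid(spec, matrix(rpois(12, 80), 3, 4))
  census <- census_records(c("A", "C"), "X", "production", c(100, 300))
  zones <- rasterize_admin(layer, spec)
  zonal <- zonal_population(pop, zones)
  totals <- national_totals("X", "production", 400)
  res <- disaggregate(pop, layer, census, totals, kind = "production")
  # hand composition: adjusted values equal raw (sum = reference), donor
  # rates from A and C, B's rate their unweighted mean
  rate_a <- 100 / zonal[["A"]]
  rate_c <- 300 / zonal[["C"]]
  rate_b <- mean(c(rate_a, rate_c))
  rb <- res$report[res$report$unit_id == "B", ]
  expect_true(rb$imputed)
  expect_equal(rb$rate, rate_b, tolerance = 1e-12)
  bpix <- which(zones$values == "B")
  expect_equal(res$grid$values[bpix], rate_b * pop$values[bpix],
               tolerance = 1e-12)
  expect_equal(res$imputation_log$donors, "A;C")
})

test_that("all-urban units follow the zero-population policy", {
  spec <- tiny_spec(2, 4)
  layer <- admin_layer(list(px_rect("U", "X", spec, 1, 1, 1, 4),
                            px_rect("R", "X", spec, 2, 2, 1, 4)))
  vals <- rbind(rep(9000, 4), rep(100, 4))  # unit U entirely urban
  pop <- population_grid(spec, vals)
  census <- census_records(c("U", "R"), "X", "production", c(40, 60))
  totals <- national_totals("X", "production", 100)
  expect_warning(
    res <- disaggregate(pop, layer, census, totals, kind = "production"),
    "zero rural population")
  ru <- res$report[res$report$unit_id == "U", ]
  expect_equal(ru$status, "zero-population")
  # uniform spread over the unit's 4 pixels, conservation kept
  expect_equal(res$grid$values[1, ], rep(10, 4))
  expect_equal(sum(res$grid$values), 100)

  cfg <- allocation_config(zero_population_policy = "leave-unallocated")
  res2 <- disaggregate(pop, layer, census, totals, kind = "production",
                       config = cfg)
  expect_equal(res2$grid$values[1, ], rep(0, 4))
  expect_equal(res2$report$residual[res2$report$unit_id == "U"], 40)
})
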