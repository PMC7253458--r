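test_that("adjacency requires a shared boundary of positive length", {
  spec <- tiny_spec(3, 4)
  adj <- adjacency(chain_layer(spec))
  expect_setequal(adj$A, "B")
  expect_setequal(adj$B, c("A", "C"))
  expect_setequal(adj$C, "B")

  # corner touch only: not adjacent
  corner <- admin_layer(list(px_rect("P", "X", spec, 1, 1, 1, 2),
                             px_rect("Q", "X", spec, 2, 2, 3, 4)))
  expect_length(adjacency(corner)$P, 0)

  # 3x3 grid of squares: centre has 4 rook neighbours, corners have 2
  s9 <- tiny_spec(3, 3)
  cells <- list()
  for (r in 1:3) for (c in 1:3)
    cells[[length(cells) + 1]] <- px_rect(sprintf("r%dc%d", r, c), "X",
                                          s9, r, r, c, c)
  a9 <- adjacency(admin_layer(cells))
  expect_setequal(a9$r2c2, c("r1c2", "r3c2", "r2c1", "r2c3"))
  expect_setequal(a9$r1c1, c("r1c2", "r2c1"))
  # symmetry and irreflexivity
  for (u in names(a9)) {
    expect_false(u %in% a9[[u]])
    for (v in a9[[u]]) expect_true(u %in% a9[[v]])
  }

  # units of different countries are never adjacent
  two <- admin_layer(list(px_rect("P", "X", spec, 1, 3, 1, 2),
                          px_rect("Q", "Y", spec, 1, 3, 3, 4)))
  expect_length(adjacency(two)$P, 0)
})

make_rates <- function(ids, country, rate, status = NULL) {
  df <- data.frame(unit_id = ids, country = country,
                   quantity_kind = "production",
                   adjusted_value = ifelse(is.na(rate), NA, 1),
                   zonal_pop = 10, rate = rate,
                   status = ifelse(is.na(rate), "missing", "ok"),
                   imputed = FALSE, stringsAsFactors = FALSE)
  if (!is.null(status)) df$status <- status
  df
}

test_that("missing rates are imputed by unweighted donor means", {
  adj <- list(m = c("a", "b"), a = "m", b = "m", c = character(0))
  rates <- make_rates(c("m", "a", "b", "c"), "X", c(NA, 0.1, 0.3, 0.9))
  imp <- impute_missing_rate("m", rates, adj)
  expect_equal(imp$rate, 0.2)
  expect_setequal(imp$donors, c("a", "b"))
  expect_equal(imp$fun, "mean")

  # single donor: mean of one
  r1 <- make_rates(c("m", "a"), "X", c(NA, 0.05))
  expect_equal(impute_missing_rate("m", r1, list(m = "a", a = "m"))$rate, 0.05)

  # group map overrides adjacency donors
  groups <- c(m = "g", p = "g", q = "g", r = "g")
  rg <- make_rates(c("m", "a", "b", "p", "q", "r"), "X",
                   c(NA, 0.1, 0.3, 0.2, 0.4, 0.6))
  impg <- impute_missing_rate("m", rg, adj, groups)
  expect_equal(impg$rate, 0.4)
  expect_equal(impg$strategy, "group")

  # fallback: no adjacent donor with data -> country mean
  iso <- make_rates(c("m", "far"), "X", c(NA, 0.7))
  impf <- impute_missing_rate("m", iso, list(m = character(0)))
  expect_equal(impf$rate, 0.7)
  expect_equal(impf$strategy, "country")

  # same-country restriction: donors never cross the border
  xb <- make_rates(c("m", "f"), c("X", "Y"), c(NA, 0.7))
  expect_error(impute_missing_rate("m", xb, list(m = "f")), "no donor")
})

test_that("batch imputation preserves non-missing rates and donor bounds", {
  set.seed(5)
  for (i in 1:10) {
    n <- 8
    rate <- runif(n, 0, 1)
    rate[sample(n, 2)] <- NA
    ids <- sprintf("u%d", 1:n)
    rates <- make_rates(ids, "X", rate)
    adj <- stats::setNames(lapply(1:n, function(j)
      ids[unique(pmax(1, pmin(n, j + c(-1, 1))))]), ids)
    out <- impute_all_rates(rates, adj)
    keep <- !is.na(rate)
    expect_equal(out$rates$rate[keep], rate[keep])
    expect_false(any(out$rates$imputed[keep]))
    # imputed values lie within the donor range, flags and log set
    for (k in which(is.na(rate))) {
      donors <- strsplit(out$log$donors[out$log$unit_id == ids[k]], ";")[[1]]
      dr <- rate[match(donors, ids)]
      expect_gte(out$rates$rate[k], min(dr))
      expect_lte(out$rates$rate[k], max(dr))
      expect_true(out$rates$imputed[k])
    }
    expect_equal(nrow(out$log), 2)
  }
})

test_that("bbox gap-fill writes constant_rate x population into nodata holes", {
  spec <- tiny_spec(2, 3)
  d <- spec$cell_size / 3600
  # unit covers column 1 only; columns 2-3 are outside all units
  layer <- admin_layer(list(px_rect("A", "X", spec, 1, 2, 1, 1)))
  vals <- matrix(NA_real_, 2, 3)
  vals[, 1] <- 5
  grid <- allocation_grid(spec, vals, "production")
  pop <- population_grid(spec, matrix(c(50, 50, 100, 0, 30, NA), 2, 3))
  box <- bbox_fill(spec$origin_lon, spec$origin_lat - 2 * d,
                   spec$origin_lon + 2 * d, spec$origin_lat)  # cols 1-2
  filled <- fill_bbox_gaps(grid, list(box), pop)
  expect_equal(filled$values[1, 2], 0.02 * 100)  # nodata, pop 100
  expect_equal(filled$values[, 1], c(5, 5))      # non-nodata untouched
  expect_true(is.na(filled$values[2, 2]))        # nodata, pop 0: untouched
  expect_true(all(is.na(filled$values[, 3])))    # outside every bbox
  expect_equal(attr(filled, "bbox_added_mass"), 2)

  # bbox entirely off-grid: warning, no-op
  far <- bbox_fill(200, 50, 201, 51, 0.02)
  expect_warning(unchanged <- fill_bbox_gaps(grid, list(far), pop),
                 "outside")
  expect_equal(unchanged$values, grid$values)
})
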