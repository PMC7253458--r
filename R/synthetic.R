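#' Water-level solution of the capped allocation
#'
#' Closed-form fixed point of capped proportional allocation: per-pixel
#' values are `min(cap, lambda * pop)` with the water level `lambda` found
#' by bisection so the total is conserved (or every populated pixel is at
#' cap when the total exceeds capacity). Independent of the iterative
#' redistribution loop; used to build synthetic ground truth and as a
#' cross-check in tests.
#'
#' @param total Unit total to allocate.
#' @param pixel_pops Per-pixel population weights.
#' @param cap Per-pixel capacity.
#' @param tol Convergence tolerance on the allocated total.
#' @return Numeric vector of per-pixel allocations.
#' @export
water_level_alloc <- function(total, pixel_pops, cap, tol = 1e-12) {
  stopifnot(total >= 0, cap > 0, all(pixel_pops >= 0))
  n_slots <- sum(pixel_pops > 0)
  if (total <= 0 || n_slots == 0) return(numeric(length(pixel_pops)))
  if (total >= n_slots * cap) return(ifelse(pixel_pops > 0, cap, 0))
  f <- function(lam) sum(pmin(cap, lam * pixel_pops))
  lo <- 0
  hi <- max(total / sum(pixel_pops), cap / min(pixel_pops[pixel_pops > 0]))
  while (f(hi) < total) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < total) lo <- mid else hi <- mid
    if (abs(f(mid) - total) <= tol * max(1, total)) break
  }
  pmin(cap, ((lo + hi) / 2) * pixel_pops)
}

#' Synthetic-landscape parameters
#'
#' Defines the study conditions the generator emulates: a lognormal rural
#' population background with Gaussian urban hotspots exceeding the urban
#' threshold, a rectangular nested admin partition, per-unit true per-capita
#' rates, per-country census jitter (so country raw sums differ from the
#' reference totals and the standardisation is exercised non-trivially) and
#' a fraction of missing unit records.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_countries,units_per_country Admin hierarchy size.
#' @param n_rows,n_cols,origin_lon,origin_lat,cell_size Grid layout.
#' @param rural_density_mean Mean rural background, people per pixel.
#' @param rural_sdlog Lognormal sdlog of the rural background.
#' @param n_urban_hotspots Number of Gaussian urban bumps on the grid.
#' @param hotspot_peak Peak hotspot population per pixel; must exceed
#'   `urban_threshold` so masking is exercised.
#' @param urban_threshold Urban cutoff used when building truth grids.
#' @param true_rate_range Named list of c(min, max) true per-capita rate
#'   ranges for `production` (t/person) and `harvested_area` (ha/person).
#' @param missing_fraction Fraction of units blanked in the census, in
#'   [0, 1); never blanks every unit of a country.
#' @param census_scale_jitter c(min, max) multiplicative factor range; one
#'   factor drawn per country and applied to all its raw census values.
#' @param config An [allocation_config()] supplying the truth caps.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(seed = 1L,
                         n_countries = 2L,
                         units_per_country = 4L,
                         n_rows = 40L, n_cols = 40L,
                         origin_lon = 30, origin_lat = 0,
                         cell_size = 30,
                         rural_density_mean = 120,
                         rural_sdlog = 0.8,
                         n_urban_hotspots = 3L,
                         hotspot_peak = 9000,
                         urban_threshold = 5000,
                         true_rate_range = list(production = c(0.1, 0.5),
                                                harvested_area = c(0.01, 0.05)),
                         missing_fraction = 0,
                         census_scale_jitter = c(0.8, 1.25),
                         config = allocation_config(urban_threshold = urban_threshold)) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1,
            hotspot_peak > urban_threshold,
            length(census_scale_jitter) == 2L,
            all(census_scale_jitter > 0))
  p <- list(seed = as.integer(seed), n_countries = as.integer(n_countries),
            units_per_country = as.integer(units_per_country),
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            origin_lon = origin_lon, origin_lat = origin_lat,
            cell_size = cell_size,
            rural_density_mean = rural_density_mean,
            rural_sdlog = rural_sdlog,
            n_urban_hotspots = as.integer(n_urban_hotspots),
            hotspot_peak = hotspot_peak,
            urban_threshold = urban_threshold,
            true_rate_range = true_rate_range,
            missing_fraction = missing_fraction,
            census_scale_jitter = census_scale_jitter,
            config = config)
  structure(p, class = "synth_params")
}

# rectangular partition: countries are vertical column bands, units a
# near-square block grid within each band, aligned to pixel edges
synth_partition <- function(params) {
  spec <- grid_spec(params$origin_lon, params$origin_lat,
                    params$n_rows, params$n_cols, params$cell_size)
  d <- cell_deg(spec)
  col_breaks <- round(seq(0, params$n_cols, length.out = params$n_countries + 1L))
  units <- list()
  for (ci in seq_len(params$n_countries)) {
    c0 <- col_breaks[ci]; c1 <- col_breaks[ci + 1L]
    if (c1 - c0 < 1L) stop("grid too narrow for requested countries")
    nr_blk <- floor(sqrt(params$units_per_country))
    nc_blk <- ceiling(params$units_per_country / nr_blk)
    rb <- round(seq(0, params$n_rows, length.out = nr_blk + 1L))
    cb <- round(seq(c0, c1, length.out = nc_blk + 1L))
    k <- 0L
    for (ri in seq_len(nr_blk)) for (cj in seq_len(nc_blk)) {
      k <- k + 1L
      if (k > params$units_per_country) break
      if (rb[ri + 1L] - rb[ri] < 1L || cb[cj + 1L] - cb[cj] < 1L)
        stop("grid too small for requested units per country")
      units[[length(units) + 1L]] <- rect_unit(
        sprintf("C%d_U%d", ci, k), sprintf("C%d", ci), 1L,
        xmin = spec$origin_lon + cb[cj] * d,
        xmax = spec$origin_lon + cb[cj + 1L] * d,
        ymin = spec$origin_lat - rb[ri + 1L] * d,
        ymax = spec$origin_lat - rb[ri] * d)
    }
    if (k < params$units_per_country)
      stop("grid too small for requested units per country")
  }
  list(spec = spec, layer = admin_layer(units))
}

#' Generate a synthetic landscape with known ground truth
#'
#' Builds a population surface (lognormal rural background plus Gaussian
#' urban hotspots), a rectangular admin partition, per-unit true per-capita
#' rates, and per-pixel truth allocation grids computed as rate x rural
#' population with the configured caps applied through the independent
#' water-level oracle. Bit-reproducible for a fixed seed.
#'
#' @param params A [synth_params()].
#' @return A list of class `synth_landscape`: `pop` ([population_grid()]),
#'   `layer` ([admin_layer()]), `zones`, `zonal` (rural zonal sums),
#'   `true_rates` (`data.frame`: unit_id, country, quantity_kind, rate),
#'   `truth` (named list of [allocation_grid()] per kind), `params`.
#' @export
make_landscape <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  part <- synth_partition(params)
  spec <- part$spec
  n <- spec$n_rows * spec$n_cols

  mlog <- log(params$rural_density_mean) - params$rural_sdlog^2 / 2
  vals <- matrix(stats::rlnorm(n, mlog, params$rural_sdlog),
                 spec$n_rows, spec$n_cols)
  if (params$n_urban_hotspots > 0L) {
    hr <- stats::runif(params$n_urban_hotspots, 1, spec$n_rows)
    hc <- stats::runif(params$n_urban_hotspots, 1, spec$n_cols)
    sig <- stats::runif(params$n_urban_hotspots, 1.2, 2.5)
    rows <- matrix(seq_len(spec$n_rows), spec$n_rows, spec$n_cols)
    cols <- matrix(seq_len(spec$n_cols), spec$n_rows, spec$n_cols, byrow = TRUE)
    for (h in seq_len(params$n_urban_hotspots)) {
      d2 <- (rows - hr[h])^2 + (cols - hc[h])^2
      vals <- vals + params$hotspot_peak * exp(-d2 / (2 * sig[h]^2))
    }
  }
  pop <- population_grid(spec, vals)
  rural <- mask_urban(pop, params$urban_threshold)
  zones <- rasterize_admin(part$layer, spec)
  zonal <- zonal_population(rural, zones)

  kinds <- names(params$true_rate_range)
  ids <- unit_ids(part$layer)
  ctry <- unit_countries(part$layer)
  true_rates <- do.call(rbind, lapply(kinds, function(k) {
    rr <- params$true_rate_range[[k]]
    data.frame(unit_id = ids, country = as.character(ctry[ids]),
               quantity_kind = k,
               rate = stats::runif(length(ids), rr[1], rr[2]),
               stringsAsFactors = FALSE)
  }))

  rp <- rural$values
  rp[is.na(rp)] <- 0
  truth <- lapply(kinds, function(k) {
    cap <- cap_for_kind(params$config, k)
    v <- matrix(NA_real_, spec$n_rows, spec$n_cols)
    rt <- true_rates[true_rates$quantity_kind == k, ]
    for (i in seq_len(nrow(rt))) {
      px <- which(zones$values == rt$unit_id[i])
      if (!length(px)) next
      v[px] <- water_level_alloc(rt$rate[i] * sum(rp[px]), rp[px], cap)
    }
    allocation_grid(spec, v, k)
  })
  names(truth) <- kinds
  structure(list(pop = pop, layer = part$layer, zones = zones, zonal = zonal,
                 true_rates = true_rates, truth = truth, params = params),
            class = "synth_landscape")
}

#' Generate census tables from a synthetic landscape
#'
#' Raw unit values are zonal sums of the truth grids multiplied by a
#' per-country jitter factor (so country raw sums differ from the reference
#' totals and the rescaling is non-trivial); reference totals are the true
#' country sums. A `missing_fraction` of units is blanked at random
#' (seeded), never blanking every unit of a country.
#'
#' @param landscape A `synth_landscape` from [make_landscape()].
#' @param params A [synth_params()] (defaults to the landscape's own).
#' @return A list: `census` ([census_records()] table, both kinds),
#'   `totals` ([national_totals()] table), `jitter` (named per-country
#'   factors), `missing_units` (character vector of blanked unit_ids).
#' @export
make_census <- function(landscape, params = landscape$params) {
  stopifnot(inherits(landscape, "synth_landscape"))
  set.seed(params$seed + 1L)
  ids <- unit_ids(landscape$layer)
  ctry <- unit_countries(landscape$layer)
  countries <- unique(as.character(ctry))
  jit <- stats::setNames(
    stats::runif(length(countries), params$census_scale_jitter[1],
                 params$census_scale_jitter[2]), countries)

  n_missing <- round(params$missing_fraction * length(ids))
  missing_units <- character(0)
  if (n_missing > 0L) {
    pool <- sample(ids)
    remaining <- table(ctry[ids])
    for (uid in pool) {
      if (length(missing_units) >= n_missing) break
      cc <- ctry[[uid]]
      if (remaining[[cc]] <= 1L) next  # keep at least one unit with data
      missing_units <- c(missing_units, uid)
      remaining[[cc]] <- remaining[[cc]] - 1L
    }
  }

  kinds <- names(landscape$truth)
  census <- do.call(rbind, lapply(kinds, function(k) {
    v <- landscape$truth[[k]]$values
    zsum <- vapply(ids, function(uid)
      sum(v[which(landscape$zones$values == uid)], na.rm = TRUE), 0)
    raw <- zsum * jit[as.character(ctry[ids])]
    raw[ids %in% missing_units] <- NA_real_
    census_records(ids, as.character(ctry[ids]), k, raw,
                   year = 2010L, source = "synthetic")
  }))
  totals <- do.call(rbind, lapply(kinds, function(k) {
    v <- landscape$truth[[k]]$values
    ref <- vapply(countries, function(cc) {
      uu <- ids[ctry[ids] == cc]
      sum(v[which(landscape$zones$values %in% uu)], na.rm = TRUE)
    }, 0)
    national_totals(countries, k, ref, 2014L)
  }))
  list(census = census, totals = totals, jitter = jit,
       missing_units = missing_units)
}
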