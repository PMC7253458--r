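#' Allocation configuration
#'
#' Holds the disaggregation parameters. Defaults are the standard study
#' parameters: urban cutoff 5,000 people per ~1 km^2 pixel; at most half a
#' pixel (approx. 50 ha) harvested; production per hectare at most 20 t/ha,
#' hence a per-pixel production cap of 1,000 t. The production cap must
#' equal `implied_max_yield * cap_harvested_area`.
#'
#' @param urban_threshold People per pixel above which a pixel is urban.
#' @param cap_harvested_area Per-pixel harvested-area cap, hectares.
#' @param cap_production Per-pixel production cap, tonnes.
#' @param implied_max_yield Maximum yield, tonnes per hectare.
#' @param convergence_tol Absolute tolerance on cap violations and residuals.
#' @param infeasible_policy What to do when a unit's total exceeds its pixel
#'   capacity: `"cap-and-report"` (every populated pixel at cap, residual
#'   reported) or `"error"`.
#' @param zero_population_policy Units with zero rural population but a
#'   positive total: `"uniform-spread"` (equal split over the unit's pixels,
#'   still capped) or `"leave-unallocated"`.
#' @return An object of class `allocation_config`.
#' @export
allocation_config <- function(urban_threshold = 5000,
                              cap_harvested_area = 50,
                              cap_production = 1000,
                              implied_max_yield = 20,
                              convergence_tol = 1e-9,
                              infeasible_policy = c("cap-and-report", "error"),
                              zero_population_policy = c("uniform-spread",
                                                         "leave-unallocated")) {
  infeasible_policy <- match.arg(infeasible_policy)
  zero_population_policy <- match.arg(zero_population_policy)
  stopifnot(urban_threshold > 0, cap_harvested_area > 0, cap_production > 0,
            implied_max_yield > 0, convergence_tol > 0)
  if (abs(cap_production - implied_max_yield * cap_harvested_area) >
      1e-9 * cap_production)
    stop("cap_production must equal implied_max_yield * cap_harvested_area")
  structure(list(urban_threshold = urban_threshold,
                 cap_harvested_area = cap_harvested_area,
                 cap_production = cap_production,
                 implied_max_yield = implied_max_yield,
                 convergence_tol = convergence_tol,
                 infeasible_policy = infeasible_policy,
                 zero_population_policy = zero_population_policy),
            class = "allocation_config")
}

cap_for_kind <- function(config, kind) {
  switch(kind,
         production = config$cap_production,
         harvested_area = config$cap_harvested_area,
         stop("unknown quantity kind: ", kind))
}

#' Linear per-capita allocation
#'
#' Multiplies each pixel's population by the per-capita rate, so the unit
#' total is spread proportionally to population.
#'
#' @param rate Per-capita rate (quantity per person), >= 0.
#' @param pixel_pops Numeric vector of per-pixel people counts, >= 0.
#' @return Numeric vector of per-pixel quantities; its sum is
#'   `rate * sum(pixel_pops)`.
#' @export
allocate_linear <- function(rate, pixel_pops) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("rate must be a single non-negative number")
  if (any(pixel_pops < 0, na.rm = TRUE))
    stop("pixel populations must be non-negative")
  rate * pixel_pops
}

#' Capped redistribution of excess allocation ("water-filling")
#'
#' Iteratively clips per-pixel allocations at `cap` and redistributes the
#' excess among the still-uncapped pixels proportionally to their
#' population weight, until no pixel exceeds the cap or every weighted
#' pixel is capped. Each iteration caps at least one new pixel, so the loop
#' terminates in at most `length(alloc)` iterations. When the unit total
#' fits (`sum(alloc) <= n_weighted_pixels * cap`) the total is conserved;
#' otherwise the infeasible branch sets every weighted pixel to `cap` and
#' reports the unallocatable remainder as `residual`.
#'
#' @param alloc Initial per-pixel allocation (from [allocate_linear()]).
#' @param pixel_pops Redistribution weights (per-pixel population).
#' @param cap Per-pixel capacity, > 0.
#' @param tol Absolute tolerance for cap violations.
#' @param infeasible_policy `"cap-and-report"` or `"error"`.
#' @return A list: `alloc` (final vector), `iterations`, `residual`
#'   (unallocated mass, 0 in the feasible case), `n_capped`.
#' @export
redistribute_capped <- function(alloc, pixel_pops, cap, tol = 1e-9,
                                infeasible_policy = "cap-and-report") {
  if (!is.numeric(cap) || length(cap) != 1L || is.na(cap) || cap <= 0)
    stop("cap must be a single positive number")
  stopifnot(length(alloc) == length(pixel_pops))
  n_slots <- sum(pixel_pops > 0)
  total <- sum(alloc)
  if (total > n_slots * cap + tol) {
    if (infeasible_policy == "error")
      stop(sprintf("infeasible: total %g exceeds capacity %g", total,
                   n_slots * cap))
    out <- ifelse(pixel_pops > 0, cap, 0)
    return(list(alloc = out, iterations = 0L,
                residual = total - n_slots * cap, n_capped = n_slots))
  }
  x <- alloc
  capped <- logical(length(x))
  it <- 0L
  repeat {
    over <- !capped & x > cap + tol
    if (!any(over)) break
    it <- it + 1L
    excess <- sum(x[over] - cap)
    x[over] <- cap
    capped <- capped | over
    w <- ifelse(capped, 0, pixel_pops)
    sw <- sum(w)
    if (sw <= 0) break  # everything capped; feasibility check above makes excess ~0
    x <- x + excess * w / sw
  }
  list(alloc = x, iterations = it,
       residual = max(0, total - sum(pmin(x, cap))),
       n_capped = sum(capped))
}

#' End-to-end dasymetric disaggregation
#'
#' Runs the full pipeline for one quantity kind: urban masking,
#' rasterisation, zonal population, standardisation to national totals,
#' per-capita rates, imputation of missing rates, per-unit linear
#' allocation with capped redistribution, and optional bounding-box
#' gap-filling.
#'
#' @param pop A [population_grid()].
#' @param layer An [admin_layer()] in the same coordinate frame.
#' @param census Census table ([census_records()]); may hold both kinds.
#' @param totals National totals ([national_totals()]).
#' @param kind `"production"` or `"harvested_area"`.
#' @param groups Optional named character vector, unit_id -> group label,
#'   overriding adjacency-based imputation donors.
#' @param bboxes Optional list of [bbox_fill()] gap fills.
#' @param config An [allocation_config()].
#' @return A list of class `disaggregation`:
#'   `grid` (an [allocation_grid()], nodata outside all units),
#'   `report` (per-unit `data.frame`: unit_id, country, quantity_kind,
#'   adjusted_value, zonal_pop, rate, imputed, n_pixels, n_capped,
#'   iterations, residual, status), `imputation_log`, `config`, and
#'   `bbox_added_mass`.
#' @export
disaggregate <- function(pop, layer, census, totals,
                         kind = c("production", "harvested_area"),
                         groups = NULL, bboxes = NULL,
                         config = allocation_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(pop, "population_grid"), inherits(layer, "admin_layer"),
            inherits(config, "allocation_config"))
  rural <- mask_urban(pop, config$urban_threshold)
  zones <- rasterize_admin(layer, pop$spec)
  zonal <- zonal_population(rural, zones)

  recs <- census[census$quantity_kind == kind, , drop = FALSE]
  unknown <- setdiff(recs$unit_id, unit_ids(layer))
  if (length(unknown)) {
    warning("census units absent from admin layer, skipped: ",
            paste(unknown, collapse = ", "))
    recs <- recs[!recs$unit_id %in% unknown, , drop = FALSE]
  }
  # units with no census row are treated as missing records
  absent <- setdiff(unit_ids(layer), recs$unit_id)
  if (length(absent)) {
    ctry <- unit_countries(layer)
    recs <- rbind(recs, census_records(absent, ctry[absent], kind, NA_real_))
  }
  adjusted <- standardize_to_national(recs, totals)
  rates <- per_capita_rates(adjusted, zonal)
  imp <- impute_all_rates(rates, adjacency(layer), groups)
  rates <- imp$rates

  cap <- cap_for_kind(config, kind)
  vals <- matrix(NA_real_, pop$spec$n_rows, pop$spec$n_cols)
  report <- rates[c("unit_id", "country", "quantity_kind", "adjusted_value",
                    "zonal_pop", "rate", "imputed", "status")]
  report$n_pixels <- 0L
  report$n_capped <- 0L
  report$iterations <- 0L
  report$residual <- 0

  rp <- rural$values
  rp[is.na(rp)] <- 0
  for (i in seq_len(nrow(rates))) {
    uid <- rates$unit_id[i]
    px <- which(zones$values == uid)
    report$n_pixels[i] <- length(px)
    if (!length(px)) next
    pops <- rp[px]
    if (rates$status[i] == "undefined") {
      # positive total, zero rural population: policy decides
      if (config$zero_population_policy == "leave-unallocated") {
        vals[px] <- 0
        report$residual[i] <- rates$adjusted_value[i]
        report$status[i] <- "zero-population"
        next
      }
      warning(sprintf(
        "unit '%s' has zero rural population; spreading %g uniformly",
        uid, rates$adjusted_value[i]))
      w <- rep(1, length(px))
      lin <- rep(rates$adjusted_value[i] / length(px), length(px))
      red <- redistribute_capped(lin, w, cap, config$convergence_tol,
                                 config$infeasible_policy)
      report$status[i] <- "zero-population"
    } else {
      lin <- allocate_linear(rates$rate[i], pops)
      red <- redistribute_capped(lin, pops, cap, config$convergence_tol,
                                 config$infeasible_policy)
      if (red$residual > config$convergence_tol) {
        warning(sprintf("unit '%s' infeasible: residual %g %s left unallocated",
                        uid, red$residual,
                        if (kind == "production") "t" else "ha"))
        report$status[i] <- "infeasible"
      }
    }
    vals[px] <- red$alloc
    report$n_capped[i] <- red$n_capped
    report$iterations[i] <- red$iterations
    report$residual[i] <- red$residual
  }

  grid <- allocation_grid(pop$spec, vals, kind)
  added <- 0
  if (!is.null(bboxes) && length(bboxes)) {
    grid <- fill_bbox_gaps(grid, bboxes, rural)
    added <- attr(grid, "bbox_added_mass")
  }
  structure(list(grid = grid, report = report, imputation_log = imp$log,
                 config = config, bbox_added_mass = added),
            class = "disaggregation")
}

#' @export
print.disaggregation <- function(x, ...) {
  r <- x$report
  cat(sprintf("disaggregation (%s): %d units, total allocated %.6g\n",
              x$grid$quantity_kind, nrow(r),
              sum(x$grid$values, na.rm = TRUE)))
  cat(sprintf("  imputed: %d; infeasible: %d; zero-population: %d; bbox-added: %.6g\n",
              sum(r$imputed), sum(r$status == "infeasible"),
              sum(r$status == "zero-population"), x$bbox_added_mass))
  invisible(x)
}
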