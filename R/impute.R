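#' Impute one missing per-capita rate
#'
#' Fills a missing rate by the unweighted mean of donor rates. Donor
#' preference: an explicit unit-group map (if supplied and covering the
#' unit), then same-country adjacent units with data, then all same-country
#' units with data. The group map is the hook for reproducing curated
#' "same agro-ecological zone" choices that cannot be automated.
#'
#' @param unit_id Unit whose rate is missing.
#' @param rates Rate table from [per_capita_rates()].
#' @param adj Adjacency list from [adjacency()].
#' @param groups Optional named character vector, unit_id -> group label.
#' @return A list: `rate` (the imputed value), `donors` (character vector),
#'   `fun` (always `"mean"`), `strategy` (`group`/`adjacent`/`country`).
#' @export
impute_missing_rate <- function(unit_id, rates, adj, groups = NULL) {
  row <- rates[rates$unit_id == unit_id, ]
  if (!nrow(row)) stop("unknown unit: ", unit_id)
  if (row$status[1L] != "missing")
    stop("unit ", unit_id, " does not have a missing rate")
  cc <- row$country[1L]
  has_data <- !is.na(rates$rate) & rates$country == cc & rates$unit_id != unit_id

  pick <- function(ids) {
    sel <- has_data & rates$unit_id %in% ids
    rates$unit_id[sel]
  }
  donors <- character(0); strategy <- NULL
  if (!is.null(groups) && unit_id %in% names(groups)) {
    g <- groups[[unit_id]]
    members <- names(groups)[groups == g]
    donors <- pick(setdiff(members, unit_id))
    if (length(donors)) strategy <- "group"
  }
  if (!length(donors)) {
    donors <- pick(adj[[unit_id]])
    if (length(donors)) strategy <- "adjacent"
  }
  if (!length(donors)) {
    donors <- rates$unit_id[has_data]
    if (length(donors)) strategy <- "country"
  }
  if (!length(donors))
    stop(sprintf("unit '%s': no donor with data anywhere in country '%s'",
                 unit_id, cc))
  val <- mean(rates$rate[match(donors, rates$unit_id)])
  list(rate = val, donors = donors, fun = "mean", strategy = strategy)
}

#' Impute all missing rates
#'
#' Applies [impute_missing_rate()] to every unit with status `"missing"`,
#' using the original (pre-imputation) rates as the donor pool so the
#' result does not depend on processing order.
#'
#' @inheritParams impute_missing_rate
#' @return A list: `rates` (table with imputed values, `imputed` flag and
#'   status `"ok"`), `log` (a `data.frame` mirroring a missing-data
#'   calculation record: unit_id, quantity_kind, donors (semicolon-joined),
#'   fun, strategy, imputed_rate).
#' @export
impute_all_rates <- function(rates, adj, groups = NULL) {
  todo <- rates$unit_id[rates$status == "missing"]
  log <- data.frame(unit_id = character(0), quantity_kind = character(0),
                    donors = character(0), fun = character(0),
                    strategy = character(0), imputed_rate = numeric(0),
                    stringsAsFactors = FALSE)
  out <- rates
  for (uid in todo) {
    imp <- impute_missing_rate(uid, rates, adj, groups)
    i <- which(out$unit_id == uid)
    out$rate[i] <- imp$rate
    out$imputed[i] <- TRUE
    out$status[i] <- "ok"
    log <- rbind(log, data.frame(
      unit_id = uid, quantity_kind = out$quantity_kind[i],
      donors = paste(imp$donors, collapse = ";"), fun = imp$fun,
      strategy = imp$strategy, imputed_rate = imp$rate,
      stringsAsFactors = FALSE))
  }
  list(rates = out, log = log)
}

#' Bounding-box constant fill
#'
#' @param min_lon,min_lat,max_lon,max_lat Bounding box in degrees.
#' @param constant_rate Per-capita rate applied inside the box (default
#'   0.02 quantity per person).
#' @return An object of class `bbox_fill`.
#' @export
bbox_fill <- function(min_lon, min_lat, max_lon, max_lat,
                      constant_rate = 0.02) {
  stopifnot(min_lon < max_lon, min_lat < max_lat, constant_rate >= 0)
  structure(list(min_lon = min_lon, min_lat = min_lat,
                 max_lon = max_lon, max_lat = max_lat,
                 constant_rate = constant_rate),
            class = "bbox_fill")
}

#' Fill nodata gaps inside declared bounding boxes
#'
#' Pixels covered by no administrative unit (nodata in the allocation grid)
#' that lie inside a declared bounding box and carry rural population
#' receive `constant_rate * rural_population`; all other pixels are
#' untouched. The added mass sits on top of the admin-based allocation
#' (those pixels belong to no unit), so country conservation is
#' intentionally relaxed there; the total added is reported via the
#' `"bbox_added_mass"` attribute.
#'
#' @param grid An [allocation_grid()].
#' @param fills List of [bbox_fill()] objects.
#' @param rural Rural [population_grid()] on the same spec.
#' @return The filled [allocation_grid()] with attribute `bbox_added_mass`.
#' @export
fill_bbox_gaps <- function(grid, fills, rural) {
  stopifnot(inherits(grid, "allocation_grid"))
  if (!same_spec(grid$spec, rural$spec))
    stop("allocation and population grids are not aligned")
  spec <- grid$spec
  ctr <- pixel_centres(spec)
  v <- grid$values
  pop <- rural$values
  added <- 0
  for (f in fills) {
    stopifnot(inherits(f, "bbox_fill"))
    cols <- which(ctr$lon >= f$min_lon & ctr$lon <= f$max_lon)
    rows <- which(ctr$lat >= f$min_lat & ctr$lat <= f$max_lat)
    if (!length(cols) || !length(rows)) {
      warning("bbox fill outside grid extent; skipped")
      next
    }
    sub <- v[rows, cols, drop = FALSE]
    psub <- pop[rows, cols, drop = FALSE]
    tgt <- is.na(sub) & !is.na(psub) & psub > 0
    sub[tgt] <- f$constant_rate * psub[tgt]
    added <- added + sum(sub[tgt])
    v[rows, cols] <- sub
  }
  out <- allocation_grid(spec, v, grid$quantity_kind)
  attr(out, "bbox_added_mass") <- added
  out
}
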