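#' Write a grid as an Esri ASCII raster
#'
#' Plain-text single-band raster (.asc) with the standard six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value), readable
#' by GDAL/QGIS. Values are written at full double precision so the
#' write/read round trip is exact. `NA` pixels are written as the spec's
#' nodata sentinel.
#'
#' @param grid A `dc_grid` (population or allocation grid).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path) {
  stopifnot(inherits(grid, "dc_grid"))
  spec <- grid$spec
  d <- cell_deg(spec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.*g", 17L, spec$origin_lon),
    sprintf("yllcorner %.*g", 17L, spec$origin_lat - spec$n_rows * d),
    sprintf("cellsize %.*g", 17L, d),
    sprintf("NODATA_value %.*g", 17L, spec$nodata)), con)
  v <- grid$values
  v[is.na(v)] <- spec$nodata
  utils::write.table(format(v, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = " ")
  invisible(path)
}

#' Read an Esri ASCII raster
#'
#' @param path File written by [write_asc()] (or any .asc raster).
#' @param kind `"population"` for a [population_grid()], otherwise the
#'   quantity kind of an [allocation_grid()].
#' @return A grid object; nodata pixels are `NA`.
#' @export
read_asc <- function(path, kind = "population") {
  if (!file.exists(path)) stop("no such raster file: ", path)
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2L]), tolower(kv[, 1L]))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(h)))
    stop("malformed ASCII raster header in ", path)
  v <- matrix(scan(path, skip = 6L, quiet = TRUE),
              h[["nrows"]], h[["ncols"]], byrow = TRUE)
  v[v == h[["nodata_value"]]] <- NA_real_
  spec <- grid_spec(origin_lon = h[["xllcorner"]],
                    origin_lat = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]],
                    n_rows = h[["nrows"]], n_cols = h[["ncols"]],
                    cell_size = h[["cellsize"]] * 3600,
                    nodata = h[["nodata_value"]])
  if (kind == "population") population_grid(spec, v)
  else allocation_grid(spec, v, kind)
}

#' Write an admin layer as GeoJSON
#'
#' One Feature per unit with properties `unit_id`, `country`, `level` and a
#' Polygon geometry (first ring outer; additional rings written as further
#' Polygon rings).
#'
#' @param layer An [admin_layer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_admin_geojson <- function(layer, path) {
  feats <- lapply(layer$units, function(u) {
    rings <- lapply(u$rings, function(r) {
      r <- rbind(r, r[1L, ])  # close ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
    })
    list(type = "Feature",
         properties = list(unit_id = u$unit_id, country = u$country,
                           level = u$level),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an admin layer from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; all rings are collected and
#' membership uses the even-odd rule, so holes need no special casing.
#' Features must carry `unit_id`, `country` and `level` properties.
#'
#' @param path GeoJSON file path.
#' @return An [admin_layer()].
#' @export
read_admin_geojson <- function(path) {
  if (!file.exists(path)) stop("no such vector file: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  units <- lapply(seq_along(gj$features), function(i) {
    ft <- gj$features[[i]]
    pr <- ft$properties
    for (fld in c("unit_id", "country", "level"))
      if (is.null(pr[[fld]]))
        stop(sprintf("%s: feature %d lacks required property '%s'",
                     path, i, fld))
    geom <- ft$geometry
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(p) lapply(p, ring_mat)),
                            recursive = FALSE),
      stop(sprintf("%s: feature %d has unsupported geometry '%s'",
                   path, i, geom$type)))
    admin_unit(as.character(pr$unit_id), as.character(pr$country),
               as.integer(pr$level), rings)
  })
  admin_layer(units)
}

read_checked_csv <- function(path, required, label) {
  if (!file.exists(path)) stop("no such ", label, " file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s (%s): missing required column(s): %s",
                 label, path, paste(miss, collapse = ", ")))
  df
}

num_col <- function(df, col, path, allow_na = FALSE, min = -Inf) {
  raw <- df[[col]]
  v <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(v) & !(is.na(raw) | trimws(as.character(raw)) == ""))
  if (length(bad))
    stop(sprintf("%s: column '%s' non-numeric at data row %d (value '%s')",
                 path, col, bad[1L], raw[bad[1L]]))
  if (!allow_na && anyNA(v)) {
    bad <- which(is.na(v))
    stop(sprintf("%s: column '%s' empty at data row %d", path, col, bad[1L]))
  }
  low <- which(!is.na(v) & v < min)
  if (length(low))
    stop(sprintf("%s: column '%s' below %g at data row %d (value %g)",
                 path, col, min, low[1L], v[low[1L]]))
  v
}

#' Read a census CSV
#'
#' Columns: unit_id, country, level, quantity_kind, value (empty = missing),
#' year, source. Negative or non-numeric values are rejected with the
#' offending row number.
#'
#' @param path CSV file path.
#' @return A [census_records()] table.
#' @export
read_census_csv <- function(path) {
  df <- read_checked_csv(path, c("unit_id", "country", "quantity_kind",
                                 "value"), "census table")
  census_records(df$unit_id, df$country, df$quantity_kind,
                 num_col(df, "value", path, allow_na = TRUE, min = 0),
                 year = if ("year" %in% names(df)) df$year else NA_integer_,
                 source = if ("source" %in% names(df)) df$source else NA_character_,
                 level = if ("level" %in% names(df)) df$level else 1L)
}

#' Read a national-totals CSV
#'
#' Columns: country, quantity_kind, reference_value, reference_year.
#'
#' @param path CSV file path.
#' @return A [national_totals()] table.
#' @export
read_totals_csv <- function(path) {
  df <- read_checked_csv(path, c("country", "quantity_kind",
                                 "reference_value"), "national totals")
  national_totals(df$country, df$quantity_kind,
                  num_col(df, "reference_value", path, min = 0),
                  if ("reference_year" %in% names(df)) df$reference_year
                  else 2014L)
}

#' Read a unit-group map CSV (columns: unit_id, group)
#'
#' @param path CSV file path.
#' @return Named character vector, unit_id -> group label.
#' @export
read_groups_csv <- function(path) {
  df <- read_checked_csv(path, c("unit_id", "group"), "unit-group map")
  if (anyDuplicated(df$unit_id))
    stop(path, ": duplicate unit_id in group map")
  stats::setNames(as.character(df$group), df$unit_id)
}

#' Read a bounding-box gap-fill CSV
#'
#' Columns: min_lon, min_lat, max_lon, max_lat, constant_rate.
#'
#' @param path CSV file path.
#' @return List of [bbox_fill()] objects.
#' @export
read_bbox_csv <- function(path) {
  df <- read_checked_csv(path, c("min_lon", "min_lat", "max_lon", "max_lat",
                                 "constant_rate"), "bbox fills")
  lapply(seq_len(nrow(df)), function(i)
    bbox_fill(df$min_lon[i], df$min_lat[i], df$max_lon[i], df$max_lat[i],
              df$constant_rate[i]))
}

#' Read and validate a full input bundle
#'
#' @param population,units,census,totals Required file paths (.asc raster,
#'   GeoJSON, CSVs).
#' @param groups,bboxes Optional file paths.
#' @return A list with elements `pop`, `layer`, `census`, `totals`,
#'   `groups`, `bboxes`, schema-validated and frame-checked.
#' @export
read_inputs <- function(population, units, census, totals,
                        groups = NULL, bboxes = NULL) {
  pop <- read_asc(population, kind = "population")
  layer <- read_admin_geojson(units)
  cen <- read_census_csv(census)
  tot <- read_totals_csv(totals)
  grp <- if (!is.null(groups)) read_groups_csv(groups) else NULL
  bbx <- if (!is.null(bboxes)) read_bbox_csv(bboxes) else NULL
  # frame compatibility: every unit bbox should intersect the raster extent
  spec <- pop$spec
  ext <- c(spec$origin_lon, spec$origin_lat - spec$n_rows * cell_deg(spec),
           spec$origin_lon + spec$n_cols * cell_deg(spec), spec$origin_lat)
  for (u in layer$units) {
    bb <- ring_bbox(u$rings)
    if (bb["xmax"] < ext[1] || bb["xmin"] > ext[3] ||
        bb["ymax"] < ext[2] || bb["ymin"] > ext[4])
      warning(sprintf("unit '%s' lies entirely outside the raster extent",
                      u$unit_id))
  }
  list(pop = pop, layer = layer, census = cen, totals = tot,
       groups = grp, bboxes = bbx)
}

report_legend <- function() {
  data.frame(
    column = c("unit_id", "country", "quantity_kind", "adjusted_value",
               "zonal_pop", "rate", "imputed", "status", "n_pixels",
               "n_capped", "iterations", "residual"),
    description = c(
      "administrative unit identifier",
      "country code",
      "production (tonnes) or harvested_area (hectares)",
      "unit value rescaled to the national reference-year total",
      "rural population sum over the unit's pixels (people)",
      "per-capita rate used for allocation (quantity per person)",
      "TRUE if the rate was imputed from donor units",
      "ok | infeasible | zero-population",
      "number of pixels in the unit",
      "pixels held at the per-pixel cap",
      "redistribution iterations",
      "unallocated mass (0 unless infeasible)"),
    stringsAsFactors = FALSE)
}

#' Write disaggregation outputs
#'
#' Writes `<kind>_grid.asc`, `<kind>_report.csv`, `imputation_log.csv` and
#' `legend.csv` (a header legend for the report columns) to a directory.
#'
#' @param result A `disaggregation` from [disaggregate()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "disaggregation"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kind <- result$grid$quantity_kind
  files <- c(grid = file.path(out_dir, paste0(kind, "_grid.asc")),
             report = file.path(out_dir, paste0(kind, "_report.csv")),
             imputation_log = file.path(out_dir, "imputation_log.csv"),
             legend = file.path(out_dir, "legend.csv"))
  write_asc(result$grid, files["grid"])
  utils::write.csv(result$report, files["report"], row.names = FALSE)
  utils::write.csv(result$imputation_log, files["imputation_log"],
                   row.names = FALSE)
  utils::write.csv(report_legend(), files["legend"], row.names = FALSE)
  invisible(files)
}

#' Validate written outputs
#'
#' Rereads an output directory and asserts cap compliance (no pixel above
#' the applicable cap) and conservation (per-country grid sums match the
#' national reference totals, allowing for reported infeasible residuals,
#' imputed units and bbox-added mass).
#'
#' @param out_dir Directory written by [write_outputs()].
#' @param kind Quantity kind to validate.
#' @param totals [national_totals()] table to check conservation against
#'   (optional; skipped when `NULL`).
#' @param config The [allocation_config()] used for the run.
#' @param bbox_added Mass added by bounding-box gap fills in the run, if
#'   any (it sits outside all units, so it is excluded from conservation).
#' @param tol Absolute tolerance per unit.
#' @return A list: `ok` (logical) and `messages` (character vector of
#'   violations, empty when valid).
#' @export
validate_outputs <- function(out_dir, kind, totals = NULL,
                             config = allocation_config(), bbox_added = 0,
                             tol = 1e-6) {
  grid <- read_asc(file.path(out_dir, paste0(kind, "_grid.asc")), kind = kind)
  report <- utils::read.csv(file.path(out_dir, paste0(kind, "_report.csv")),
                            stringsAsFactors = FALSE)
  msgs <- character(0)
  cap <- cap_for_kind(config, kind)
  mx <- max(grid$values, na.rm = TRUE)
  if (mx > cap + tol)
    msgs <- c(msgs, sprintf("cap violation: max pixel %.6g > cap %g", mx, cap))
  if (any(grid$values < 0, na.rm = TRUE))
    msgs <- c(msgs, "negative allocated values present")
  if (!is.null(totals)) {
    # imputed units add mass beyond the reference totals by design, and
    # infeasible residuals are mass that could not be placed
    alloc_sum <- sum(grid$values, na.rm = TRUE)
    ref_sum <- sum(totals$reference_value[totals$quantity_kind == kind])
    imput_mass <- sum(ifelse(report$imputed %in% TRUE,
                             report$rate * report$zonal_pop, 0), na.rm = TRUE)
    resid <- sum(report$residual, na.rm = TRUE)
    expected <- ref_sum + imput_mass - resid + bbox_added
    if (abs(alloc_sum - expected) > tol * max(1, nrow(report)))
      msgs <- c(msgs, sprintf(
        "conservation violation: allocated %.8g vs expected %.8g", alloc_sum,
        expected))
  }
  list(ok = length(msgs) == 0L, messages = msgs)
}

#' Write a full synthetic input bundle to a directory
#'
#' Generates a landscape and census with [make_landscape()] and
#' [make_census()] and writes the pipeline's input files (population
#' raster, admin GeoJSON, census and totals CSVs) plus the per-pixel truth
#' grids and a parameters JSON (seed included) for provenance.
#'
#' @param params A [synth_params()].
#' @param dir Output directory.
#' @return Named character vector of files written, invisibly.
#' @export
simulate_bundle <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ls <- make_landscape(params)
  cz <- make_census(ls)
  files <- c(population = file.path(dir, "population.asc"),
             units = file.path(dir, "units.geojson"),
             census = file.path(dir, "census.csv"),
             totals = file.path(dir, "totals.csv"),
             params = file.path(dir, "params.json"))
  write_asc(ls$pop, files["population"])
  write_admin_geojson(ls$layer, files["units"])
  utils::write.csv(cz$census, files["census"], row.names = FALSE, na = "")
  utils::write.csv(cz$totals, files["totals"], row.names = FALSE)
  for (k in names(ls$truth)) {
    f <- file.path(dir, paste0("truth_", k, ".asc"))
    write_asc(ls$truth[[k]], f)
    files[paste0("truth_", k)] <- f
  }
  meta <- params
  meta$config <- unclass(params$config)
  jsonlite::write_json(unclass(meta), files["params"], auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)
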