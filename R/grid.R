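#' Grid specification
#'
#' Describes a regular lon/lat grid by its upper-left corner, cell size in
#' arc-seconds, and dimensions. Two grids are alignable iff their specs are
#' identical; no reprojection or latitude-dependent area correction is
#' applied (every pixel is treated as approx. 1 km^2).
#'
#' @param origin_lon,origin_lat Upper-left corner of the grid, decimal degrees.
#' @param n_rows,n_cols Grid dimensions, positive integers.
#' @param cell_size Cell size in arc-seconds (default 30, i.e. ~1 km).
#' @param nodata Sentinel written to files for absent pixels; in memory,
#'   absent pixels are `NA`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_lon, origin_lat, n_rows, n_cols,
                      cell_size = 30, nodata = -9999) {
  stopifnot(is.numeric(origin_lon), is.numeric(origin_lat))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number (arc-seconds)")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  structure(list(origin_lon = as.numeric(origin_lon),
                 origin_lat = as.numeric(origin_lat),
                 cell_size = as.numeric(cell_size),
                 n_rows = n_rows, n_cols = n_cols,
                 nodata = as.numeric(nodata)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g\" (%.6g deg), origin (%.6g, %.6g), nodata %g\n",
              x$n_rows, x$n_cols, x$cell_size, cell_deg(x),
              x$origin_lon, x$origin_lat, x$nodata))
  invisible(x)
}

cell_deg <- function(spec) spec$cell_size / 3600

#' @exportS3Method base::all.equal
all.equal.grid_spec <- function(target, current, ...) {
  ok <- inherits(current, "grid_spec") &&
    isTRUE(all.equal(unclass(target)[c("origin_lon", "origin_lat", "cell_size")],
                     unclass(current)[c("origin_lon", "origin_lat", "cell_size")])) &&
    target$n_rows == current$n_rows && target$n_cols == current$n_cols
  if (ok) TRUE else "grid specs differ"
}

same_spec <- function(a, b) isTRUE(all.equal(a, b))

#' Pixel-centre coordinates
#'
#' @param spec A [grid_spec()].
#' @return A list with `lon` (length `n_cols`) and `lat` (length `n_rows`)
#'   vectors of pixel-centre coordinates; rows run north to south.
#' @export
pixel_centres <- function(spec) {
  d <- cell_deg(spec)
  list(lon = spec$origin_lon + (seq_len(spec$n_cols) - 0.5) * d,
       lat = spec$origin_lat - (seq_len(spec$n_rows) - 0.5) * d)
}

new_grid <- function(spec, values, class, quantity_kind = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$n_rows, spec$n_cols)))
    stop(sprintf("values must be a %d x %d matrix", spec$n_rows, spec$n_cols))
  g <- list(spec = spec, values = values)
  if (!is.null(quantity_kind)) g$quantity_kind <- quantity_kind
  structure(g, class = c(class, "dc_grid"))
}

#' Population grid
#'
#' Per-pixel people counts. `NA` marks nodata pixels (outside the data
#' extent); all non-`NA` values must be non-negative.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix, `n_rows` x `n_cols`, people per pixel.
#' @return An object of class `population_grid`.
#' @export
population_grid <- function(spec, values) {
  g <- new_grid(spec, values, "population_grid")
  if (any(g$values < 0, na.rm = TRUE))
    stop("population values must be non-negative")
  g
}

#' Allocation grid
#'
#' Per-pixel allocated quantity (tonnes or hectares). `NA` marks pixels
#' covered by no administrative unit.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix of allocated quantity per pixel.
#' @param quantity_kind `"production"` or `"harvested_area"`.
#' @return An object of class `allocation_grid`.
#' @export
allocation_grid <- function(spec, values,
                            quantity_kind = c("production", "harvested_area")) {
  quantity_kind <- match.arg(quantity_kind)
  g <- new_grid(spec, values, "allocation_grid", quantity_kind)
  if (any(g$values < 0, na.rm = TRUE))
    stop("allocated values must be non-negative")
  g
}

#' @export
print.dc_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("%s: %d x %d, %d nodata pixels, sum %.6g, max %.6g\n",
              class(x)[1L], x$spec$n_rows, x$spec$n_cols,
              sum(is.na(x$values)), sum(v), if (length(v)) max(v) else NA))
  invisible(x)
}

#' Mask urban pixels
#'
#' Pixels with population strictly greater than `threshold` are considered
#' urban (unsuitable for the crop) and set to weight 0; they are retained in
#' the grid so output rasters stay full-extent. Pixels exactly at the
#' threshold count as rural and are unchanged. Nodata is preserved.
#'
#' @param pop A [population_grid()].
#' @param threshold Urban density cutoff in people per pixel (default 5000,
#'   i.e. 5,000 inhabitants per ~1 km^2).
#' @return A [population_grid()] of rural population.
#' @export
mask_urban <- function(pop, threshold = 5000) {
  stopifnot(inherits(pop, "population_grid"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a positive number of people per pixel")
  v <- pop$values
  v[!is.na(v) & v > threshold] <- 0
  population_grid(pop$spec, v)
}

#' Zonal population sums
#'
#' Sums (rural) population over the pixels of each administrative unit.
#' Units present in the source layer but covering no pixel get sum 0;
#' nodata population pixels contribute 0.
#'
#' @param rural A [population_grid()] (normally post-[mask_urban()]).
#' @param zones A unit-id grid from [rasterize_admin()] on the same spec.
#' @return A named numeric vector, unit_id -> population sum, covering every
#'   unit of the rasterised layer.
#' @export
zonal_population <- function(rural, zones) {
  stopifnot(inherits(rural, "population_grid"), inherits(zones, "unit_grid"))
  if (!same_spec(rural$spec, zones$spec))
    stop("grid specs of population and zone grids do not match")
  units <- attr(zones, "unit_ids")
  out <- stats::setNames(numeric(length(units)), units)
  v <- rural$values
  v[is.na(v)] <- 0
  lab <- zones$values
  keep <- !is.na(lab)
  if (any(keep)) {
    sums <- tapply(v[keep], lab[keep], sum)
    out[names(sums)] <- as.numeric(sums)
  }
  out
}
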