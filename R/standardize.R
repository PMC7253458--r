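#' Build a census record table
#'
#' @param unit_id,country,quantity_kind,value,year,source Column vectors;
#'   `value` may contain `NA` for missing records.
#' @param level Administrative level (optional, default 1).
#' @return A `data.frame` with one row per (unit, quantity_kind).
#' @export
census_records <- function(unit_id, country, quantity_kind, value,
                           year = NA_integer_, source = NA_character_,
                           level = 1L) {
  df <- data.frame(unit_id = as.character(unit_id),
                   country = as.character(country),
                   level = as.integer(level),
                   quantity_kind = as.character(quantity_kind),
                   value = as.numeric(value),
                   year = as.integer(year),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  bad <- !df$quantity_kind %in% c("production", "harvested_area")
  if (any(bad))
    stop("quantity_kind must be 'production' or 'harvested_area'")
  if (any(df$value < 0, na.rm = TRUE))
    stop("census values must be non-negative")
  if (anyDuplicated(df[c("unit_id", "quantity_kind")]))
    stop("duplicate (unit_id, quantity_kind) census record")
  df
}

#' Build a national reference-totals table
#'
#' @param country,quantity_kind,reference_value,reference_year Column vectors.
#' @return A `data.frame` with one row per (country, quantity_kind).
#' @export
national_totals <- function(country, quantity_kind, reference_value,
                            reference_year = 2014L) {
  df <- data.frame(country = as.character(country),
                   quantity_kind = as.character(quantity_kind),
                   reference_value = as.numeric(reference_value),
                   reference_year = as.integer(reference_year),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$reference_value) | df$reference_value < 0))
    stop("reference values must be non-negative and present")
  if (anyDuplicated(df[c("country", "quantity_kind")]))
    stop("duplicate (country, quantity_kind) national total")
  df
}

#' Standardise admin-unit statistics to national reference totals
#'
#' Rescales raw unit values proportionally so that each country's sum equals
#' its reference-year national total:
#' `adjusted = raw / country_raw_sum * reference_value`.
#' Country raw sums run over non-missing records only; missing records pass
#' through still missing (they are filled later on the per-capita scale).
#' The census year plays no role: this is standardisation, not trend
#' modelling.
#'
#' @param records Census table from [census_records()] (a single
#'   quantity_kind, or several processed independently).
#' @param totals National totals from [national_totals()].
#' @return `records` with an `adjusted_value` column added.
#' @export
standardize_to_national <- function(records, totals) {
  out <- records
  out$adjusted_value <- NA_real_
  for (kind in unique(records$quantity_kind)) {
    krec <- records$quantity_kind == kind
    for (cc in unique(records$country[krec])) {
      sel <- krec & records$country == cc
      tot <- totals[totals$country == cc & totals$quantity_kind == kind, ]
      if (!nrow(tot))
        stop(sprintf("no national %s total for country '%s'", kind, cc))
      ref <- tot$reference_value[1L]
      raw <- records$value[sel]
      csum <- sum(raw, na.rm = TRUE)
      if (csum <= 0) {
        if (ref > 0)
          stop(sprintf(
            "country '%s' (%s): raw sum is 0 but reference total is %g; cannot rescale",
            cc, kind, ref))
        out$adjusted_value[sel] <- ifelse(is.na(raw), NA_real_, 0)
      } else {
        out$adjusted_value[sel] <- raw / csum * ref
      }
    }
  }
  out
}

#' Per-capita rates over rural population
#'
#' Divides each unit's adjusted total by its rural population. Units with
#' zero rural population but a positive adjusted value get an `"undefined"`
#' status (the allocator's zero-population policy decides what to do with
#' them); units with adjusted value 0 get rate 0; units still missing an
#' adjusted value get status `"missing"` for downstream imputation.
#'
#' @param adjusted Output of [standardize_to_national()].
#' @param zonal Named vector from [zonal_population()].
#' @return A `data.frame`: unit_id, country, quantity_kind, adjusted_value,
#'   zonal_pop, rate, status (`ok`/`undefined`/`missing`), imputed (logical).
#' @export
per_capita_rates <- function(adjusted, zonal) {
  miss <- setdiff(adjusted$unit_id, names(zonal))
  if (length(miss))
    stop("units absent from zonal population: ", paste(miss, collapse = ", "))
  pop <- as.numeric(zonal[adjusted$unit_id])
  av <- adjusted$adjusted_value
  rate <- rep(NA_real_, length(av))
  status <- rep("ok", length(av))
  status[is.na(av)] <- "missing"
  defined <- !is.na(av) & pop > 0
  rate[defined] <- av[defined] / pop[defined]
  zero <- !is.na(av) & av == 0
  rate[zero] <- 0
  undef <- !is.na(av) & av > 0 & pop <= 0
  rate[undef] <- NA_real_
  status[undef] <- "undefined"
  data.frame(unit_id = adjusted$unit_id, country = adjusted$country,
             quantity_kind = adjusted$quantity_kind,
             adjusted_value = av, zonal_pop = pop,
             rate = rate, status = status, imputed = FALSE,
             stringsAsFactors = FALSE)
}
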