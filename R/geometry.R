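#' Administrative unit
#'
#' A polygonal administrative unit in the grid's lon/lat frame. Geometry is
#' a list of rings (two-column lon/lat matrices); interior membership uses
#' the even-odd rule, so holes are simply additional rings.
#'
#' @param unit_id Unique identifier within a layer.
#' @param country Country code.
#' @param level Administrative level (0 = national).
#' @param rings List of numeric matrices with columns lon, lat (>= 3 vertices;
#'   closing vertex optional).
#' @return An object of class `admin_unit`.
#' @export
admin_unit <- function(unit_id, country, level, rings) {
  stopifnot(is.character(unit_id), nchar(unit_id) > 0,
            is.character(country), length(rings) >= 1)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L || anyNA(r))
      stop("each ring must be a finite matrix with >= 3 lon/lat rows")
    # drop explicit closing vertex; edges wrap implicitly
    if (all(r[1L, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3L) stop("degenerate ring in unit ", unit_id)
    unname(r)
  })
  structure(list(unit_id = unit_id, country = country,
                 level = as.integer(level), rings = rings),
            class = "admin_unit")
}

#' Rectangular administrative unit
#'
#' Convenience constructor for an axis-aligned rectangular unit.
#'
#' @inheritParams admin_unit
#' @param xmin,ymin,xmax,ymax Rectangle bounds in degrees.
#' @return An [admin_unit()].
#' @export
rect_unit <- function(unit_id, country, level, xmin, ymin, xmax, ymax) {
  stopifnot(xmin < xmax, ymin < ymax)
  admin_unit(unit_id, country, level,
             list(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))))
}

#' Administrative layer
#'
#' @param units List of [admin_unit()] objects. `unit_id`s must be unique;
#'   each country should appear at a single admin level per run.
#' @return An object of class `admin_layer`.
#' @export
admin_layer <- function(units) {
  stopifnot(length(units) >= 0, all(vapply(units, inherits, TRUE, "admin_unit")))
  ids <- vapply(units, `[[`, "", "unit_id")
  if (anyDuplicated(ids))
    stop("duplicate unit_id in admin layer: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(units = units), class = "admin_layer")
}

#' @export
print.admin_layer <- function(x, ...) {
  cat(sprintf("admin_layer: %d units, %d countries\n", length(x$units),
              length(unique(vapply(x$units, `[[`, "", "country")))))
  invisible(x)
}

unit_ids <- function(layer) vapply(layer$units, `[[`, "", "unit_id")
unit_countries <- function(layer)
  stats::setNames(vapply(layer$units, `[[`, "", "country"), unit_ids(layer))

#' Point-in-polygon test (even-odd rule)
#'
#' Ray-casting over all rings of a unit. Points exactly on an edge are
#' assigned quasi-arbitrarily; pipeline geometry is constructed so pixel
#' centres never lie on unit boundaries.
#'
#' @param lon,lat Numeric vectors of point coordinates.
#' @param rings List of two-column lon/lat matrices.
#' @return Logical vector: point inside an odd number of rings.
#' @export
point_in_rings <- function(lon, lat, rings) {
  inside <- rep(FALSE, length(lon))
  for (r in rings) {
    n <- nrow(r)
    j <- n
    for (i in seq_len(n)) {
      xi <- r[i, 1L]; yi <- r[i, 2L]
      xj <- r[j, 1L]; yj <- r[j, 2L]
      crosses <- ((yi > lat) != (yj > lat)) &
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

ring_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1L]))
  ys <- unlist(lapply(rings, function(r) r[, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Rasterise an administrative layer
#'
#' Assigns each pixel to the unit whose polygon contains the pixel centre
#' (centre-containment, not "all touched", so the assignment is an
#' unambiguous partition). Pixels whose centre falls in no unit are labelled
#' `NA` ("outside"). Units covering no pixel centre are reported via the
#' `"uncovered_units"` attribute and a warning.
#'
#' @param layer An [admin_layer()].
#' @param spec A [grid_spec()] sharing the layer's coordinate frame.
#' @return An object of class `unit_grid`: `spec` plus a character matrix of
#'   unit ids (`NA` = outside), with attributes `unit_ids` (all layer units)
#'   and `uncovered_units`.
#' @export
rasterize_admin <- function(layer, spec) {
  stopifnot(inherits(layer, "admin_layer"), inherits(spec, "grid_spec"))
  ctr <- pixel_centres(spec)
  lab <- matrix(NA_character_, spec$n_rows, spec$n_cols)
  uncovered <- character(0)
  for (u in layer$units) {
    bb <- ring_bbox(u$rings)
    cols <- which(ctr$lon >= bb["xmin"] & ctr$lon <= bb["xmax"])
    rows <- which(ctr$lat >= bb["ymin"] & ctr$lat <= bb["ymax"])
    if (!length(cols) || !length(rows)) {
      uncovered <- c(uncovered, u$unit_id)
      next
    }
    pts <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
    hit <- point_in_rings(ctr$lon[pts$col], ctr$lat[pts$row], u$rings)
    if (!any(hit)) {
      uncovered <- c(uncovered, u$unit_id)
      next
    }
    idx <- cbind(pts$row[hit], pts$col[hit])
    clash <- !is.na(lab[idx])
    if (any(clash)) {
      other <- lab[idx][clash][1L]
      stop(sprintf("units '%s' and '%s' overlap: both contain a pixel centre",
                   other, u$unit_id))
    }
    lab[idx] <- u$unit_id
  }
  if (length(uncovered))
    warning("units covering no pixel centre: ", paste(uncovered, collapse = ", "))
  structure(list(spec = spec, values = lab),
            class = c("unit_grid", "dc_grid"),
            unit_ids = unit_ids(layer), uncovered_units = uncovered)
}

# collinear overlap length of two segments, 0 if not collinear
segment_overlap_length <- function(p1, p2, q1, q2, tol = 1e-9) {
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len < tol) return(0)
  u <- d / len
  cross1 <- (q1[1] - p1[1]) * u[2] - (q1[2] - p1[2]) * u[1]
  cross2 <- (q2[1] - p1[1]) * u[2] - (q2[2] - p1[2]) * u[1]
  if (abs(cross1) > tol || abs(cross2) > tol) return(0)
  # project onto the segment direction
  t0 <- 0; t1 <- len
  s0 <- sum((q1 - p1) * u); s1 <- sum((q2 - p1) * u)
  lo <- max(min(t0, t1), min(s0, s1))
  hi <- min(max(t0, t1), max(s0, s1))
  max(0, hi - lo)
}

ring_edges <- function(rings) {
  do.call(rbind, lapply(rings, function(r) {
    n <- nrow(r)
    cbind(r, r[c(2:n, 1L), , drop = FALSE])
  }))
}

#' Unit adjacency by shared boundary
#'
#' Two units of the same country are adjacent iff their boundaries share a
#' segment of positive length; touching at a single point does not count.
#' The relation is symmetric and irreflexive; isolated units get empty sets.
#'
#' @param layer An [admin_layer()].
#' @param tol Length tolerance in degrees below which shared boundary is
#'   treated as point contact.
#' @return Named list, unit_id -> character vector of adjacent unit_ids.
#' @export
adjacency <- function(layer, tol = 1e-9) {
  ids <- unit_ids(layer)
  ctry <- unit_countries(layer)
  edges <- lapply(layer$units, function(u) ring_edges(u$rings))
  bbs <- lapply(layer$units, function(u) ring_bbox(u$rings))
  nbr <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  n <- length(ids)
  if (n < 2L) return(nbr)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (ctry[a] != ctry[b]) next
    ba <- bbs[[a]]; bb <- bbs[[b]]
    if (ba["xmax"] < bb["xmin"] - tol || bb["xmax"] < ba["xmin"] - tol ||
        ba["ymax"] < bb["ymin"] - tol || bb["ymax"] < ba["ymin"] - tol) next
    ea <- edges[[a]]; eb <- edges[[b]]
    shared <- 0
    for (i in seq_len(nrow(ea))) {
      for (j in seq_len(nrow(eb))) {
        shared <- shared + segment_overlap_length(
          ea[i, 1:2], ea[i, 3:4], eb[j, 1:2], eb[j, 3:4], tol)
        if (shared > tol) break
      }
      if (shared > tol) break
    }
    if (shared > tol) {
      nbr[[ids[a]]] <- c(nbr[[ids[a]]], ids[b])
      nbr[[ids[b]]] <- c(nbr[[ids[b]]], ids[a])
    }
  }
  nbr
}
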