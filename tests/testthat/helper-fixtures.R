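# shared fixtures: tiny grids and layers built in code

# a spec whose pixel edges sit on multiples of cell_deg, so rectangles built
# with px_rect() align exactly with pixel boundaries
tiny_spec <- function(n_rows = 4, n_cols = 4, cell_size = 30) {
  grid_spec(origin_lon = 10, origin_lat = 5, n_rows = n_rows, n_cols = n_cols,
            cell_size = cell_size)
}

# rectangle covering pixel columns [c0, c1] and rows [r0, r1] (1-based,
# inclusive) of a spec
px_rect <- function(id, country, spec, r0, r1, c0, c1, level = 1) {
  d <- spec$cell_size / 3600
  rect_unit(id, country, level,
            xmin = spec$origin_lon + (c0 - 1) * d,
            xmax = spec$origin_lon + c1 * d,
            ymin = spec$origin_lat - r1 * d,
            ymax = spec$origin_lat - (r0 - 1) * d)
}

# chain of 3 abutting rectangles in one country, one grid row each
chain_layer <- function(spec = tiny_spec(3, 4)) {
  admin_layer(list(px_rect("A", "X", spec, 1, 1, 1, 4),
                   px_rect("B", "X", spec, 2, 2, 1, 4),
                   px_rect("C", "X", spec, 3, 3, 1, 4)))
}

# brute-force per-pixel zonal accumulation, independent of tapply
zonal_loop_oracle <- function(rural, zones) {
  out <- stats::setNames(numeric(length(attr(zones, "unit_ids"))),
                         attr(zones, "unit_ids"))
  for (r in seq_len(rural$spec$n_rows)) for (c in seq_len(rural$spec$n_cols)) {
    uid <- zones$values[r, c]
    v <- rural$values[r, c]
    if (!is.na(uid) && !is.na(v)) out[uid] <- out[uid] + v
  }
  out
}
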