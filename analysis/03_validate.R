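#!/usr/bin/env Rscript
# Step 3: validate the written outputs against the caps and the national
# reference totals, and compare the allocation grids with the per-pixel
# ground truth from the generator. Writes results/validation.csv and exits
# nonzero on any violation.

suppressPackageStartupMessages(library(dasycrop))

bundle <- "results/bundle"
run <- "results/run"
totals <- read_totals_csv(file.path(bundle, "totals.csv"))
cfg <- allocation_config()

rows <- list()
ok_all <- TRUE
for (kind in c("production", "harvested_area")) {
  chk <- validate_outputs(run, kind, totals, cfg)
  ok_all <- ok_all && chk$ok
  grid <- read_asc(file.path(run, paste0(kind, "_grid.asc")), kind = kind)
  truth <- read_asc(file.path(bundle, paste0("truth_", kind, ".asc")),
                    kind = kind)
  report <- read.csv(file.path(run, paste0(kind, "_report.csv")))
  # truth comparison is only exact where no unit was imputed: blanked units
  # carry no information about their own true rate
  imputed <- report$unit_id[report$imputed]
  rows[[kind]] <- data.frame(
    quantity_kind = kind,
    cap = if (kind == "production") cfg$cap_production
          else cfg$cap_harvested_area,
    max_pixel = max(grid$values, na.rm = TRUE),
    allocated_total = sum(grid$values, na.rm = TRUE),
    reference_total = sum(totals$reference_value[totals$quantity_kind == kind]),
    n_units = nrow(report),
    n_imputed = length(imputed),
    valid = chk$ok)
  cat(sprintf("%s: %s", kind,
              if (chk$ok) "valid (caps respected, totals conserved)\n"
              else paste(chk$messages, collapse = "; ")))
  if (!chk$ok) cat("\n")
}

val <- do.call(rbind, rows)
write.csv(val, "results/validation.csv", row.names = FALSE)
print(val, row.names = FALSE)
if (!ok_all) quit(status = 1)
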