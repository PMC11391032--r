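#!/usr/bin/env Rscript
# Exercise the cell-level image quantifications on rendered fields with
# known ground truth: fraction of marker-positive cells (activation
# marker readout) and punctate granules per cell (storage-granule
# readout). Fields are rendered per condition, quantified blind to the
# truth, and the recovered values compared with what was drawn.

library(thrombochip)

set.seed(404)
conds <- list(
  HUVEC = list(pos_frac = 0.15, mean_spots = 2),
  `LV-Ctrl` = list(pos_frac = 0.45, mean_spots = 4),
  `LV-TF` = list(pos_frac = 0.70, mean_spots = 6))
n_fields <- 3
n_cells <- 12

rows <- list()
for (cname in names(conds)) {
  cc <- conds[[cname]]
  for (f in seq_len(n_fields)) {
    seed <- 404 + 10 * f + match(cname, names(conds))
    n_pos <- round(cc$pos_frac * n_cells)
    spot_counts <- rpois(n_cells, cc$mean_spots)
    img <- render_cell_image(n_cells,
                             positive_ids = sample(n_cells, n_pos),
                             spot_counts = spot_counts,
                             frame_dim = c(320, 320), seed = seed,
                             min_sep = 34)
    pcf <- positive_cell_fraction(img$nuclei, img$marker,
                                  marker_threshold = 400)
    spc <- spots_per_cell(img$spots, pcf$n_cells)
    rows[[paste(cname, f)]] <- data.frame(
      condition = cname, field = f,
      n_cells_true = n_cells, n_cells_found = pcf$n_cells,
      pos_frac_true = n_pos / n_cells, pos_frac_found = pcf$fraction,
      spots_true = mean(spot_counts),
      spots_found = spc$spots_per_cell)
  }
}
tab <- do.call(rbind, rows)

out <- "results/image_quant"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write.csv(tab, file.path(out, "field_quantification.csv"),
          row.names = FALSE)

cat("Field-level recovery (rendered truth vs quantification):\n")
print(tab, digits = 3, row.names = FALSE)
cat(sprintf("\nCell detection: %d/%d fields exact; positive fraction %d/%d exact; max |spots/cell error| %.2f\n",
            sum(tab$n_cells_found == tab$n_cells_true), nrow(tab),
            sum(tab$pos_frac_found == tab$pos_frac_true), nrow(tab),
            max(abs(tab$spots_found - tab$spots_true))))
cat("\nTables ->", out, "\n")
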