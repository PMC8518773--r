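#!/usr/bin/env Rscript
# Step 1: generate the synthetic study site with known ground truth.
# Writes every raster product plus the 23-plot field table under results/.

library(biocrustmap)

seed <- 1
out <- "results/scene"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- scene_config(seed = seed)   # 140 x 140 m at 1 m, winter conditions
scene <- generate_scene(cfg, n_plots = 23)

write_raster(scene$dtm, file.path(out, "dtm.asc"))
write_raster(scene$moisture, file.path(out, "moisture.asc"))
write_raster(scene$classes, file.path(out, "classes_truth.asc"))
write_raster(scene$reflectance, file.path(out, "reflectance.asc"))
write_raster(scene$raw_dn, file.path(out, "raw_dn.asc"))
write_raster(scene$t_predawn, file.path(out, "thermal_predawn.asc"))
write_raster(scene$t_noon, file.path(out, "thermal_noon.asc"))
write_raster(scene$ati_true, file.path(out, "ati_true.asc"))
write.csv(scene$plots, file.path(out, "plots.csv"), row.names = FALSE)
writeLines(c(
  paste("seed", seed),
  paste("ati_link_a", cfg$ati_link[[1]]),
  paste("ati_link_b", cfg$ati_link[[2]]),
  paste("moisture_m0", cfg$moisture_link[[1]]),
  paste("moisture_m_north", cfg$moisture_link[[2]]),
  paste("moisture_m_psir", cfg$moisture_link[[3]]),
  paste("panel_dn", paste(scene$panel_dn, collapse = " "))
), file.path(out, "truth.txt"))

cat("Scene written to", out, "\n")
cat("  moisture range:", paste(round(range(scene$moisture$values,
                                           na.rm = TRUE), 2),
                               collapse = " - "), "%\n")
cat("  cover fractions:\n")
print(round(table(factor(cover_classes()[scene$classes$labels],
                         levels = cover_classes())) /
              sum(!is.na(scene$classes$labels)), 3))
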