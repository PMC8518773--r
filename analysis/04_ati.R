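#!/usr/bin/env Rscript
# Step 4: thermal pair -> apparent thermal inertia (ATI), vegetation
# masking, plot zonal means, and the ATI-soil moisture regression.

library(biocrustmap)

scene_dir <- "results/scene"
cls_dir <- "results/classification"
out <- "results/ati"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

reflectance <- {
  raw <- read_raster(file.path(scene_dir, "raw_dn.asc"), expected_bands = 4)
  truth_lines <- readLines(file.path(scene_dir, "truth.txt"))
  panel_dn <- as.numeric(strsplit(sub("panel_dn ", "",
                                      grep("panel_dn", truth_lines,
                                           value = TRUE)), " ")[[1]])
  names(panel_dn) <- band_names()
  calibrate_dn(raw, default_camera(), panel_dn)
}
t1 <- read_raster(file.path(scene_dir, "thermal_predawn.asc"))
t2 <- read_raster(file.path(scene_dir, "thermal_noon.asc"))
classes <- read_class_raster(file.path(cls_dir, "classes.asc"))
plots <- read.csv(file.path(scene_dir, "plots.csv"))

alb <- albedo(reflectance)
ati_map <- ati(alb, t1, t2)
ati_masked <- mask_vegetation(ati_map, classes)
write_raster(ati_masked, file.path(out, "ati.asc"))

zm <- zonal_mean(ati_masked, plots)
reg <- regress_ati_moisture(zm$mean, plots$moisture)
write.csv(data.frame(plot_id = plots$plot_id, ati = zm$mean,
                     n_cells = zm$n_cells, moisture = plots$moisture),
          file.path(out, "plot_ati.csv"), row.names = FALSE)
write.csv(data.frame(term = c("slope", "intercept", "r_squared", "n_plots",
                              "residual_sd"),
                     value = c(reg$slope, reg$intercept, reg$r_squared,
                               reg$n_plots, reg$residual_sd)),
          file.path(out, "ati_moisture_regression.csv"), row.names = FALSE)

cat("ATI products written to", out, "\n")
print(reg)
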