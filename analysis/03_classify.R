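#!/usr/bin/env Rscript
# Step 3: radiometric calibration of the raw DN image, SVM classification of
# the 4-band reflectance into the seven surface covers, continuum-removal
# refinement, and accuracy assessment against held-out labelled pixels.

library(biocrustmap)

scene_dir <- "results/scene"
out <- "results/classification"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1

raw <- read_raster(file.path(scene_dir, "raw_dn.asc"), expected_bands = 4)
truth <- read_class_raster(file.path(scene_dir, "classes_truth.asc"))
truth_lines <- readLines(file.path(scene_dir, "truth.txt"))
panel_dn <- as.numeric(strsplit(sub("panel_dn ", "",
                                    grep("panel_dn", truth_lines,
                                         value = TRUE)), " ")[[1]])
names(panel_dn) <- band_names()

reflectance <- calibrate_dn(raw, default_camera(), panel_dn)
cr <- cr_red(reflectance)

training <- sample_labelled_pixels(truth, reflectance, n_per_class = 100,
                                   seed = seed + 11L)
model <- train_classifier(training, seed = seed + 12L)
predicted <- classify(model, reflectance)
refined <- refine(predicted, cr)

validation <- sample_labelled_pixels(truth, reflectance, n_per_class = 90,
                                     seed = seed + 13L,
                                     exclude = training$cell)
acc <- assess_accuracy(
  cover_classes()[refined$classes$labels[validation$cell]],
  validation$class)

write_raster(refined$classes, file.path(out, "classes.asc"))
write_raster(cr, file.path(out, "cr_red.asc"))
write.csv(as.data.frame.matrix(acc$confusion),
          file.path(out, "confusion_matrix.csv"))
write.csv(data.frame(metric = c("overall_accuracy", "kappa",
                                "dryveg_to_moss", "bl_to_soil"),
                     value = c(acc$overall_accuracy, acc$kappa,
                               refined$counts)),
          file.path(out, "accuracy.csv"), row.names = FALSE)

cat("Classification written to", out, "\n")
print(acc)
cat("refinement reassigned:", refined$counts[1], "DryVeg->Moss,",
    refined$counts[2], "BL->Soil pixels\n")
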