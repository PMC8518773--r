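# Surface-cover classification of the 4-band reflectance image: an RBF-kernel
# SVM over the four bands, followed by a continuum-removal refinement of the
# chlorophyll-a absorption at 660 nm, and confusion-matrix accuracy metrics.

#' Continuum-removed reflectance at the red band
#'
#' The continuum baseline is the straight line between the green (550 nm) and
#' red-edge (735 nm) reflectances; `CR_red` is the 660 nm reflectance divided
#' by the baseline value there, clipped to at most 1 so that spectra without
#' red absorption (bare soil) sit exactly at 1.
#'
#' @param image A `bc_multiband` of reflectance with positive green and
#'   red-edge values.
#' @return A `bc_raster` of `CR_red` in `[0, 1]`.
#' @export
cr_red <- function(image) {
  stopifnot(inherits(image, "bc_multiband"))
  g <- image$bands$green; re <- image$bands$red_edge; r <- image$bands$red
  w <- (660 - 550) / (735 - 550)
  cont <- g + (re - g) * w
  if (any(cont <= 0, na.rm = TRUE))
    stop("continuum baseline <= 0: green/red-edge reflectance must be positive")
  bc_raster(image$grid, pmin(r / cont, 1))
}

#' CR_red for plain per-band vectors (training spectra, spot checks)
#' @param green,red,red_edge Reflectance values.
#' @return `CR_red` values in `[0, 1]`.
#' @export
cr_red_values <- function(green, red, red_edge) {
  cont <- green + (red_edge - green) * (660 - 550) / (735 - 550)
  if (any(cont <= 0, na.rm = TRUE)) stop("continuum baseline <= 0")
  pmin(red / cont, 1)
}

#' Train the surface-cover classifier
#'
#' A radial-basis-kernel support vector machine over the four reflectance
#' bands, with fixed hyperparameters (cost 1, kernel width
#' `1 / (4 * var(features))`) so that training is deterministic given the
#' data and seed.
#'
#' @param training Data frame with columns `class` (values from
#'   [cover_classes()]) and the four band columns [band_names()].
#' @param seed Integer seed.
#' @return An object of class `bc_classifier`.
#' @export
train_classifier <- function(training, seed = 1) {
  stopifnot(is.data.frame(training),
            all(c("class", band_names()) %in% names(training)))
  if (nrow(training) == 0) stop("empty training set")
  cls <- factor(training$class, levels = cover_classes())
  if (anyNA(cls)) stop("unknown class labels in training set")
  cls <- droplevels(cls)
  if (nlevels(cls) < 2) stop("need at least 2 classes to train")
  x <- as.matrix(training[, band_names()])
  set.seed(seed)
  fit <- e1071::svm(x = x, y = cls, kernel = "radial",
                    gamma = 1 / (ncol(x) * stats::var(as.vector(x))),
                    cost = 1, scale = TRUE)
  structure(list(fit = fit, levels = levels(cls), seed = seed),
            class = "bc_classifier")
}

#' Sample labelled training or validation pixels from a reference map
#'
#' Draws up to `n_per_class` pixels per cover from a labelled class raster
#' and attaches their 4-band reflectance, emulating the field practice of
#' digitizing labelled polygons over the orthomosaic (about 100 pixels per
#' class for training, 90 for validation).
#'
#' @param classes A `bc_classraster` of reference labels.
#' @param image An aligned `bc_multiband` of reflectance.
#' @param n_per_class Pixels per class (classes with fewer pixels contribute
#'   all of them).
#' @param seed Integer seed.
#' @param exclude Optional linear cell indices to avoid (e.g. pixels already
#'   used for training when sampling validation).
#' @return Data frame with `class`, the four band columns and `cell` (linear
#'   index).
#' @export
sample_labelled_pixels <- function(classes, image, n_per_class = 100,
                                   seed = 1, exclude = integer(0)) {
  assert_aligned(classes, image)
  set.seed(seed)
  out <- lapply(seq_along(cover_classes()), function(code) {
    idx <- which(classes$labels == code)
    idx <- setdiff(idx, exclude)
    if (!length(idx)) return(NULL)
    idx <- idx[sample.int(length(idx), min(n_per_class, length(idx)))]
    df <- data.frame(class = cover_classes()[code], cell = idx)
    for (b in band_names()) df[[b]] <- image$bands[[b]][idx]
    df
  })
  do.call(rbind, out)
}

#' Classify a 4-band image into the seven surface covers
#'
#' @param model A [train_classifier()] model.
#' @param image A `bc_multiband` of reflectance on the grid to classify.
#' @return A `bc_classraster`; nodata pixels (any band missing) propagate.
#' @export
classify <- function(model, image) {
  stopifnot(inherits(model, "bc_classifier"), inherits(image, "bc_multiband"))
  x <- vapply(band_names(), function(b) as.vector(image$bands[[b]]),
              numeric(length(image$bands$green)))
  ok <- stats::complete.cases(x)
  labels <- rep(NA_integer_, nrow(x))
  if (any(ok)) {
    pred <- stats::predict(model$fit, x[ok, , drop = FALSE])
    labels[ok] <- match(as.character(pred), cover_classes())
  }
  bc_classraster(image$grid,
                 matrix(labels, image$grid$nrows, image$grid$ncols))
}

#' Refinement rules applied after classification
#'
#' @param dryveg_to_moss_threshold Pixels classified DryVeg with `CR_red`
#'   below this become Moss (default 0.75: dry canopies lack the chlorophyll
#'   absorption that mosses show).
#' @param bl_to_soil_value Pixels classified BL with `CR_red` at this value
#'   (no absorption at all) become Soil (default 1).
#' @param epsilon Floating-point tolerance for "equal to 1".
#' @export
refinement_rules <- function(dryveg_to_moss_threshold = 0.75,
                             bl_to_soil_value = 1, epsilon = 1e-6) {
  stopifnot(dryveg_to_moss_threshold > 0, dryveg_to_moss_threshold <= 1,
            bl_to_soil_value > 0, bl_to_soil_value <= 1, epsilon >= 0)
  list(dryveg_to_moss_threshold = dryveg_to_moss_threshold,
       bl_to_soil_value = bl_to_soil_value, epsilon = epsilon)
}

#' Refine a classification with CR_red thresholds
#'
#' Only DryVeg and BL pixels can change; the operation is idempotent.
#'
#' @param classes A `bc_classraster`.
#' @param cr A `bc_raster` of `CR_red` aligned with `classes`.
#' @param rules A [refinement_rules()].
#' @return List: `classes` (refined `bc_classraster`) and `counts`
#'   (`dryveg_to_moss`, `bl_to_soil` pixels reassigned).
#' @export
refine <- function(classes, cr, rules = refinement_rules()) {
  assert_aligned(classes, cr)
  lab <- classes$labels
  crv <- cr$values
  code <- function(nm) match(nm, cover_classes())
  m1 <- !is.na(lab) & lab == code("DryVeg") & !is.na(crv) &
    crv < rules$dryveg_to_moss_threshold
  m2 <- !is.na(lab) & lab == code("BL") & !is.na(crv) &
    crv >= rules$bl_to_soil_value - rules$epsilon
  lab[m1] <- code("Moss")
  lab[m2] <- code("Soil")
  list(classes = bc_classraster(classes$grid, lab),
       counts = c(dryveg_to_moss = sum(m1), bl_to_soil = sum(m2)))
}

#' Classification accuracy report
#'
#' Confusion matrix with classified data on the rows and ground truth on the
#' columns; overall accuracy is the diagonal sum over the total and Cohen's
#' kappa corrects it for chance agreement from the marginals.
#'
#' @param predicted Predicted labels: a `bc_classraster` or an
#'   integer/character vector.
#' @param reference Ground-truth labels of the same cells (vector, or a
#'   `bc_classraster` aligned with `predicted`); cells missing in either are
#'   dropped.
#' @return List of class `bc_accuracy`: `confusion`, `overall_accuracy`,
#'   `kappa`, `per_class` (producer's accuracy per truth class), `n`.
#' @export
assess_accuracy <- function(predicted, reference) {
  as_labels <- function(x) {
    if (inherits(x, "bc_classraster")) x <- as.vector(x$labels)
    if (is.numeric(x)) x <- cover_classes()[x]
    factor(x, levels = cover_classes())
  }
  if (inherits(predicted, "bc_classraster") &&
      inherits(reference, "bc_classraster"))
    assert_aligned(predicted, reference)
  p <- as_labels(predicted); r <- as_labels(reference)
  stopifnot(length(p) == length(r))
  keep <- !is.na(p) & !is.na(r)
  p <- p[keep]; r <- r[keep]
  if (length(p) == 0) stop("no reference pixels")
  used <- union(levels(droplevels(p)), levels(droplevels(r)))
  used <- cover_classes()[cover_classes() %in% used]
  p <- factor(p, levels = used); r <- factor(r, levels = used)
  cm <- table(classified = p, truth = r)
  n <- sum(cm)
  oa <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1 - 1e-15) stop("degenerate confusion matrix: chance agreement 1")
  kappa <- (oa - pe) / (1 - pe)
  per_class <- diag(cm) / colSums(cm)
  structure(list(confusion = cm, overall_accuracy = oa, kappa = kappa,
                 per_class = per_class, n = n),
            class = "bc_accuracy")
}

#' @export
print.bc_accuracy <- function(x, ...) {
  cat("Overall accuracy:", round(x$overall_accuracy, 4),
      " kappa:", round(x$kappa, 4), " (n =", x$n, ")\n")
  print(x$confusion)
  invisible(x)
}
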