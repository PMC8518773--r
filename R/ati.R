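# Apparent thermal inertia (ATI) as a soil-moisture proxy: ATI = C (1 - albedo)
# / deltaT, with deltaT the diurnal surface temperature amplitude (noon minus
# pre-dawn) and albedo approximated as the mean of the four band reflectances.
# Emissivity is taken as 1 (gypsum soils and biocrusts are near-black bodies in
# the 8.5-13.5 um window); the solar correction factor C is an input constant.

#' ATI configuration
#'
#' @param C_solar Solar correction factor (default 1.19).
#' @param delta_t_min Minimum diurnal amplitude in K; cells below it become
#'   nodata rather than producing unstable ratios (default 0.1).
#' @export
ati_config <- function(C_solar = 1.19, delta_t_min = 0.1) {
  stopifnot(C_solar > 0, delta_t_min >= 0)
  list(C_solar = C_solar, delta_t_min = delta_t_min)
}

#' Thermal DN to temperature
#'
#' `T = 0.01 R - 100` (degrees C), the radiometric scaling of the thermal
#' camera's 16-bit output.
#'
#' @param raw A `bc_raster` of thermal DN.
#' @return A `bc_raster` of temperature in degrees C.
#' @export
dn_to_temperature <- function(raw) {
  bc_raster(raw$grid, 0.01 * raw$values - 100)
}

#' Broadband albedo proxy
#'
#' Mean of the four band reflectances; any missing band makes the cell nodata.
#'
#' @param image A `bc_multiband` of calibrated reflectance.
#' @return A `bc_raster`.
#' @export
albedo <- function(image) {
  stopifnot(inherits(image, "bc_multiband"))
  a <- (image$bands$green + image$bands$red + image$bands$red_edge +
          image$bands$nir) / 4
  bc_raster(image$grid, a)
}

#' Apparent thermal inertia
#'
#' @param albedo_r A `bc_raster` of albedo.
#' @param t_predawn,t_noon `bc_raster`s of surface temperature (degrees C; a
#'   shared offset cancels in the difference).
#' @param config An [ati_config()].
#' @return A `bc_raster` of ATI in 1/K; cells with `deltaT < delta_t_min` or
#'   `albedo >= 1` are nodata.
#' @export
ati <- function(albedo_r, t_predawn, t_noon, config = ati_config()) {
  assert_aligned(albedo_r, t_predawn); assert_aligned(albedo_r, t_noon)
  dt <- t_noon$values - t_predawn$values
  a <- albedo_r$values
  v <- config$C_solar * (1 - a) / dt
  v[!is.na(dt) & dt < config$delta_t_min] <- NA
  v[!is.na(a) & a >= 1] <- NA
  bc_raster(albedo_r$grid, v)
}

#' Mask vegetation cells out of a raster
#'
#' GreenVeg and DryVeg cells become nodata; everything else is untouched.
#'
#' @param raster A `bc_raster`.
#' @param classes A `bc_classraster` aligned with it.
#' @return A masked `bc_raster`.
#' @export
mask_vegetation <- function(raster, classes) {
  assert_aligned(raster, classes)
  veg <- match(c("GreenVeg", "DryVeg"), cover_classes())
  v <- raster$values
  v[!is.na(classes$labels) & classes$labels %in% veg] <- NA
  bc_raster(raster$grid, v)
}

# linear indices of cells whose centres fall inside an axis-aligned square
# plot given by its centre and side
plot_cells <- function(grid, cx, cy, side) {
  cc <- cell_centres(grid)
  jin <- which(cc$x > cx - side / 2 & cc$x < cx + side / 2)
  iin <- which(cc$y > cy - side / 2 & cc$y < cy + side / 2)
  if (length(jin) == 0 || length(iin) == 0) return(integer(0))
  as.vector(outer(iin, (jin - 1) * grid$nrows, `+`))
}

#' Zonal means of a raster over field plots
#'
#' Mean of non-nodata cells whose centres fall inside each plot polygon
#' (axis-aligned squares given by centre and side). Plots with no valid cell
#' get `NA` and are flagged.
#'
#' @param raster A `bc_raster`.
#' @param plots Data frame with columns `plot_id`, `x`, `y` (plot centre, m)
#'   and `side` (m; default 2 if absent).
#' @return Data frame `plot_id`, `mean`, `n_cells`, `flagged`.
#' @export
zonal_mean <- function(raster, plots) {
  stopifnot(all(c("plot_id", "x", "y") %in% names(plots)))
  side <- if ("side" %in% names(plots)) plots$side else rep(2, nrow(plots))
  cc <- cell_centres(raster$grid)
  if (any(plots$x + side / 2 < min(cc$x) | plots$x - side / 2 > max(cc$x) |
          plots$y + side / 2 < min(cc$y) | plots$y - side / 2 > max(cc$y)))
    stop("plot fully outside the raster")
  res <- lapply(seq_len(nrow(plots)), function(i) {
    idx <- plot_cells(raster$grid, plots$x[i], plots$y[i], side[i])
    vals <- raster$values[idx]
    vals <- vals[!is.na(vals)]
    data.frame(plot_id = plots$plot_id[i],
               mean = if (length(vals)) mean(vals) else NA_real_,
               n_cells = length(vals),
               flagged = length(vals) == 0)
  })
  do.call(rbind, res)
}

#' Linear regression of soil moisture on ATI
#'
#' Ordinary least squares over the field plots; the headline diagnostic is
#' r-squared.
#'
#' @param ati_means Per-plot mean ATI (1/K).
#' @param moisture Per-plot soil moisture (%).
#' @return List of class `bc_ati_regression`: `slope`, `intercept`,
#'   `r_squared`, `n_plots`, `residual_sd`.
#' @export
regress_ati_moisture <- function(ati_means, moisture) {
  keep <- !is.na(ati_means) & !is.na(moisture)
  x <- ati_means[keep]; y <- moisture[keep]
  if (length(x) < 3) stop("need at least 3 plots with valid ATI and moisture")
  if (stats::var(x) == 0) stop("zero variance in ATI across plots")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; noise-free scenes reach them by design
  sm <- suppressWarnings(summary(fit))
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_plots = length(x),
                 residual_sd = sm$sigma,
                 fit = fit),
            class = "bc_ati_regression")
}

#' @export
print.bc_ati_regression <- function(x, ...) {
  cat("moisture = ", signif(x$intercept, 5), " + ", signif(x$slope, 5),
      " * ATI;  r^2 = ", round(x$r_squared, 4), " (n = ", x$n_plots, ")\n",
      sep = "")
  invisible(x)
}
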