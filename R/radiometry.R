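# Radiometric calibration of 4-band raw digital numbers (DN) to reflectance.
# Per band: pseudo-radiance R = f^2 (P - B) / (A gamma epsilon + C); the
# panel-derived coefficient K = rho_ref / R_ref converts R to reflectance
# rho = K R. The denominator grouping (A * ISO * exposure + C) follows the
# standard small-camera calibration literature; the alternative typeset
# groupings are not used (see the methods vignette).

#' Camera parameters for DN calibration
#'
#' @param A,B,C_cal Per-band sensor calibration coefficients (length-4 numeric
#'   named by band, or scalars recycled over bands).
#' @param iso ISO number (gamma).
#' @param exposure Exposure time in seconds (epsilon, > 0).
#' @param f_number Aperture f-number (> 0).
#' @param panel_reflectance Known per-band reflectance of the calibration
#'   panel.
#' @return An object of class `bc_camera`.
#' @export
camera_params <- function(A, B, C_cal, iso, exposure, f_number,
                          panel_reflectance) {
  per_band <- function(x) {
    if (length(x) == 1) x <- rep(x, 4)
    stopifnot(length(x) == 4)
    stats::setNames(as.numeric(x), band_names())
  }
  stopifnot(exposure > 0, f_number > 0)
  cam <- list(A = per_band(A), B = per_band(B), C_cal = per_band(C_cal),
              iso = iso, exposure = exposure, f_number = f_number,
              panel_reflectance = per_band(panel_reflectance))
  if (any(cam$A * iso * exposure + cam$C_cal <= 0))
    stop("A * iso * exposure + C_cal must be positive")
  structure(cam, class = "bc_camera")
}

dn_to_radiance <- function(P, cam, band) {
  cam$f_number^2 * (P - cam$B[[band]]) /
    (cam$A[[band]] * cam$iso * cam$exposure + cam$C_cal[[band]])
}

radiance_to_dn <- function(R, cam, band) {
  cam$B[[band]] + R *
    (cam$A[[band]] * cam$iso * cam$exposure + cam$C_cal[[band]]) /
    cam$f_number^2
}

#' Calibrate raw DN to reflectance
#'
#' @param raw A `bc_multiband` of raw DN.
#' @param cam A [camera_params()].
#' @param panel_dn Named per-band mean DN measured on the calibration panel
#'   with the same camera settings.
#' @return A `bc_multiband` of reflectance; negative values are floored at 0
#'   and their count attached as attribute `n_floored`.
#' @export
calibrate_dn <- function(raw, cam, panel_dn) {
  stopifnot(inherits(raw, "bc_multiband"), inherits(cam, "bc_camera"))
  panel_dn <- panel_dn[band_names()]
  if (anyNA(panel_dn)) stop("panel_dn must be named by band")
  n_floored <- 0
  bands <- lapply(band_names(), function(b) {
    R_ref <- dn_to_radiance(panel_dn[[b]], cam, b)
    if (R_ref <= 0) stop("panel pseudo-radiance <= 0 in band ", b,
                         " (panel darker than sensor bias)")
    K <- cam$panel_reflectance[[b]] / R_ref
    rho <- K * dn_to_radiance(raw$bands[[b]], cam, b)
    neg <- !is.na(rho) & rho < 0
    n_floored <<- n_floored + sum(neg)
    rho[neg] <- 0
    rho
  })
  out <- bc_multiband(raw$grid, stats::setNames(bands, band_names()))
  attr(out, "n_floored") <- n_floored
  out
}

#' Resample a field spectrum to sensor bands
#'
#' Response-weighted mean of the linearly interpolated spectrum.
#'
#' @param wavelengths Strictly increasing wavelengths (nm) of the spectrum.
#' @param reflectance Spectrum reflectance at those wavelengths.
#' @param bands List of sensor bands, each `list(wavelength =, weight =)`
#'   with non-negative weights summing > 0; see [sensor_bands_gaussian()].
#' @return Named per-band reflectance.
#' @export
resample_spectrum <- function(wavelengths, reflectance, bands) {
  stopifnot(length(wavelengths) >= 2, all(diff(wavelengths) > 0),
            length(reflectance) == length(wavelengths))
  vapply(bands, function(b) {
    w <- b$weight
    stopifnot(all(w >= 0), sum(w) > 0)
    if (min(b$wavelength) < min(wavelengths) ||
        max(b$wavelength) > max(wavelengths))
      stop("band response support outside the spectrum range")
    v <- stats::approx(wavelengths, reflectance, xout = b$wavelength)$y
    sum(w * v) / sum(w)
  }, numeric(1))
}

#' Gaussian band-response model of the 4-band camera
#'
#' Band responses sampled as Gaussians centred on [band_centres()] with the
#' nominal half-widths (40/40/10/10 nm), a convenient stand-in where the
#' measured response function is not available.
#'
#' @param n Samples per band.
#' @return Named list of bands for [resample_spectrum()].
#' @export
sensor_bands_gaussian <- function(n = 41) {
  centres <- band_centres()
  half <- c(green = 40, red = 40, red_edge = 10, nir = 10)
  out <- lapply(band_names(), function(b) {
    wl <- seq(centres[[b]] - half[[b]], centres[[b]] + half[[b]],
              length.out = n)
    sigma <- half[[b]] / 2
    list(wavelength = wl, weight = exp(-0.5 * ((wl - centres[[b]]) / sigma)^2))
  })
  stats::setNames(out, band_names())
}

#' Fit an empirical-line correction
#'
#' Per-band ordinary least squares mapping sensor reflectance to ground
#' reflectance measured on reference targets (with exactly two targets this
#' is the line through both points). Any measured surface may serve as a
#' target (bright biocrust patches included).
#'
#' @param uav_reflectance,ground_reflectance Matrices or data frames with one
#'   column per band (named by [band_names()]) and one row per target.
#' @return An object of class `bc_empirical_line`: per band gain, offset,
#'   number of targets and residual s.d.
#' @export
fit_empirical_line <- function(uav_reflectance, ground_reflectance) {
  u <- as.data.frame(uav_reflectance); g <- as.data.frame(ground_reflectance)
  stopifnot(all(band_names() %in% names(u)), all(band_names() %in% names(g)),
            nrow(u) == nrow(g))
  if (nrow(u) < 2) stop("need at least 2 targets per band")
  coefs <- lapply(band_names(), function(b) {
    x <- u[[b]]; y <- g[[b]]
    if (length(unique(x)) < 2)
      stop("identical target reflectances in band ", b, " (singular fit)")
    fit <- stats::lm(y ~ x)
    # residual s.d. computed directly: noiseless targets fit exactly and
    # summary.lm would warn on the perfect fit
    rsd <- if (length(x) > 2)
      sqrt(sum(stats::resid(fit)^2) / (length(x) - 2)) else 0
    list(gain = unname(stats::coef(fit)[2]),
         offset = unname(stats::coef(fit)[1]),
         n = length(x),
         residual_sd = rsd)
  })
  structure(stats::setNames(coefs, band_names()), class = "bc_empirical_line")
}

#' Apply an empirical-line correction to an image
#'
#' @param model A [fit_empirical_line()] model.
#' @param image A `bc_multiband` of reflectance.
#' @return A corrected `bc_multiband`.
#' @export
apply_empirical_line <- function(model, image) {
  stopifnot(inherits(model, "bc_empirical_line"),
            inherits(image, "bc_multiband"))
  bands <- lapply(band_names(), function(b)
    model[[b]]$offset + model[[b]]$gain * image$bands[[b]])
  bc_multiband(image$grid, stats::setNames(bands, band_names()))
}
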