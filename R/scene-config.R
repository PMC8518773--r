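# Configuration of the synthetic study site. Defaults emulate a semi-arid
# gypsum hillslope in winter: soil moisture in the observed 4.44-22.6 % range
# (mean near 14 %), a dominant dry-tussock matrix with lichen- and
# moss-dominated biocrust patches, and a linear ATI-moisture link so the
# thermal pipeline has a known ground truth.

#' Hand-authored endmember reflectance table of the seven covers
#'
#' Mean reflectance per band plus a common per-band noise s.d. The table is
#' configuration data, chosen to satisfy the qualitative spectral ordering of
#' the field classes: bright lichens (BL) are the brightest cover; mosses are
#' the darkest biocrust, with only dry vegetation darker still; green
#' vegetation has the deepest chlorophyll absorption (lowest `CR_red`); bare
#' soil has no absorption (`CR_red` exactly 1, i.e. collinear bands).
#'
#' @return Data frame: `class`, `green`, `red`, `red_edge`, `nir`.
#' @export
default_endmembers <- function() {
  soil_red <- 0.28 + (0.34 - 0.28) * (660 - 550) / (735 - 550)  # on the line
  data.frame(
    class    = cover_classes(),
    green    = c(0.28, 0.42, 0.30, 0.14, 0.26, 0.12, 0.11),
    red      = c(soil_red, 0.44, 0.28, 0.085, 0.24, 0.05, 0.115),
    red_edge = c(0.34, 0.50, 0.38, 0.26, 0.34, 0.30, 0.15),
    nir      = c(0.36, 0.55, 0.44, 0.33, 0.40, 0.45, 0.17))
}

#' Default camera model of the synthetic scene
#'
#' Plausible small-camera settings (ISO 100, 1 ms exposure, f/2.2) with a
#' 16-bit DN range; `k_true` is the radiance-to-reflectance coefficient the
#' generator uses when inverting the calibration, recoverable from the panel
#' DN it also produces.
#'
#' @export
default_camera <- function() {
  cam <- camera_params(A = 0.5, B = 1000, C_cal = 50, iso = 100,
                       exposure = 0.001, f_number = 2.2,
                       panel_reflectance = 0.5)
  cam$k_true <- stats::setNames(rep(2e-4, 4), band_names())
  cam$dn_max <- 65535
  cam
}

#' Synthetic scene configuration
#'
#' @param extent `c(width, height)` of the site in metres.
#' @param cell_size Cell size in metres.
#' @param seed Integer seed; one seed reproduces the whole scene bit-exactly.
#' @param plane_gradient `c(dz/dx, dz/dy)`, the regional tilt (unitless).
#' @param bump_amplitude,bump_count Amplitude (m) and number of smooth
#'   Gaussian knolls added to the plane.
#' @param moisture_link `c(m0, m_north, m_psir, noise_sd)` in moisture %:
#'   moisture = m0 + m_north * normalized northernness + m_psir * normalized
#'   PSIR + noise.
#' @param clip_moisture Moisture clipped to this range (%), the observed
#'   field range.
#' @param ati_link `c(a, b)`: true ATI = a + b * moisture (1/K per %).
#' @param thermal_baseline Pre-dawn surface temperature, degrees C.
#' @param thermal_noise_sd Gaussian noise s.d. on each thermal image (K;
#'   default 0.75, the calibration-level accuracy of uncooled thermal
#'   cameras).
#' @param class_priors Named probabilities of the seven covers (sum 1).
#' @param class_response Log-odds shift per standard deviation of moisture:
#'   Moss rises by this, the lichen classes (BL, BLM, Fulg) fall by half of
#'   it.
#' @param veg_clump_radius Smoothing radius (m) of the noise field whose
#'   upper quantiles become vegetation clumps.
#' @param reflectance_noise_sd Per-band Gaussian reflectance noise s.d.
#' @param endmembers Endmember table ([default_endmembers()]).
#' @param camera Camera model ([default_camera()]).
#' @param smooth_radius Optional Gaussian smoothing radius (m) applied to the
#'   moisture noise, giving spatially correlated noise (0 = independent).
#' @export
scene_config <- function(extent = c(140, 140), cell_size = 1, seed = 1,
                         plane_gradient = c(0.05, 0.08),
                         bump_amplitude = 1.5, bump_count = 12,
                         moisture_link = c(m0 = 10, m_north = 8,
                                           m_psir = -6, noise_sd = 1),
                         clip_moisture = c(4.44, 22.6),
                         ati_link = c(a = 0.02, b = 0.003),
                         thermal_baseline = 5, thermal_noise_sd = 0.75,
                         class_priors = c(Soil = 0.05, BL = 0.03, BLM = 0.10,
                                          Moss = 0.17, Fulg = 0.07,
                                          GreenVeg = 0.10, DryVeg = 0.48),
                         class_response = 0.8,
                         veg_clump_radius = 3,
                         reflectance_noise_sd = 0.012,
                         endmembers = default_endmembers(),
                         camera = default_camera(),
                         smooth_radius = 0) {
  stopifnot(length(extent) == 2, all(extent > 0), cell_size > 0)
  if (abs(sum(class_priors) - 1) > 1e-9) stop("class priors must sum to 1")
  if (!setequal(names(class_priors), cover_classes()))
    stop("class priors must be named by the 7 covers")
  a <- ati_link[[1]]; b <- ati_link[[2]]
  if (a + b * clip_moisture[1] <= 0)
    stop("ati_link must keep true ATI positive at the moisture floor")
  structure(list(extent = extent, cell_size = cell_size, seed = seed,
                 plane_gradient = plane_gradient,
                 bump_amplitude = bump_amplitude, bump_count = bump_count,
                 moisture_link = moisture_link,
                 clip_moisture = clip_moisture, ati_link = ati_link,
                 thermal_baseline = thermal_baseline,
                 thermal_noise_sd = thermal_noise_sd,
                 class_priors = class_priors[cover_classes()],
                 class_response = class_response,
                 veg_clump_radius = veg_clump_radius,
                 reflectance_noise_sd = reflectance_noise_sd,
                 endmembers = endmembers, camera = camera,
                 smooth_radius = smooth_radius),
            class = "bc_scene_config")
}
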