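# Annual potential solar incoming radiation (PSIR) over a DTM under a
# uniform clear sky: direct beam attenuated as transmissivity^airmass with
# airmass = 1/cos(zenith), projected on the tilted cell, plus an isotropic
# diffuse fraction weighted by the sky-view term (1 + cos slope)/2.
# Optional terrain shading uses per-cell horizon angles ray-marched in the
# eight compass directions.

#' PSIR configuration
#'
#' @param latitude Site latitude in degrees (default 40.03 N).
#' @param transmissivity Atmospheric transmissivity of the clear sky
#'   (default 0.5).
#' @param diffuse_proportion Fraction of the attenuated beam added as
#'   isotropic diffuse radiation (default 0.3).
#' @param solar_constant Top-of-atmosphere irradiance, W/m^2.
#' @param day_step Days between sampled days (the annual integral weights
#'   each sampled day by this step).
#' @param hour_step Hours between sampled sun positions within a day.
#' @param horizon_shading Zero the direct beam when the sun is below the
#'   terrain horizon along its azimuth (8-direction ray march).
#' @param max_ray Maximum horizon ray length in metres (caps the ray march).
#' @export
psir_config <- function(latitude = 40.03, transmissivity = 0.5,
                        diffuse_proportion = 0.3, solar_constant = 1367,
                        day_step = 5, hour_step = 0.25,
                        horizon_shading = TRUE, max_ray = 100) {
  stopifnot(transmissivity > 0, transmissivity <= 1,
            diffuse_proportion >= 0, diffuse_proportion <= 1,
            day_step >= 1, hour_step > 0)
  if (abs(latitude) >= 90) stop("|latitude| must be < 90 degrees")
  list(latitude = latitude, transmissivity = transmissivity,
       diffuse_proportion = diffuse_proportion,
       solar_constant = solar_constant, day_step = day_step,
       hour_step = hour_step, horizon_shading = horizon_shading,
       max_ray = max_ray)
}

# tangent of the terrain horizon angle in each of the 8 compass directions,
# computed by whole-grid shifts out to max_ray
horizon_tangents <- function(z, cell_size, max_ray) {
  dirs <- list(N = c(-1, 0), NE = c(-1, 1), E = c(0, 1), SE = c(1, 1),
               S = c(1, 0), SW = c(1, -1), W = c(0, -1), NW = c(-1, -1))
  out <- lapply(dirs, function(o) {
    len <- sqrt(sum(o^2)) * cell_size
    kmax <- max(1, floor(max_ray / len))
    tanh_ <- matrix(0, nrow(z), ncol(z))
    for (k in seq_len(kmax)) {
      s <- shift_mat(z, o[1] * k, o[2] * k)
      t <- (s - z) / (k * len)
      upd <- !is.na(t) & t > tanh_
      tanh_[upd] <- t[upd]
    }
    tanh_
  })
  out
}

#' Annual potential solar incoming radiation
#'
#' Integrates the clear-sky direct + diffuse irradiance on every (tilted)
#' cell over one year at the configured day/hour sampling, in Wh/m^2/yr.
#' The result depends on elevation only through slope, aspect and (when
#' shading is on) horizon geometry, so it is invariant to adding a constant
#' to the DTM.
#'
#' @param dtm A `bc_raster` (used for horizon shading geometry).
#' @param slope,aspect `bc_raster`s from [slope_aspect()] (degrees).
#' @param config A [psir_config()].
#' @return A `bc_raster` of annual insolation (Wh/m^2/yr).
#' @export
psir_annual <- function(dtm, slope, aspect, config = psir_config()) {
  assert_aligned(dtm, slope); assert_aligned(dtm, aspect)
  phi <- config$latitude * pi / 180
  s_rad <- slope$values * pi / 180
  a_rad <- aspect$values * pi / 180
  a_rad[is.na(a_rad)] <- 0          # flat cells: aspect irrelevant (sin s = 0)
  cos_s <- cos(s_rad); sin_s <- sin(s_rad)
  cos_a <- cos(a_rad); sin_a <- sin(a_rad)
  sky <- (1 + cos_s) / 2
  live <- !is.na(slope$values)
  total <- matrix(0, nrow(s_rad), ncol(s_rad))
  hor <- NULL
  dir_names <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  if (config$horizon_shading)
    hor <- horizon_tangents(dtm$values, dtm$grid$cell_size, config$max_ray)
  days <- seq(1, 365, by = config$day_step)
  hours <- seq(config$hour_step / 2, 24 - config$hour_step / 2,
               by = config$hour_step)
  for (d in days) {
    delta <- 23.45 * pi / 180 * sin(2 * pi * (284 + d) / 365)
    for (t in hours) {
      H <- (t - 12) * 15 * pi / 180
      cosz <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(H)
      if (cosz <= 1e-6) next
      sinz <- sqrt(1 - cosz^2)
      sun_e <- -cos(delta) * sin(H)
      sun_n <- cos(phi) * sin(delta) - sin(phi) * cos(delta) * cos(H)
      az <- atan2(sun_e, sun_n)
      beam <- config$solar_constant * config$transmissivity^(1 / cosz)
      cos_inc <- cosz * cos_s + sinz * sin_s *
        (cos(az) * cos_a + sin(az) * sin_a)
      cos_inc[cos_inc < 0] <- 0
      if (!is.null(hor)) {
        k <- 1 + (round((az * 180 / pi) %% 360 / 45) %% 8)
        shaded <- hor[[dir_names[k]]] > (cosz / max(sinz, 1e-9))
        cos_inc[shaded] <- 0
      }
      total <- total + config$hour_step *
        (beam * cos_inc + config$diffuse_proportion * beam * sky)
    }
  }
  total <- total * config$day_step
  total[!live] <- NA
  bc_raster(dtm$grid, total)
}
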