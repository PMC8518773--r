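# End-to-end drivers: from a DTM to the terrain attribute stack, and from a
# full (synthetic or measured) scene to the plot- and landscape-level
# statistics. These are the functions the analysis scripts and the
# acceptance checks call.

#' Terrain attribute stack from a DTM
#'
#' Pit filling (with a strict-drainage epsilon), Zevenbergen-Thorne slope and
#' aspect, northernness, D-infinity specific catchment area, TWI, LSF and
#' annual PSIR; optionally a circular focal smoothing of the DTM first.
#'
#' @param dtm A `bc_raster` DTM.
#' @param psir_cfg A [psir_config()].
#' @param lsf_par An [lsf_params()].
#' @param smooth_diameter Diameter (m) of the circular pre-smoothing window
#'   (0 = off).
#' @param fill_eps Epsilon for [fill_pits()].
#' @return Named list of aligned `bc_raster`s: `elevation`, `slope`,
#'   `aspect`, `northernness`, `cca`, `twi`, `lsf`, `psir`.
#' @export
terrain_stack <- function(dtm, psir_cfg = psir_config(),
                          lsf_par = lsf_params(), smooth_diameter = 0,
                          fill_eps = 1e-6) {
  if (smooth_diameter > 0) dtm <- focal_mean_circular(dtm, smooth_diameter)
  filled <- fill_pits(dtm, eps = fill_eps)
  sa <- slope_aspect(dtm)
  flow <- dinf_flow(filled)
  cca <- dinf_area(flow)
  list(elevation = dtm, slope = sa$slope, aspect = sa$aspect,
       northernness = northernness(sa$aspect), cca = cca,
       twi = twi(cca, sa$slope), lsf = lsf(cca, sa$slope, lsf_par),
       psir = psir_annual(dtm, sa$slope, sa$aspect, psir_cfg))
}

#' Landscape ordination of a classified scene
#'
#' Samples minimum-distance points over the vegetation-free area, extracts
#' biocrust cover responses and terrain + ATI + cover-fraction predictors in
#' circular buffers, and fits the RDA. Responses are the biocrust covers
#' (BL, BLM, Moss, Fulg); vegetation and soil fractions join the predictors.
#'
#' @param classes A `bc_classraster`.
#' @param attrs Named list of predictor rasters (e.g. from [terrain_stack()]
#'   plus `ati`).
#' @param config An [ordination_config()].
#' @return List: `points`, `Y`, `X`, `rda` ([rda_fit()] result).
#' @export
landscape_rda <- function(classes, attrs, config = ordination_config()) {
  mask <- bc_raster(classes$grid,
                    ifelse(is.na(classes$labels), NA, 1))
  pts <- sample_min_distance(mask, config)
  cov <- extract_cover(classes, pts, config$buffer_radius)
  X <- as.data.frame(lapply(attrs, extract_attr, points = pts,
                            radius = config$buffer_radius))
  X$veg <- cov$veg_fraction
  X$soil <- cov$soil_fraction
  Y <- cov$cover[, c("BL", "BLM", "Moss", "Fulg")]
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  list(points = pts[keep, ], Y = Y, X = X, rda = rda_fit(Y, X))
}
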