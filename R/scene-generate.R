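# Synthetic scene generation. Each generate_* step draws from its own
# deterministic substream (seed + fixed offset) so the full scene is
# bit-reproducible per seed, and intermediate products can be regenerated
# independently.

round_half_up <- function(x) floor(x + 0.5)

scene_grid <- function(config) {
  nc <- round(config$extent[1] / config$cell_size)
  nr <- round(config$extent[2] / config$cell_size)
  bc_grid(nr, nc, config$cell_size, origin = c(0, config$extent[2]))
}

minmax01 <- function(v) {
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  if (hi <= lo) stop("constant field: min-max normalization undefined")
  (v - lo) / (hi - lo)
}

gaussian_smooth <- function(m, radius_cells) {
  if (radius_cells <= 0) return(m)
  r <- ceiling(3 * radius_cells)
  acc <- matrix(0, nrow(m), ncol(m)); wsum <- matrix(0, nrow(m), ncol(m))
  for (di in -r:r) for (dj in -r:r) {
    w <- exp(-0.5 * (di^2 + dj^2) / radius_cells^2)
    if (w < 1e-4) next
    s <- shift_mat(m, di, dj)
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + w * s[ok]
    wsum[ok] <- wsum[ok] + w
  }
  out <- acc / wsum
  out[is.na(m)] <- NA
  out
}

#' Generate the synthetic DTM
#'
#' An inclined plane plus seeded smooth Gaussian knolls; with
#' `bump_amplitude = 0` the surface is exactly the plane.
#'
#' @param config A [scene_config()].
#' @return A `bc_raster` of elevation (m).
#' @export
generate_dtm <- function(config) {
  g <- scene_grid(config)
  cc <- cell_centres(g)
  gx <- config$plane_gradient[1]; gy <- config$plane_gradient[2]
  z <- outer(cc$y * gy, cc$x * gx, `+`)
  if (config$bump_amplitude > 0 && config$bump_count > 0) {
    set.seed(config$seed + 101L)
    for (b in seq_len(config$bump_count)) {
      bx <- stats::runif(1, 0, config$extent[1])
      by <- stats::runif(1, 0, config$extent[2])
      amp <- config$bump_amplitude * stats::runif(1, 0.4, 1) *
        sample(c(-1, 1), 1)          # knolls and hollows, zero-mean terrain
      sig <- stats::runif(1, 0.06, 0.15) * min(config$extent)
      z <- z + amp * exp(-0.5 * (outer((cc$y - by)^2, (cc$x - bx)^2, `+`)) /
                           sig^2)
    }
  }
  bc_raster(g, z)
}

#' Generate the soil-moisture field
#'
#' `moisture = m0 + m_north * northernness01 + m_psir * psir01 + noise`,
#' where the hats are min-max-normalized inputs, then clipped to the
#' configured range. North-facing, low-insolation cells end up wetter.
#'
#' @param dtm,northern,psir Aligned `bc_raster`s (elevation is unused but
#'   kept in the signature for interface symmetry).
#' @param config A [scene_config()].
#' @return A `bc_raster` of moisture (%).
#' @export
generate_moisture <- function(dtm, northern, psir, config) {
  assert_aligned(dtm, northern); assert_aligned(dtm, psir)
  ml <- config$moisture_link
  nhat <- if (ml[[2]] != 0) minmax01(northern$values) else 0
  phat <- if (ml[[3]] != 0) minmax01(psir$values) else 0
  m <- ml[[1]] + ml[[2]] * nhat + ml[[3]] * phat
  if (length(m) == 1) m <- matrix(m, dtm$grid$nrows, dtm$grid$ncols)
  if (ml[[4]] > 0) {
    set.seed(config$seed + 202L)
    noise <- matrix(stats::rnorm(length(m), 0, ml[[4]]), nrow(m), ncol(m))
    if (config$smooth_radius > 0) {
      noise <- gaussian_smooth(noise, config$smooth_radius / config$cell_size)
      noise <- noise / stats::sd(noise) * ml[[4]]
    }
    m <- m + noise
  }
  m <- pmin(pmax(m, config$clip_moisture[1]), config$clip_moisture[2])
  if (ml[[2]] != 0) m[is.na(northern$values)] <- NA
  if (ml[[3]] != 0) m[is.na(psir$values)] <- NA
  bc_raster(dtm$grid, m)
}

#' Generate the surface-cover map
#'
#' Vegetation (GreenVeg, DryVeg) forms clumped patches: Gaussian-smoothed
#' white noise thresholded at the prior-matching quantile. The remaining
#' cells draw a cover from a multinomial whose Moss log-odds rise with
#' standardized moisture while the lichen-class (BL, BLM, Fulg) log-odds
#' fall at half that rate, reproducing the moss-wet / lichen-dry contrast.
#'
#' @param moisture A `bc_raster` of moisture (%).
#' @param config A [scene_config()].
#' @return A `bc_classraster`.
#' @export
generate_class_map <- function(moisture, config) {
  pr <- config$class_priors
  if (abs(sum(pr) - 1) > 1e-9) stop("class priors must sum to 1")
  g <- moisture$grid
  m <- moisture$values
  set.seed(config$seed + 303L)
  nr <- g$nrows; nc <- g$ncols
  lab <- matrix(NA_integer_, nr, nc)
  # vegetation clumps
  p_veg <- pr[["GreenVeg"]] + pr[["DryVeg"]]
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  field <- gaussian_smooth(noise, config$veg_clump_radius / g$cell_size)
  veg <- field >= stats::quantile(field, 1 - p_veg)
  p_green <- pr[["GreenVeg"]] / p_veg
  is_green <- matrix(stats::runif(nr * nc) < p_green, nr, nc)
  lab[veg & is_green] <- match("GreenVeg", cover_classes())
  lab[veg & !is_green] <- match("DryVeg", cover_classes())
  # ground covers: moisture-tilted multinomial over the non-vegetation cells
  ground <- c("Soil", "BL", "BLM", "Moss", "Fulg")
  open <- which(!veg)
  zm <- (m - mean(m, na.rm = TRUE)) / stats::sd(m, na.rm = TRUE)
  if (!is.finite(zm[1]) && stats::sd(m, na.rm = TRUE) == 0) zm <- 0 * m
  beta <- stats::setNames(rep(0, length(ground)), ground)
  beta["Moss"] <- config$class_response
  beta[c("BL", "BLM", "Fulg")] <- -config$class_response / 2
  logit <- vapply(ground, function(cl) log(pr[[cl]]) + beta[[cl]] * zm[open],
                  numeric(length(open)))
  pmat <- exp(logit)
  pmat <- pmat / rowSums(pmat)
  u <- stats::runif(length(open))
  cum <- t(apply(pmat, 1, cumsum))
  pick <- 1L + rowSums(u > cum)
  pick[pick > length(ground)] <- length(ground)
  lab[open] <- match(ground, cover_classes())[pick]
  lab[is.na(m)] <- NA
  bc_classraster(g, lab)
}

#' Generate the multispectral pair (reflectance and raw DN)
#'
#' Reflectance is the class endmember plus independent Gaussian noise,
#' floored at 0; the raw DN image inverts the radiometric calibration
#' (`P = B + rho (A gamma eps + C) / (K f^2)`), rounding half-up to integers
#' and clamping to the sensor range, so [calibrate_dn()] recovers the
#' reflectance to within one DN quantization step.
#'
#' @param classes A `bc_classraster`.
#' @param config A [scene_config()].
#' @return List: `reflectance` and `raw_dn` (`bc_multiband`), plus
#'   `panel_dn` (named per-band panel DN for [calibrate_dn()]).
#' @export
generate_multispectral <- function(classes, config) {
  g <- classes$grid
  em <- config$endmembers
  cam <- config$camera
  if (is.null(cam$k_true)) stop("camera must carry k_true for DN inversion")
  set.seed(config$seed + 404L)
  lab <- classes$labels
  idx <- match(cover_classes()[lab], em$class)
  refl <- list(); dn <- list()
  for (b in band_names()) {
    mu <- matrix(em[[b]][idx], g$nrows, g$ncols)
    if (config$reflectance_noise_sd > 0)
      mu <- mu + matrix(stats::rnorm(length(mu), 0,
                                     config$reflectance_noise_sd),
                        g$nrows, g$ncols)
    mu[mu < 0] <- 0
    refl[[b]] <- mu
    R <- mu / cam$k_true[[b]]
    P <- round_half_up(radiance_to_dn(R, cam, b))
    P <- pmin(pmax(P, 0), cam$dn_max)
    dn[[b]] <- P
  }
  panel_dn <- vapply(band_names(), function(b) {
    R_ref <- cam$panel_reflectance[[b]] / cam$k_true[[b]]
    round_half_up(radiance_to_dn(R_ref, cam, b))
  }, numeric(1))
  list(reflectance = bc_multiband(g, refl),
       raw_dn = bc_multiband(g, dn),
       panel_dn = panel_dn)
}

#' Generate the pre-dawn / noon thermal pair
#'
#' The diurnal amplitude inverts the ATI identity:
#' `deltaT = C (1 - albedo) / ATI_true` with `ATI_true = a + b * moisture`,
#' so the thermal pipeline recovers `ATI_true` exactly at zero noise.
#' Temperatures are also emitted as raw DN (`R = 100 (T + 100)`, rounded).
#'
#' @param moisture A `bc_raster` of moisture (%).
#' @param albedo_r A `bc_raster` of albedo.
#' @param config A [scene_config()]; `ati_config()$C_solar` is the same C
#'   used downstream.
#' @param ati_cfg An [ati_config()].
#' @return List: `t_predawn`, `t_noon` (degrees C), `dn_predawn`, `dn_noon`,
#'   `ati_true`.
#' @export
generate_thermal_pair <- function(moisture, albedo_r, config,
                                  ati_cfg = ati_config()) {
  assert_aligned(moisture, albedo_r)
  a <- config$ati_link[[1]]; b <- config$ati_link[[2]]
  ati_true <- a + b * moisture$values
  if (any(ati_true <= 0, na.rm = TRUE))
    stop("true ATI must be positive everywhere")
  dt <- ati_cfg$C_solar * (1 - albedo_r$values) / ati_true
  g <- moisture$grid
  t1 <- matrix(config$thermal_baseline, g$nrows, g$ncols)
  if (config$thermal_noise_sd > 0) {
    set.seed(config$seed + 505L)
    t1 <- t1 + matrix(stats::rnorm(length(t1), 0, config$thermal_noise_sd),
                      g$nrows, g$ncols)
    dt <- dt + matrix(stats::rnorm(length(dt), 0, config$thermal_noise_sd),
                      g$nrows, g$ncols)
  }
  t2 <- t1 + dt
  na <- is.na(moisture$values) | is.na(albedo_r$values)
  t1[na] <- NA; t2[na] <- NA
  list(t_predawn = bc_raster(g, t1), t_noon = bc_raster(g, t2),
       dn_predawn = bc_raster(g, round_half_up(100 * (t1 + 100))),
       dn_noon = bc_raster(g, round_half_up(100 * (t2 + 100))),
       ati_true = bc_raster(g, ati_true))
}

#' Generate the field-plot table
#'
#' `n_plots` non-overlapping 2 x 2 m plots at seeded locations. Plot
#' moisture is the zonal mean of the moisture field; soluble salts decrease
#' and organic carbon, total P and total N increase with plot northernness
#' (plus noise), clipped to the observed field ranges; fractional covers come
#' from the class map.
#'
#' @param moisture,northern Aligned `bc_raster`s.
#' @param classes A `bc_classraster`.
#' @param n_plots Number of plots (default 23).
#' @param config A [scene_config()].
#' @param side Plot side in metres.
#' @return Data frame: `plot_id`, `x`, `y`, `side`, `moisture`, `SolSal`,
#'   `OrgCarb`, `P_tot`, `N_tot` and the seven cover-fraction columns
#'   `cover_*`.
#' @export
generate_plot_table <- function(moisture, northern, classes, n_plots = 23,
                                config, side = 2) {
  assert_aligned(moisture, northern); assert_aligned(moisture, classes)
  g <- moisture$grid
  set.seed(config$seed + 606L)
  xr <- c(side, g$ncols * g$cell_size - side)
  yr <- c(side, g$nrows * g$cell_size - side)
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n_plots && tries < 2000 * n_plots) {
    tries <- tries + 1
    px <- stats::runif(1, xr[1], xr[2])
    py <- g$origin[2] - stats::runif(1, yr[1], yr[2])
    if (length(xs) && any(abs(xs - px) < side & abs(ys - py) < side)) next
    lab <- classes$labels[plot_cells(g, px, py, side)]
    lab <- lab[!is.na(lab)]
    # field plots characterize plant interspaces: reject locations whose
    # footprint is entirely vascular vegetation
    veg_codes <- match(c("GreenVeg", "DryVeg"), cover_classes())
    if (!length(lab) || all(lab %in% veg_codes)) next
    xs <- c(xs, px); ys <- c(ys, py)
  }
  if (length(xs) < n_plots)
    stop("could not place ", n_plots, " non-overlapping plots")
  plots <- data.frame(plot_id = seq_len(n_plots), x = xs, y = ys, side = side)
  plots$moisture <- zonal_mean(moisture, plots)$mean
  nmean <- zonal_mean(northern, plots)$mean
  nhat <- nmean / 2                                   # northernness in [0,2]
  clip <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  n <- n_plots
  plots$SolSal <- clip(88 - 25 * nhat + stats::rnorm(n, 0, 5), 19, 96)
  plots$OrgCarb <- clip(0.4 + 1.8 * nhat + stats::rnorm(n, 0, 0.3),
                        0.14, 3.96)
  plots$P_tot <- clip(0.2 + 1.2 * nhat + stats::rnorm(n, 0, 0.3), 0, 7.26)
  plots$N_tot <- clip(0.03 + 0.12 * nhat + stats::rnorm(n, 0, 0.02),
                      0.01, 0.37)
  plots$northernness <- nmean
  covs <- matrix(0, n, length(cover_classes()),
                 dimnames = list(NULL, paste0("cover_", cover_classes())))
  for (i in seq_len(n)) {
    idx <- plot_cells(g, plots$x[i], plots$y[i], side)
    lab <- classes$labels[idx]
    lab <- lab[!is.na(lab)]
    if (!length(lab)) stop("plot ", i, " covers no classified cells")
    covs[i, ] <- tabulate(lab, nbins = length(cover_classes())) / length(lab)
  }
  cbind(plots, as.data.frame(covs))
}

#' Generate a complete synthetic scene
#'
#' Runs the whole generator: DTM, terrain attributes (needed for the
#' moisture field), moisture, class map, multispectral pair, thermal pair
#' and plot table, returning every product plus the ground-truth parameters.
#'
#' @param config A [scene_config()].
#' @param n_plots Number of field plots.
#' @param psir_cfg A [psir_config()] for the insolation input to moisture.
#' @param ati_cfg An [ati_config()].
#' @return List of scene products (see the individual generators).
#' @export
generate_scene <- function(config = scene_config(), n_plots = 23,
                           psir_cfg = psir_config(),
                           ati_cfg = ati_config()) {
  dtm <- generate_dtm(config)
  sa <- slope_aspect(dtm)
  north <- northernness(sa$aspect)
  psir <- psir_annual(dtm, sa$slope, sa$aspect, psir_cfg)
  moist <- generate_moisture(dtm, north, psir, config)
  classes <- generate_class_map(moist, config)
  ms <- generate_multispectral(classes, config)
  alb <- albedo(ms$reflectance)
  th <- generate_thermal_pair(moist, alb, config, ati_cfg)
  plots <- generate_plot_table(moist, north, classes, n_plots, config)
  list(config = config, dtm = dtm, slope = sa$slope, aspect = sa$aspect,
       northernness = north, psir = psir, moisture = moist,
       classes = classes, reflectance = ms$reflectance, raw_dn = ms$raw_dn,
       panel_dn = ms$panel_dn, albedo = alb,
       t_predawn = th$t_predawn, t_noon = th$t_noon,
       dn_predawn = th$dn_predawn, dn_noon = th$dn_noon,
       ati_true = th$ati_true, plots = plots)
}
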