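# Shared fixtures: tiny deterministic rasters and a small default scene.

plane_raster <- function(gx = 0, gy = 0, n = 9, h = 1, z0 = 10) {
  g <- bc_grid(n, n, h, origin = c(0, n * h))
  cc <- cell_centres(g)
  bc_raster(g, outer(cc$y * gy, cc$x * gx, `+`) + z0)
}

# coarse solar sampling for test scenes: keeps the annual integral cheap
# while preserving slope/aspect contrast
psir_coarse <- function(shading = FALSE) {
  psir_config(day_step = 30, hour_step = 1, horizon_shading = shading)
}

small_scene <- function(seed = 1, extent = 40, ...) {
  cfg <- scene_config(extent = c(extent, extent), cell_size = 1, seed = seed,
                      ...)
  generate_scene(cfg, n_plots = 10, psir_cfg = psir_coarse())
}

# independent brute-force D-infinity accumulation: recursive definition
# A(c) = cell area + sum over donors of their proportional contribution
brute_force_dinf_area <- function(flow) {
  z <- flow$elev
  n <- length(z)
  h <- flow$grid$cell_size
  donors <- vector("list", n)
  props <- vector("list", n)
  for (c0 in seq_len(n)) {
    if (is.na(z[c0])) next
    if (flow$p1[c0] > 0 && !is.na(flow$rec1[c0])) {
      r <- flow$rec1[c0]
      donors[[r]] <- c(donors[[r]], c0); props[[r]] <- c(props[[r]], flow$p1[c0])
    }
    if (flow$p2[c0] > 0 && !is.na(flow$rec2[c0])) {
      r <- flow$rec2[c0]
      donors[[r]] <- c(donors[[r]], c0); props[[r]] <- c(props[[r]], flow$p2[c0])
    }
  }
  acc <- rep(NA_real_, n)
  visiting <- rep(FALSE, n)
  rec <- function(c0) {
    if (!is.na(acc[c0])) return(acc[c0])
    if (visiting[c0]) stop("cycle")
    visiting[c0] <<- TRUE
    a <- h^2
    ds <- donors[[c0]]
    if (length(ds))
      for (k in seq_along(ds)) a <- a + props[[c0]][k] * rec(ds[k])
    visiting[c0] <<- FALSE
    acc[c0] <<- a
    a
  }
  for (c0 in seq_len(n)) if (!is.na(z[c0])) rec(c0)
  matrix(acc / h, nrow(z), ncol(z))
}

random_rough_dtm <- function(seed, n = 6, h = 1) {
  set.seed(seed)
  g <- bc_grid(n, n, h, origin = c(0, n * h))
  cc <- cell_centres(g)
  z <- outer(cc$y * runif(1, -0.3, 0.3), cc$x * runif(1, -0.3, 0.3), `+`) +
    matrix(rnorm(n * n, sd = 0.2), n, n)
  bc_raster(g, z)
}
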