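test_that("fill_pits raises a pit exactly to its spill and never lowers", {
  flat <- plane_raster(gx = 0.1, n = 5)
  expect_equal(fill_pits(flat)$values, flat$values)

  g <- bc_grid(5, 5, 1)
  z <- matrix(10, 5, 5)
  z[3, 3] <- 9                       # 1 m pit in a flat plateau
  z[3, 4] <- 9.8; z[3, 5] <- 9.8     # spill corridor to the boundary
  r <- fill_pits(bc_raster(g, z))
  expect_equal(r$values[3, 3], 9.8)  # raised exactly to the spill elevation
  expect_true(all(r$values >= z))

  set.seed(42)
  rough <- bc_raster(g, matrix(rnorm(25), 5, 5))
  expect_true(all(fill_pits(rough, eps = 1e-6)$values >= rough$values))
  expect_error(fill_pits(bc_raster(g, matrix(NA_real_, 5, 5))), "all-nodata")
})

test_that("slope/aspect match the closed form for planes", {
  # plane falling eastward at gradient 0.5: slope atan(0.5), aspect 90
  east <- plane_raster(gx = -0.5, n = 7)
  sa <- slope_aspect(east)
  expect_equal(sa$slope$values, matrix(atan(0.5) * 180 / pi, 7, 7),
               tolerance = 1e-10)
  expect_equal(sa$aspect$values, matrix(90, 7, 7), tolerance = 1e-10)

  # rotating the plane 90 degrees rotates the aspect by 90
  south <- plane_raster(gy = 0.5, n = 7)  # z grows northward -> falls south
  expect_equal(slope_aspect(south)$aspect$values, matrix(180, 7, 7),
               tolerance = 1e-10)

  flat <- plane_raster(n = 5)
  saf <- slope_aspect(flat)
  expect_equal(saf$slope$values, matrix(0, 5, 5))
  expect_true(all(is.na(saf$aspect$values)))
  expect_error(slope_aspect(plane_raster(n = 2)), "3x3")
})

test_that("northernness maps compass aspect to [0, 2] and pairs with southness", {
  g <- bc_grid(1, 4, 1)
  asp <- bc_raster(g, matrix(c(0, 90, 180, 270), 1, 4))
  n <- northernness(asp)
  expect_equal(as.vector(n$values), c(2, 1, 0, 1), tolerance = 1e-12)
  south <- cos((asp$values - 180) * pi / 180) + 1
  expect_equal(n$values + south, matrix(2, 1, 4), tolerance = 1e-12)
})

test_that("D-infinity routes cardinal and diagonal planes correctly", {
  east <- plane_raster(gx = -0.2, n = 6)
  fl <- dinf_flow(fill_pits(east, eps = 1e-9))
  i <- 3; j <- 3  # interior cell
  expect_equal(fl$angle[i, j], 0, tolerance = 1e-12)     # due east
  expect_equal(fl$p1[i, j], 1, tolerance = 1e-12)
  expect_equal(fl$rec1[i, j], which(row(east$values) == i &
                                      col(east$values) == j + 1))

  # plane dipping halfway between E and SE: 50/50 split
  g <- bc_grid(6, 6, 1)
  cc <- cell_centres(g)
  ang <- -pi / 8
  z <- -outer(cc$y * sin(ang), cc$x * cos(ang), `+`)
  fl2 <- dinf_flow(bc_raster(g, z))
  expect_equal(fl2$p1[3, 3], 0.5, tolerance = 1e-10)
  expect_equal(fl2$p2[3, 3], 0.5, tolerance = 1e-10)

  # symmetric cone, peak at the centre, falling outward. On a discretized
  # cone the facet planes tilt the steepest direction slightly off the
  # radial (about 0.12 rad at cardinal cells, 0.07 at diagonals, worse right
  # at the apex where "radial" is ill-defined); assert four-fold symmetry of
  # the deviation and the discretization bound away from the apex.
  n <- 9
  gc <- bc_grid(n, n, 1, origin = c(0, n))
  ccc <- cell_centres(gc)
  zc <- -sqrt(outer((ccc$y - 4.5)^2, (ccc$x - 4.5)^2, `+`))
  flc <- dinf_flow(bc_raster(gc, zc))
  quads <- c(flc$angle[2, 8] - pi / 4, flc$angle[8, 8] - 7 * pi / 4,
             flc$angle[8, 2] - 5 * pi / 4, flc$angle[2, 2] - 3 * pi / 4)
  expect_equal(max(quads) - min(quads), 0, tolerance = 1e-9)  # same tie-break
  radial <- atan2(outer(ccc$y - 4.5, rep(1, n)),
                  outer(rep(1, n), ccc$x - 4.5)) %% (2 * pi)
  interior <- matrix(FALSE, n, n); interior[2:(n - 1), 2:(n - 1)] <- TRUE
  interior[4:6, 4:6] <- FALSE     # apex neighbourhood: radial ill-defined
  dev <- abs(flc$angle - radial)
  dev <- pmin(dev, 2 * pi - dev)
  expect_lt(max(dev[interior], na.rm = TRUE), 0.17)
})

test_that("contributing area matches hand counts and conserves mass", {
  # ridge cell: own area only; single-file column accumulates k cells
  g <- bc_grid(6, 3, 1)
  cc <- cell_centres(g)
  z <- outer(cc$y, rep(0, 3), `+`)        # south-dipping channel grid
  z[, 1] <- z[, 1] + 0.5; z[, 3] <- z[, 3] + 0.5
  fl <- dinf_flow(bc_raster(g, z))
  area <- dinf_area(fl)
  expect_equal(area$values[1, 2], 1)      # top of channel: own area (A = h)
  expect_true(area$values[6, 2] > area$values[1, 2])

  # plane: row k from the top accumulates k cells of area in its column
  gp <- bc_grid(6, 6, 1)
  ccp <- cell_centres(gp)
  zp <- outer(ccp$y, rep(0, 6), `+`)
  ap <- dinf_area(dinf_flow(bc_raster(gp, zp)))
  expect_equal(ap$values[, 3], 1:6, tolerance = 1e-12)

  # mass conservation: outflow equals total grid area
  expect_equal(attr(ap, "outflow"), 36, tolerance = 1e-9)
})

test_that("D-infinity equals the brute-force oracle on random rough DTMs", {
  worst <- 0
  for (seed in 1:100) {
    dtm <- random_rough_dtm(seed)
    filled <- fill_pits(dtm, eps = 1e-6)
    fl <- dinf_flow(filled)
    fast <- dinf_area(fl)$values
    slow <- brute_force_dinf_area(fl)
    worst <- max(worst, max(abs(fast - slow)))
    total <- attr(dinf_area(fl), "outflow")
    expect_equal(total, 36, tolerance = 1e-6 * 36)
  }
  expect_lt(worst, 1e-9)
})

test_that("TWI and LSF reproduce their closed forms", {
  g <- bc_grid(2, 2, 1)
  a <- bc_raster(g, matrix(10, 2, 2))
  s45 <- bc_raster(g, matrix(45, 2, 2))
  expect_equal(twi(a, s45)$values[1, 1], log(10), tolerance = 1e-12)
  flat <- bc_raster(g, matrix(0, 2, 2))
  expect_equal(twi(a, flat)$values[1, 1], log(10 / 1e-3), tolerance = 1e-12)
  expect_error(twi(bc_raster(g, matrix(0, 2, 2)), s45), "positive")

  # unit case: A = 22.13, sin(beta) = 0.0896 -> LSF = n + 1 = 1.4
  beta <- asin(0.0896) * 180 / pi
  aa <- bc_raster(g, matrix(22.13, 2, 2))
  ss <- bc_raster(g, matrix(beta, 2, 2))
  expect_equal(lsf(aa, ss)$values[1, 1], 1.4, tolerance = 1e-12)
  expect_equal(lsf(bc_raster(g, matrix(0, 2, 2)), ss)$values[1, 1], 0)
  # doubling A multiplies LSF by 2^0.4
  a2 <- bc_raster(g, matrix(44.26, 2, 2))
  expect_equal(lsf(a2, ss)$values[1, 1] / lsf(aa, ss)$values[1, 1], 2^0.4,
               tolerance = 1e-12)
})

test_that("annual PSIR is uniform on flat ground, favours south slopes, and is elevation-invariant", {
  flat <- plane_raster(n = 5)
  cfg <- psir_coarse()
  p <- psir_annual(flat, slope_aspect(flat)$slope, slope_aspect(flat)$aspect,
                   cfg)
  expect_lt(diff(range(p$values)) / mean(p$values), 1e-9)
  expect_gt(mean(p$values), 0)

  # two-slope ridge: 20 deg south- vs north-facing at 40 N
  g <- bc_grid(11, 5, 1)
  cc <- cell_centres(g)
  ridge_y <- cc$y[6]
  z <- -abs(outer(cc$y - ridge_y, rep(0, 5), `+`)) * tan(20 * pi / 180)
  dtm <- bc_raster(g, z)
  sa <- slope_aspect(dtm)
  pr <- psir_annual(dtm, sa$slope, sa$aspect, cfg)
  south_mean <- mean(pr$values[8:10, ])   # below the ridge: south-facing
  north_mean <- mean(pr$values[2:4, ])
  expect_gt(south_mean, north_mean)

  # invariant to adding a constant to the DTM
  dtm2 <- bc_raster(g, z + 57)
  pr2 <- psir_annual(dtm2, sa$slope, sa$aspect, cfg)
  expect_equal(pr2$values, pr$values, tolerance = 1e-12)

  # transmissivity -> 0 kills the direct beam: output tends to diffuse-only
  cfg0 <- psir_config(transmissivity = 1e-8, day_step = 30, hour_step = 1,
                      horizon_shading = FALSE)
  p0 <- psir_annual(flat, slope_aspect(flat)$slope, slope_aspect(flat)$aspect,
                    cfg0)
  expect_lt(max(p0$values), 1e-3 * mean(p$values))
})

test_that("circular focal mean uses the plus-shaped window at 1 m / 0.5 m cells", {
  g <- bc_grid(3, 3, 0.5)
  v <- matrix(1:9, 3, 3)
  r <- bc_raster(g, v)
  sm <- focal_mean_circular(r, 1)
  # centre: cells within 0.5 m of centre = centre + 4 edge-adjacent cells
  expect_equal(sm$values[2, 2], mean(c(5, 2, 8, 4, 6)))
  expect_equal(focal_mean_circular(r, 0.4)$values, v + 0)   # identity
  const <- bc_raster(g, matrix(7, 3, 3))
  expect_equal(focal_mean_circular(const, 1)$values, matrix(7, 3, 3))
})
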