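test_that("DTM generator: plane degenerate case, determinism, bump mean", {
  cfg0 <- scene_config(extent = c(10, 10), cell_size = 1, seed = 4,
                       bump_amplitude = 0)
  dtm <- generate_dtm(cfg0)
  cc <- cell_centres(dtm$grid)
  expect_equal(dtm$values, outer(cc$y * 0.08, cc$x * 0.05, `+`),
               tolerance = 1e-12)

  cfg <- scene_config(extent = c(10, 10), cell_size = 1, seed = 4)
  expect_identical(generate_dtm(cfg)$values, generate_dtm(cfg)$values)

  # bumps are signed and zero-mean: over 50 seeds the Monte-Carlo mean of
  # (scene mean - plane mean) is within 3 s.e. of zero
  plane_mean <- mean(dtm$values)
  devs <- vapply(1:50, function(s) {
    mean(generate_dtm(scene_config(extent = c(10, 10), cell_size = 1,
                                   seed = s))$values) - plane_mean
  }, numeric(1))
  expect_lt(abs(mean(devs)) / (sd(devs) / sqrt(50)), 3)
  expect_error(generate_dtm(scene_config(extent = c(0, 10))))
})

test_that("moisture field: constant case, aspect contrast, observed range", {
  g <- bc_grid(11, 5, 1, origin = c(0, 11))
  cc <- cell_centres(g)
  ridge <- bc_raster(g, -abs(outer(cc$y - cc$y[6], rep(0, 5), `+`)) * 0.4)
  sa <- slope_aspect(ridge)
  north <- northernness(sa$aspect)
  psir <- psir_annual(ridge, sa$slope, sa$aspect, psir_coarse())

  cfg <- scene_config(extent = c(5, 11), cell_size = 1, seed = 2)
  m <- generate_moisture(ridge, north, psir, cfg)
  expect_true(all(m$values >= 4.44 & m$values <= 22.6, na.rm = TRUE))
  # north-facing rows (above the ridge, aspect 0) wetter than south-facing
  expect_gt(mean(m$values[2:4, ]), mean(m$values[8:10, ]))

  cfg0 <- scene_config(extent = c(5, 11), cell_size = 1, seed = 2,
                       moisture_link = c(10, 0, 0, 0))
  m0 <- generate_moisture(ridge, north, psir, cfg0)
  expect_equal(m0$values, matrix(10, 11, 5))

  # constant northernness with a nonzero coefficient is an error
  flatn <- bc_raster(g, matrix(1, 11, 5))
  expect_error(generate_moisture(ridge, flatn, psir,
                                 scene_config(extent = c(5, 11),
                                              cell_size = 1)),
               "constant")
})

test_that("class map: priors recovered, moss-moisture link, determinism", {
  g <- bc_grid(60, 60, 1, origin = c(0, 60))
  set.seed(8)
  m <- bc_raster(g, matrix(runif(3600, 5, 22), 60, 60))
  cfg0 <- scene_config(extent = c(60, 60), cell_size = 1, seed = 9,
                       class_response = 0)
  cl <- generate_class_map(m, cfg0)
  freq <- tabulate(cl$labels, 7) / 3600
  pr <- cfg0$class_priors
  # vegetation is placed by quantile thresholding (exact); multinomial
  # ground classes within 3 binomial s.e.
  for (k in 1:5) {
    se <- sqrt(pr[[k]] * (1 - pr[[k]]) / 3600)
    expect_lt(abs(freq[k] - pr[[k]]), 3 * se + 1e-9)
  }

  cfg1 <- scene_config(extent = c(60, 60), cell_size = 1, seed = 9)
  cl1 <- generate_class_map(m, cfg1)
  code <- function(x) match(x, cover_classes())
  expect_gt(mean(m$values[cl1$labels == code("Moss")]),
            mean(m$values[cl1$labels == code("BL")]))
  expect_identical(generate_class_map(m, cfg1)$labels, cl1$labels)
  bad <- cfg1; bad$class_priors[1] <- bad$class_priors[1] + 0.5
  expect_error(generate_class_map(m, bad), "sum to 1")
})

test_that("endmember table satisfies the field spectral ordering", {
  em <- default_endmembers()
  rownames(em) <- em$class
  brightness <- rowMeans(em[, band_names()])
  biocrusts <- c("BL", "BLM", "Moss", "Fulg")
  expect_equal(names(which.max(brightness[biocrusts])), "BL")
  expect_true(brightness[["BL"]] == max(brightness))          # brightest of all
  expect_equal(names(which.min(brightness[biocrusts])), "Moss")
  expect_lt(brightness[["DryVeg"]], brightness[["Moss"]])
  cr <- cr_red_values(em$green, em$red, em$red_edge)
  names(cr) <- em$class
  expect_equal(cr[["Soil"]], 1, tolerance = 1e-12)            # no absorption
  expect_equal(names(which.min(cr)), "GreenVeg")              # deepest
  expect_equal(names(which.min(cr[biocrusts])), "Moss")
  expect_lt(cr[["Moss"]], 0.75)                               # refinable
  expect_gt(cr[["DryVeg"]], 0.75)                             # not refinable
})

test_that("multispectral generator: exact endmembers at zero noise, BL > Moss brightness", {
  sc <- small_scene(seed = 21, reflectance_noise_sd = 0)
  em <- default_endmembers()
  code <- function(x) match(x, cover_classes())
  soil_px <- which(sc$classes$labels == code("Soil"))
  for (b in band_names())
    expect_true(all(sc$reflectance$bands[[b]][soil_px] ==
                      em[[b]][em$class == "Soil"]))
  bright <- Reduce(`+`, sc$reflectance$bands) / 4
  expect_gt(mean(bright[sc$classes$labels == code("BL")]),
            mean(bright[sc$classes$labels == code("Moss")]))
})

test_that("thermal pair: exact ATI round trip at zero noise, positive and monotone deltaT", {
  sc <- small_scene(seed = 13, thermal_noise_sd = 0)
  rec <- ati(sc$albedo, sc$t_predawn, sc$t_noon)
  expect_lt(max(abs(rec$values - sc$ati_true$values), na.rm = TRUE), 1e-10)
  dt <- sc$t_noon$values - sc$t_predawn$values
  expect_true(all(dt > 0, na.rm = TRUE))
  # deltaT strictly decreasing in moisture at fixed albedo
  cfg <- sc$config
  a <- 0.25
  m_seq <- seq(4.44, 22.6, length.out = 10)
  dt_seq <- 1.19 * (1 - a) / (cfg$ati_link[[1]] + cfg$ati_link[[2]] * m_seq)
  expect_true(all(diff(dt_seq) < 0))
  # thermal DN round trip within the 0.01 degC quantization
  t_back <- dn_to_temperature(sc$dn_noon)
  expect_lt(max(abs(t_back$values - sc$t_noon$values), na.rm = TRUE), 0.005 + 1e-12)
})

test_that("plot table: covers sum to 1, ranges respected, northernness trends", {
  sc <- small_scene(seed = 31, extent = 60)
  pl <- sc$plots
  cover_cols <- paste0("cover_", cover_classes())
  expect_equal(rowSums(pl[, cover_cols]), rep(1, nrow(pl)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(pl$moisture >= 4.44 & pl$moisture <= 22.6))
  expect_true(all(pl$SolSal >= 19 & pl$SolSal <= 96))
  expect_true(all(pl$OrgCarb >= 0.14 & pl$OrgCarb <= 3.96))
  expect_true(all(pl$P_tot >= 0 & pl$P_tot <= 7.26))
  expect_true(all(pl$N_tot >= 0.01 & pl$N_tot <= 0.37))
  # trend directions over a larger pooled sample (23 plots x several seeds)
  pool <- do.call(rbind, lapply(31:34, function(s)
    small_scene(seed = s, extent = 60)$plots))
  expect_lt(cor(pool$SolSal, pool$northernness), 0)
  expect_gt(cor(pool$OrgCarb, pool$northernness), 0)
  expect_gt(cor(pool$P_tot, pool$northernness), 0)
  expect_gt(cor(pool$N_tot, pool$northernness), 0)
})

test_that("one seed reproduces the full scene bit-exactly", {
  a <- small_scene(seed = 77)
  b <- small_scene(seed = 77)
  expect_identical(a$dtm$values, b$dtm$values)
  expect_identical(a$moisture$values, b$moisture$values)
  expect_identical(a$classes$labels, b$classes$labels)
  expect_identical(a$reflectance$bands, b$reflectance$bands)
  expect_identical(a$raw_dn$bands, b$raw_dn$bands)
  expect_identical(a$t_noon$values, b$t_noon$values)
  expect_identical(a$plots, b$plots)
})
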