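test_that("semivariogram: flat field, white noise, smoothed monotone rise", {
  set.seed(3)
  n <- 300
  x <- runif(n, 0, 50); y <- runif(n, 0, 50)
  sv0 <- empirical_semivariogram(x, y, rep(4, n), max_lag = 20)
  expect_true(all(sv0$gamma == 0, na.rm = TRUE))

  # white noise with variance sigma^2: gamma(h) ~ sigma^2 at all lags,
  # within 3 s.e. of the mean of squared differences
  sigma <- 2
  v <- rnorm(n, 0, sigma)
  sv <- empirical_semivariogram(x, y, v, max_lag = 20, n_bins = 8)
  for (k in seq_along(sv$gamma)) {
    if (is.na(sv$gamma[k]) || sv$n_pairs[k] < 30) next
    se <- sqrt(2) * sigma^2 / sqrt(sv$n_pairs[k])  # var of 0.5*chi2_1 pairs
    expect_lt(abs(sv$gamma[k] - sigma^2), 3 * se + 0.5)
  }

  # spatially smoothed field: gamma rises over the first bins
  g <- bc_grid(40, 40, 1, origin = c(0, 40))
  set.seed(4)
  f <- gaussian_smooth(matrix(rnorm(1600), 40, 40), 3)
  cc <- cell_centres(g)
  pts <- expand.grid(i = seq(1, 40, by = 2), j = seq(1, 40, by = 2))
  svs <- empirical_semivariogram(cc$x[pts$j], cc$y[pts$i],
                                 f[cbind(pts$i, pts$j)], max_lag = 16,
                                 n_bins = 8)
  expect_true(all(diff(svs$gamma[1:4]) > 0))
  expect_error(empirical_semivariogram(1:5, 1:5, rnorm(5), 10), "30 points")
})

test_that("minimum-distance sampling respects the constraint and the seed", {
  g <- bc_grid(40, 40, 1, origin = c(0, 40))
  mask <- bc_raster(g, matrix(1, 40, 40))
  cfg <- ordination_config(n_points = 60, min_distance = 3, seed = 9)
  pts <- sample_min_distance(mask, cfg)
  expect_equal(nrow(pts), 60)
  expect_gte(min(dist(pts)), 3)
  pts2 <- sample_min_distance(mask, cfg)
  expect_identical(pts, pts2)
  # demanding more than the packing density allows reports the achieved count
  too_many <- ordination_config(n_points = 400, min_distance = 3, seed = 9)
  expect_error(sample_min_distance(mask, too_many, max_proposals = 20000),
               "could only place")
})

test_that("cover extraction returns exact fractions on constructed maps", {
  g <- bc_grid(20, 20, 1, origin = c(0, 20))
  code <- function(x) match(x, cover_classes())
  moss <- bc_classraster(g, matrix(code("Moss"), 20, 20))
  pts <- data.frame(x = c(10, 5), y = c(10, 15))
  ec <- extract_cover(moss, pts, radius = 3)
  expect_equal(ec$cover[, "Moss"], c(1, 1))
  expect_equal(rowSums(ec$cover), c(1, 1), tolerance = 1e-12)
  expect_equal(ec$veg_fraction, c(0, 0))

  # half Soil / half Moss split through the point: 0.5 each within one cell
  lab <- matrix(code("Soil"), 20, 20)
  lab[, 11:20] <- code("Moss")
  half <- bc_classraster(g, lab)
  eh <- extract_cover(half, data.frame(x = 10, y = 10), radius = 3)
  expect_equal(unname(eh$cover[1, "Soil"] + eh$cover[1, "Moss"]), 1,
               tolerance = 1e-12)
  expect_lt(abs(eh$cover[1, "Soil"] - 0.5), 0.11)  # one-cell discretization
  expect_error(extract_cover(moss, data.frame(x = 500, y = 500), 3),
               "no valid cells")
})

test_that("RDA: span, orthogonal and brute-force-oracle cases", {
  set.seed(11)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("p1", "p2")))
  B <- matrix(rnorm(2 * 3), 2, 3)
  Y_span <- X %*% B
  f1 <- rda_fit(Y_span, X)
  expect_equal(f1$proportion_explained, 1, tolerance = 1e-10)

  # Y orthogonal to X by construction: regress out X first
  Y0 <- matrix(rnorm(n * 3), n, 3)
  Yc <- scale(Y0, scale = FALSE)
  Xs <- scale(X)
  Y_orth <- qr.resid(qr(Xs), Yc)
  f0 <- rda_fit(Y_orth, X)
  expect_equal(f0$proportion_explained, 0, tolerance = 1e-10)

  # brute-force oracle: explicit projection then full PCA of fitted values
  Y <- matrix(rnorm(n * 3), n, 3)
  f <- rda_fit(Y, X)
  Ycc <- scale(Y, scale = FALSE)
  H <- Xs %*% solve(t(Xs) %*% Xs) %*% t(Xs)
  Yhat <- H %*% Ycc
  ev <- eigen(t(Yhat) %*% Yhat / (n - 1), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(f$eig_constrained, ev, tolerance = 1e-8)

  # eigenvalue bookkeeping: constrained + unconstrained = total inertia
  expect_equal(sum(f$eig_constrained) + sum(f$eig_unconstrained),
               f$total_inertia, tolerance = 1e-9)
  # proportion explained invariant to affine rescaling of X columns
  X2 <- X %*% diag(c(100, 0.01)); X2[, 1] <- X2[, 1] + 5
  colnames(X2) <- colnames(X)
  expect_equal(rda_fit(Y, X2)$proportion_explained, f$proportion_explained,
               tolerance = 1e-10)
  expect_error(rda_fit(Y[1:3, ], X[1:3, ]), "too few")
  expect_error(rda_fit(Y, cbind(X, p3 = X[, 1])), "rank")
})

test_that("RDA agrees with vegan on eigenvalues and adjusted r-squared", {
  skip_if_not_installed("vegan")
  set.seed(21)
  n <- 40
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  Y <- matrix(rnorm(n * 4), n, 4)
  Y[, 1] <- Y[, 1] + 2 * X$a
  f <- rda_fit(Y, X)
  v <- vegan::rda(Y ~ a + b + c, data = X, scale = FALSE)
  expect_equal(unname(f$eig_constrained),
               unname(v$CCA$eig[v$CCA$eig > 1e-10]), tolerance = 1e-8)
  expect_equal(f$proportion_explained,
               unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-10)
  expect_equal(f$adj_r_squared,
               vegan::RsquareAdj(v)$adj.r.squared, tolerance = 1e-10)
})

test_that("marginal permutation F matches the closed-form partial ratio", {
  set.seed(31)
  n <- 30
  X <- data.frame(u = rnorm(n), w = rnorm(n))
  Y <- matrix(rnorm(n * 3), n, 3)
  Y[, 2] <- Y[, 2] + X$u
  cfg <- ordination_config(n_permutations = 49, seed = 1)
  res <- permutation_anova_marginal(Y, X, cfg)
  # independent oracle: per-term F from separate lm-based inertias
  Yc <- scale(Y, scale = FALSE)
  Xs <- scale(as.matrix(X))
  inert <- function(cols) {
    if (!length(cols)) return(0)
    sum(lm.fit(Xs[, cols, drop = FALSE], Yc)$fitted.values^2) / (n - 1)
  }
  tot <- sum(Yc^2) / (n - 1)
  full <- inert(c("u", "w"))
  for (t0 in c("u", "w")) {
    F_hand <- (full - inert(setdiff(c("u", "w"), t0))) /
      ((tot - full) / (n - 1 - 2))
    expect_equal(res$F[res$term == t0], F_hand, tolerance = 1e-10)
  }
  # p floor at 1/(N+1)
  expect_gte(min(res$p), 1 / 50)
})

test_that("marginal permutation p agrees with vegan's anova.cca by rank", {
  skip_if_not_installed("vegan")
  set.seed(41)
  n <- 50
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * 3), n, 3)
  Y[, 1] <- Y[, 1] + 1.5 * X$a
  res <- permutation_anova_marginal(Y, X, ordination_config(
    n_permutations = 199, seed = 3))
  v <- vegan::rda(Y ~ a + b, data = X)
  av <- vegan::anova.cca(v, by = "margin", permutations = 199)
  expect_equal(res$F, av$F[1:2], tolerance = 1e-8)
  expect_lt(res$p[res$term == "a"], 0.05)
  expect_gt(res$p[res$term == "b"], 0.05)
})

test_that("VIF screening flags collinearity and selects by adjusted r^2", {
  set.seed(51)
  n <- 40
  a <- rnorm(n); b <- rnorm(n)
  X <- data.frame(a = a, b = b)
  # orthogonalize numerically to make VIFs exactly ~1
  X$b <- qr.resid(qr(cbind(1, X$a)), X$b)
  Y <- matrix(rnorm(n * 3), n, 3); Y[, 1] <- Y[, 1] + X$a
  cfg <- ordination_config()
  out <- vif_select(X, Y, cfg)
  expect_equal(unname(out$vif), c(1, 1), tolerance = 1e-10)
  expect_true("a" %in% out$selected)

  # duplicated column: infinite VIF, never jointly selected
  X2 <- data.frame(a = a, b = b, a2 = a)
  out2 <- vif_select(X2, Y, cfg)
  expect_true(is.infinite(out2$vif[["a"]]) && is.infinite(out2$vif[["a2"]]))
  expect_false(all(c("a", "a2") %in% out2$selected))

  # near-duplicates: VIF = 1/(1 - r^2) ~ 5000 >> 10
  X3 <- data.frame(a = a, b = a + rnorm(n, 0, sd(a) / 70))
  r2 <- summary(lm(X3$b ~ X3$a))$r.squared
  out3 <- vif_select(X3, Y, cfg)
  expect_equal(unname(out3$vif[1]), 1 / (1 - r2), tolerance = 1e-6)
  expect_equal(length(out3$selected), 1L)  # the pair is never joint
})

test_that("VIF values match vegan::vif.cca", {
  skip_if_not_installed("vegan")
  set.seed(61)
  n <- 35
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X$c <- X$a * 0.8 + X$c * 0.3
  Y <- matrix(rnorm(n * 3), n, 3)
  out <- vif_select(X, Y, ordination_config())
  v <- vegan::rda(Y ~ a + b + c, data = X)
  expect_equal(unname(out$vif), unname(vegan::vif.cca(v)[c("a", "b", "c")]),
               tolerance = 1e-8)
})
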