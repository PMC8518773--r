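# Landscape-level ordination: semivariogram-guided minimum-distance point
# sampling, circular-buffer cover and attribute extraction, redundancy
# analysis (RDA), marginal permutation tests and VIF-screened model search.

#' Ordination configuration
#'
#' @param n_points Random sample size over the study area (default 1147).
#' @param min_distance Minimum distance between sampled points, m (default 3,
#'   chosen against the semivariogram range to avoid spatial autocorrelation).
#' @param buffer_radius Radius of the extraction circle around each point, m.
#' @param n_permutations Permutations for the marginal tests (default 999).
#' @param vif_threshold Predictors with a variance inflation factor above this
#'   are excluded (default 10).
#' @param seed Integer seed.
#' @export
ordination_config <- function(n_points = 1147, min_distance = 3,
                              buffer_radius = 3, n_permutations = 999,
                              vif_threshold = 10, seed = 1) {
  stopifnot(min_distance > 0, n_permutations >= 1, n_points >= 1)
  list(n_points = n_points, min_distance = min_distance,
       buffer_radius = buffer_radius, n_permutations = n_permutations,
       vif_threshold = vif_threshold, seed = seed)
}

#' Empirical semivariogram
#'
#' `gamma(h)` = half the mean squared difference between pairs of samples in
#' each lag bin; the range is estimated as the smallest lag centre where
#' `gamma` reaches 95% of the sill (mean of the last three bins).
#'
#' @param x,y Point coordinates (m).
#' @param values Values at the points.
#' @param max_lag Largest lag considered (m).
#' @param n_bins Number of equal-width lag bins.
#' @return List: `lag` (bin centres), `gamma`, `n_pairs`, `range`, `sill`.
#' @export
empirical_semivariogram <- function(x, y, values, max_lag, n_bins = 15) {
  keep <- !is.na(values)
  x <- x[keep]; y <- y[keep]; v <- values[keep]
  if (length(v) < 30) stop("need at least 30 points")
  d <- as.vector(stats::dist(cbind(x, y)))
  dv2 <- as.vector(stats::dist(v))^2
  sel <- d <= max_lag & d > 0
  d <- d[sel]; dv2 <- dv2[sel]
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE)
  n_pairs <- as.vector(table(bin))
  if (all(n_pairs < 2)) stop("fewer than 2 point pairs in every lag bin")
  gam <- as.vector(tapply(dv2, bin, function(z) mean(z) / 2))
  lag <- (breaks[-1] + breaks[-length(breaks)]) / 2
  sill <- mean(utils::tail(gam[!is.na(gam)], 3))
  rng <- NA_real_
  ok <- which(!is.na(gam) & gam >= 0.95 * sill)
  if (length(ok)) rng <- lag[ok[1]]
  list(lag = lag, gamma = gam, n_pairs = n_pairs, range = rng, sill = sill)
}

#' Random point sample with a minimum-distance constraint
#'
#' Seeded rejection sampling of cell-centre-uniform points over the valid
#' cells of a mask raster until `n_points` are accepted with all pairwise
#' distances >= `min_distance`. Candidate checks use a spatial hash so large
#' samples stay fast.
#'
#' @param valid_mask A `bc_raster`; cells with nodata are excluded.
#' @param config An [ordination_config()].
#' @param max_proposals Proposal budget before giving up (default
#'   `200 * n_points`).
#' @return Data frame `x`, `y` of accepted points (one per row).
#' @export
sample_min_distance <- function(valid_mask, config = ordination_config(),
                                max_proposals = 200 * config$n_points) {
  g <- valid_mask$grid
  cc <- cell_centres(g)
  ok <- which(!is.na(valid_mask$values))
  if (length(ok) == 0) stop("no valid cells to sample")
  set.seed(config$seed)
  d <- config$min_distance
  # spatial hash with bucket size d: neighbours are within one bucket ring
  hx <- function(x) floor(x / d); hy <- function(y) floor(y / d)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  xs <- numeric(config$n_points); ys <- numeric(config$n_points)
  n_acc <- 0L; n_prop <- 0L
  h <- g$cell_size
  while (n_acc < config$n_points && n_prop < max_proposals) {
    n_prop <- n_prop + 1L
    cell <- ok[sample.int(length(ok), 1)]
    i <- (cell - 1L) %% g$nrows + 1L
    j <- (cell - 1L) %/% g$nrows + 1L
    px <- cc$x[j] + stats::runif(1, -h / 2, h / 2)
    py <- cc$y[i] + stats::runif(1, -h / 2, h / 2)
    clash <- FALSE
    for (bx in (hx(px) - 1):(hx(px) + 1)) {
      for (by in (hy(py) - 1):(hy(py) + 1)) {
        key <- paste(bx, by)
        pts <- buckets[[key]]
        if (!is.null(pts) &&
            any((pts$x - px)^2 + (pts$y - py)^2 < d^2)) { clash <- TRUE; break }
      }
      if (clash) break
    }
    if (clash) next
    n_acc <- n_acc + 1L
    xs[n_acc] <- px; ys[n_acc] <- py
    key <- paste(hx(px), hy(py))
    pts <- buckets[[key]]
    buckets[[key]] <- if (is.null(pts)) list(x = px, y = py) else
      list(x = c(pts$x, px), y = c(pts$y, py))
  }
  if (n_acc < config$n_points)
    stop("could only place ", n_acc, " of ", config$n_points,
         " points at min distance ", d, " m within the proposal budget")
  data.frame(x = xs, y = ys)
}

circle_cells <- function(grid, px, py, radius) {
  cc <- cell_centres(grid)
  jin <- which(abs(cc$x - px) <= radius)
  iin <- which(abs(cc$y - py) <= radius)
  if (!length(jin) || !length(iin)) return(integer(0))
  dx2 <- outer(rep(1, length(iin)), (cc$x[jin] - px)^2)
  dy2 <- outer((cc$y[iin] - py)^2, rep(1, length(jin)))
  idx <- outer(iin, (jin - 1) * grid$nrows, `+`)
  idx[dx2 + dy2 <= radius^2]
}

#' Fractional cover around sample points
#'
#' For each point, the fraction of each of the seven covers among the valid
#' cells whose centres fall in the circle of `radius` around it, plus the
#' combined vegetation (GreenVeg + DryVeg) and bare-soil fractions used as
#' RDA predictors.
#'
#' @param classes A `bc_classraster`.
#' @param points Data frame `x`, `y`.
#' @param radius Circle radius, m.
#' @return List: `cover` (n x 7 matrix, columns [cover_classes()]),
#'   `veg_fraction`, `soil_fraction`.
#' @export
extract_cover <- function(classes, points, radius) {
  n <- nrow(points)
  cov <- matrix(0, n, length(cover_classes()),
                dimnames = list(NULL, cover_classes()))
  for (p in seq_len(n)) {
    idx <- circle_cells(classes$grid, points$x[p], points$y[p], radius)
    lab <- classes$labels[idx]
    lab <- lab[!is.na(lab)]
    if (!length(lab)) stop("sample circle ", p, " has no valid cells")
    cov[p, ] <- tabulate(lab, nbins = length(cover_classes())) / length(lab)
  }
  list(cover = cov,
       veg_fraction = cov[, "GreenVeg"] + cov[, "DryVeg"],
       soil_fraction = cov[, "Soil"])
}

#' Circle means of a raster at sample points
#'
#' @param raster A `bc_raster`.
#' @param points Data frame `x`, `y`.
#' @param radius Circle radius, m.
#' @return Numeric vector of per-point means of valid cells (`NA` when the
#'   circle holds none).
#' @export
extract_attr <- function(raster, points, radius) {
  vapply(seq_len(nrow(points)), function(p) {
    idx <- circle_cells(raster$grid, points$x[p], points$y[p], radius)
    v <- raster$values[idx]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' Redundancy analysis
#'
#' `Y` is centred, `X` standardized; the fitted values `X (X'X)^-1 X' Y`
#' are decomposed by PCA. Total inertia is the trace of `cov(Y)`; the
#' proportion explained is the constrained eigenvalue sum over it, and the
#' adjusted r-squared applies the Ezekiel correction
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' @param Y Response matrix (sites x covers).
#' @param X Predictor matrix or data frame (sites x predictors).
#' @return List of class `bc_rda`: `eig_constrained`, `eig_unconstrained`,
#'   `total_inertia`, `proportion_explained`, `adj_r_squared`, `site_scores`,
#'   `response_scores`, `biplot_scores`.
#' @export
rda_fit <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  p <- ncol(X)
  if (n <= p + 1) stop("too few rows: need n > number of predictors + 1")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X)
  if (any(!is.finite(Xs))) stop("constant predictor column")
  qr_x <- qr(Xs)
  if (qr_x$rank < p) stop("rank-deficient predictor matrix")
  Yhat <- qr.fitted(qr_x, Yc)
  total <- sum(Yc^2) / (n - 1)
  sv <- svd(Yhat)
  eig_c <- sv$d^2 / (n - 1)
  eig_c <- eig_c[eig_c > max(eig_c[1], 1) * 1e-12]
  resid <- Yc - Yhat
  sv_r <- svd(resid)
  eig_u <- sv_r$d^2 / (n - 1)
  eig_u <- eig_u[eig_u > max(sv_r$d[1]^2 / (n - 1), 1) * 1e-12]
  r2 <- sum(eig_c) / total
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  k <- length(eig_c)
  site <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k)                     # LC site scores
  resp <- sv$v[, seq_len(k), drop = FALSE]
  if (k > 0) {
    biplot <- stats::cor(Xs, site)
    colnames(site) <- colnames(resp) <- colnames(biplot) <-
      paste0("RDA", seq_len(k))
    rownames(resp) <- colnames(Y)
    rownames(biplot) <- colnames(X)
  } else biplot <- matrix(0, ncol(X), 0, dimnames = list(colnames(X), NULL))
  structure(list(eig_constrained = eig_c, eig_unconstrained = eig_u,
                 total_inertia = total, proportion_explained = r2,
                 adj_r_squared = adj, site_scores = site,
                 response_scores = resp, biplot_scores = biplot,
                 n = n, p = p),
            class = "bc_rda")
}

#' @export
print.bc_rda <- function(x, ...) {
  cat("RDA: ", x$n, " sites, ", x$p, " predictors\n",
      "total inertia ", signif(x$total_inertia, 5),
      ", proportion explained ", round(100 * x$proportion_explained, 1),
      "% (adj r^2 ", round(x$adj_r_squared, 3), ")\n", sep = "")
  invisible(x)
}

rda_inertia <- function(Y, X) {
  # constrained inertia of Y on standardized X (helper for the tests below)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(as.matrix(X))
  sum(qr.fitted(qr(Xs), Yc)^2) / (n - 1)
}

#' Marginal permutation tests for RDA terms
#'
#' For each predictor `t`, the marginal (type III) pseudo-F compares the
#' inertia lost when `t` is dropped to the residual inertia of the full
#' model. The null distribution permutes the rows of the reduced-model
#' residuals (residuals-of-reduced-model scheme), and
#' `p = (count(F* >= F) + 1) / (N + 1)`.
#'
#' @param Y Response matrix.
#' @param X Predictor matrix or data frame.
#' @param config An [ordination_config()] (permutation count and seed).
#' @return Data frame `term`, `df`, `F`, `p`.
#' @export
permutation_anova_marginal <- function(Y, X, config = ordination_config()) {
  Y <- as.matrix(Y); X <- as.data.frame(X)
  n <- nrow(Y); p <- ncol(X)
  terms <- names(X)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(as.matrix(X))
  total <- sum(Yc^2) / (n - 1)
  qr_full <- qr(Xs)
  in_full <- sum(qr.fitted(qr_full, Yc)^2) / (n - 1)
  resid_in <- total - in_full
  df_res <- n - 1 - p
  set.seed(config$seed)
  N <- config$n_permutations
  out <- lapply(terms, function(t0) {
    Xred <- Xs[, setdiff(terms, t0), drop = FALSE]
    if (ncol(Xred)) {
      qr_red <- qr(Xred)
      fit_red <- qr.fitted(qr_red, Yc)
      in_red <- sum(fit_red^2) / (n - 1)
    } else {
      fit_red <- matrix(0, n, ncol(Yc))
      in_red <- 0
    }
    res_red <- Yc - fit_red
    F_obs <- (in_full - in_red) / (resid_in / df_res)
    F_star <- vapply(seq_len(N), function(k) {
      Yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
      Ypc <- scale(Yp, center = TRUE, scale = FALSE)
      tot_p <- sum(Ypc^2) / (n - 1)
      in_full_p <- sum(qr.fitted(qr_full, Ypc)^2) / (n - 1)
      in_red_p <- if (ncol(Xred)) sum(qr.fitted(qr_red, Ypc)^2) / (n - 1) else 0
      (in_full_p - in_red_p) / ((tot_p - in_full_p) / df_res)
    }, numeric(1))
    data.frame(term = t0, df = 1, F = F_obs,
               p = (sum(F_star >= F_obs) + 1) / (N + 1))
  })
  do.call(rbind, out)
}

#' VIF screening and adjusted-r-squared model selection
#'
#' Variance inflation factors `1 / (1 - R^2_j)` from regressing each
#' predictor on the others; perfectly collinear predictors get `VIF = Inf`.
#' All predictor subsets are enumerated (up to `2^p - 1` models), subsets
#' whose own VIFs exceed the threshold are discarded, and the subset with the
#' highest adjusted r-squared of the RDA on `Y` wins.
#'
#' @param X Predictor matrix or data frame (>= 2 columns).
#' @param Y Response matrix for the RDA.
#' @param config An [ordination_config()] (VIF threshold).
#' @return List: `vif` (named, full X), `selected` (winning predictor names),
#'   `best_adj_r2`, `models` (data frame of evaluated subsets).
#' @export
vif_select <- function(X, Y, config = ordination_config()) {
  X <- as.data.frame(X)
  p <- ncol(X)
  stopifnot(p >= 2)
  vif_of <- function(Xd) {
    Xm <- scale(as.matrix(Xd))
    vapply(seq_len(ncol(Xm)), function(j) {
      others <- Xm[, -j, drop = FALSE]
      if (!ncol(others)) return(1)
      # perfect fits are expected for duplicated columns; they map to Inf
      r2 <- suppressWarnings(summary(stats::lm(Xm[, j] ~ others))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  vif_full <- stats::setNames(vif_of(X), names(X))
  subsets <- unlist(lapply(seq_len(p), function(k)
    utils::combn(names(X), k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(s) {
    Xd <- X[, s, drop = FALSE]
    v <- vif_of(Xd)
    if (any(!is.finite(v)) || any(v > config$vif_threshold))
      return(data.frame(model = paste(s, collapse = "+"), k = length(s),
                        adj_r2 = NA_real_, admissible = FALSE))
    fit <- tryCatch(rda_fit(Y, Xd), error = function(e) NULL)
    data.frame(model = paste(s, collapse = "+"), k = length(s),
               adj_r2 = if (is.null(fit)) NA_real_ else fit$adj_r_squared,
               admissible = !is.null(fit))
  })
  models <- do.call(rbind, rows)
  adm <- models[models$admissible & !is.na(models$adj_r2), ]
  if (!nrow(adm)) stop("no admissible model under the VIF threshold")
  best <- adm$model[which.max(adm$adj_r2)]
  list(vif = vif_full,
       selected = strsplit(best, "+", fixed = TRUE)[[1]],
       best_adj_r2 = max(adm$adj_r2),
       models = models)
}
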