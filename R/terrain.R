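# Terrain attributes from a vegetation-free DTM. Conventions: row 1 is the
# northernmost row, slope in degrees, aspect in degrees clockwise from north
# pointing downslope, all distances in metres.

pad_extrapolate <- function(z) {
  # linear extrapolation padding: exact for planes, so edge derivatives are
  # not biased on smooth terrain
  nr <- nrow(z); nc <- ncol(z)
  top <- 2 * z[1, ] - z[2, ]; bot <- 2 * z[nr, ] - z[nr - 1, ]
  zp <- rbind(top, z, bot)
  left <- 2 * zp[, 1] - zp[, 2]; right <- 2 * zp[, nc] - zp[, nc - 1]
  zp <- cbind(left, zp, right)
  dimnames(zp) <- NULL
  zp
}

shift_mat <- function(m, di, dj, fill = NA) {
  # value of the neighbour at (row+di, col+dj), out-of-grid -> fill
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) + di; ci <- seq_len(nc) + dj
  rok <- ri >= 1 & ri <= nr; cok <- ci >= 1 & ci <= nc
  out[rok, cok] <- m[ri[rok], ci[cok]]
  out
}

#' Remove pits from a DTM (priority-flood depression filling)
#'
#' Raises every cell minimally so that a non-ascending path to the raster
#' boundary (or to a nodata cell) exists. With `eps > 0` a small gradient is
#' imposed across filled flats so that the D-infinity router always finds a
#' strictly downslope direction.
#'
#' @param dtm A `bc_raster` of elevations (m).
#' @param eps Extra rise per cell applied across filled areas (m). The
#'   default 0 raises pits exactly to their spill elevation; use a small
#'   positive value (e.g. 1e-6) before flow routing.
#' @return A `bc_raster` with `values >= dtm$values` everywhere.
#' @export
fill_pits <- function(dtm, eps = 0) {
  z <- dtm$values
  if (all(is.na(z))) stop("all-nodata DTM")
  nr <- nrow(z); nc <- ncol(z)
  w <- matrix(Inf, nr, nc)
  # outlets: boundary cells drain off-grid; nodata drains everything beside it
  w[1, ] <- z[1, ]; w[nr, ] <- z[nr, ]; w[, 1] <- z[, 1]; w[, nc] <- z[, nc]
  w[is.na(z)] <- -Inf
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  repeat {
    nb_min <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(offs))) {
      s <- shift_mat(w, offs$di[k], offs$dj[k], fill = -Inf)
      nb_min <- pmin(nb_min, s)
    }
    w_new <- pmax(z, nb_min + eps)
    w_new[1, ] <- z[1, ]; w_new[nr, ] <- z[nr, ]
    w_new[, 1] <- z[, 1]; w_new[, nc] <- z[, nc]
    w_new[is.na(z)] <- -Inf
    live <- !is.na(z)
    delta <- abs(w_new[live] - w[live])
    converged <- all(is.finite(w_new[live])) &&
      max(delta[is.finite(delta)], 0) < 1e-12
    w <- w_new
    if (converged) break
  }
  w[is.na(z)] <- NA
  bc_raster(dtm$grid, w)
}

#' Slope and aspect by the Zevenbergen-Thorne second-order polynomial
#'
#' Central finite differences of the 3x3 neighbourhood give the partial
#' derivatives of the fitted second-order surface; edges use linear
#' extrapolation padding (exact on planes).
#'
#' @param dtm A `bc_raster` of elevations (m), at least 3x3.
#' @return List with `slope` (degrees) and `aspect` (degrees clockwise from
#'   north, downslope direction; `NA` on flat cells).
#' @export
slope_aspect <- function(dtm) {
  z <- dtm$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("raster smaller than 3x3")
  h <- dtm$grid$cell_size
  zp <- pad_extrapolate(z)
  nr <- nrow(z); nc <- ncol(z)
  ir <- 2:(nr + 1); ic <- 2:(nc + 1)
  # p = dz/dx (east positive), q = dz/dy (north positive; row 1 is north)
  p <- (zp[ir, ic + 1] - zp[ir, ic - 1]) / (2 * h)
  q <- (zp[ir - 1, ic] - zp[ir + 1, ic]) / (2 * h)
  slope <- atan(sqrt(p^2 + q^2)) * 180 / pi
  aspect <- (atan2(-p, -q) * 180 / pi) %% 360
  flat <- (p == 0 & q == 0)
  aspect[flat] <- NA
  bad <- is.na(p) | is.na(q)
  slope[bad] <- NA; aspect[bad] <- NA
  list(slope = bc_raster(dtm$grid, slope),
       aspect = bc_raster(dtm$grid, aspect))
}

#' Northernness of an aspect raster
#'
#' `cos(aspect) + 1`, ranging 2 (due north) to 0 (due south). Flat cells
#' (aspect nodata) propagate nodata.
#'
#' @param aspect A `bc_raster` of aspect in degrees from north.
#' @return A `bc_raster` in `[0, 2]`.
#' @export
northernness <- function(aspect) {
  bc_raster(aspect$grid, cos(aspect$values * pi / 180) + 1)
}

#' Topographic wetness index
#'
#' `TWI = ln(A / tan beta)`, with `tan beta` clamped from below so flat cells
#' stay finite.
#'
#' @param cca A `bc_raster` of specific catchment area (m), from [dinf_area()].
#' @param slope A `bc_raster` of slope in degrees.
#' @param tan_min Lower clamp on `tan beta` (default 1e-3, i.e. 0.057 deg).
#' @return A `bc_raster`.
#' @export
twi <- function(cca, slope, tan_min = 1e-3) {
  assert_aligned(cca, slope)
  a <- cca$values
  if (any(a <= 0, na.rm = TRUE)) stop("catchment area must be positive")
  tb <- pmax(tan(slope$values * pi / 180), tan_min)
  bc_raster(cca$grid, log(a / tb))
}

#' Length-slope factor parameters
#' @param n,m Exponents (defaults 0.4, 1.3).
#' @param area_ref,slope_ref Reference catchment area (22.13) and reference
#'   sine of slope (0.0896).
#' @export
lsf_params <- function(n = 0.4, m = 1.3, area_ref = 22.13, slope_ref = 0.0896) {
  stopifnot(n > 0, m > 0)
  list(n = n, m = m, area_ref = area_ref, slope_ref = slope_ref)
}

#' Length-slope factor (erosion-potential index)
#'
#' `LSF = (n + 1) (A / 22.13)^n (sin beta / 0.0896)^m`.
#'
#' @param cca A `bc_raster` of specific catchment area (m).
#' @param slope A `bc_raster` of slope in degrees.
#' @param params A [lsf_params()] list.
#' @return A `bc_raster`.
#' @export
lsf <- function(cca, slope, params = lsf_params()) {
  assert_aligned(cca, slope)
  a <- cca$values
  if (any(a < 0, na.rm = TRUE)) stop("negative catchment area")
  v <- (params$n + 1) * (a / params$area_ref)^params$n *
    (sin(slope$values * pi / 180) / params$slope_ref)^params$m
  bc_raster(cca$grid, v)
}

#' Circular focal mean
#'
#' Mean over all cells whose centres lie within `diameter / 2` of the target
#' cell centre, ignoring nodata. With `diameter < cell_size` only the cell
#' itself qualifies (identity).
#'
#' @param raster A `bc_raster`.
#' @param diameter Window diameter in metres.
#' @return A `bc_raster`.
#' @export
focal_mean_circular <- function(raster, diameter) {
  stopifnot(diameter >= 0)
  h <- raster$grid$cell_size
  r_cells <- floor((diameter / 2) / h)
  v <- raster$values
  if (r_cells < 1) return(bc_raster(raster$grid, v))
  acc <- matrix(0, nrow(v), ncol(v)); n <- matrix(0, nrow(v), ncol(v))
  for (di in -r_cells:r_cells) for (dj in -r_cells:r_cells) {
    if (sqrt(di^2 + dj^2) * h > diameter / 2 + 1e-12) next
    s <- shift_mat(v, di, dj)
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    n <- n + ok
  }
  out <- acc / n
  out[n == 0] <- NA
  out[is.na(v)] <- NA
  bc_raster(raster$grid, out)
}
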