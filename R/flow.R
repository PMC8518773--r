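# D-infinity flow routing: the flow direction of each cell is the steepest
# downward slope over the eight triangular facets of its 3x3 window, and flow
# is split between the two grid directions bounding that angle in proportion
# to angular distance. Angles follow the D-infinity convention: radians,
# counter-clockwise from east.

# facet table: ac, af give the global angle af*r + ac*pi/2; e1 is the
# cardinal-edge neighbour, e2 the diagonal neighbour of the facet.
# neighbour offsets (di, dj): row 1 is north, so north = di -1.
dinf_facets <- function() {
  nb <- list(E = c(0, 1), NE = c(-1, 1), N = c(-1, 0), NW = c(-1, -1),
             W = c(0, -1), SW = c(1, -1), S = c(1, 0), SE = c(1, 1))
  list(nb = nb,
       tab = data.frame(
         ac = c(0, 1, 1, 2, 2, 3, 3, 4),
         af = c(1, -1, 1, -1, 1, -1, 1, -1),
         e1 = c("E", "N", "N", "W", "W", "S", "S", "E"),
         e2 = c("NE", "NE", "NW", "NW", "SW", "SW", "SE", "SE"),
         stringsAsFactors = FALSE))
}

#' D-infinity flow field of a pit-free DTM
#'
#' Facets touching an off-grid or nodata neighbour are not evaluated; a cell
#' with no downslope facet is an outlet if it borders the grid edge or a
#' nodata cell (its accumulation exits the grid) and a routing error (a pit)
#' otherwise.
#'
#' @param dtm_filled A `bc_raster` that has been through [fill_pits()] with a
#'   positive `eps` (every interior cell must have a strictly downslope
#'   direction).
#' @return A `bc_flowfield`: per cell the flow angle and the two receiving
#'   neighbours with their proportions (linear indices into the value matrix).
#'   Outlet cells have zero proportions and `NA` angle.
#' @export
dinf_flow <- function(dtm_filled) {
  z <- dtm_filled$values
  h <- dtm_filled$grid$cell_size
  nr <- nrow(z); nc <- ncol(z)
  f <- dinf_facets()
  nbz <- lapply(f$nb, function(o) shift_mat(z, o[1], o[2]))
  has_missing_nb <- Reduce(`|`, lapply(nbz, is.na))
  best_s <- matrix(-Inf, nr, nc)
  best_r <- matrix(NA_real_, nr, nc)
  best_k <- matrix(NA_integer_, nr, nc)
  for (k in 1:8) {
    e1 <- nbz[[f$tab$e1[k]]]
    e2 <- nbz[[f$tab$e2[k]]]
    s1 <- (z - e1) / h
    s2 <- (e1 - e2) / h
    r <- atan2(s2, s1)
    s <- sqrt(s1^2 + s2^2)
    lo <- !is.na(r) & r < 0
    r[lo] <- 0; s[lo] <- s1[lo]
    hi <- !is.na(r) & r > pi / 4
    r[hi] <- pi / 4
    s[hi] <- ((z - e2) / (sqrt(2) * h))[hi]
    upd <- !is.na(s) & s > best_s
    best_s[upd] <- s[upd]; best_r[upd] <- r[upd]; best_k[upd] <- k
  }
  live <- !is.na(z)
  drains <- best_s > 0
  sink <- live & !drains & !has_missing_nb
  if (any(sink)) {
    idx <- which(sink)[1]
    stop("pits present: interior cell (", row(z)[idx], ",", col(z)[idx],
         ") has no downslope neighbour; run fill_pits(eps > 0) first")
  }
  angle <- matrix(NA_real_, nr, nc)
  rec1 <- matrix(NA_integer_, nr, nc); rec2 <- matrix(NA_integer_, nr, nc)
  p1 <- matrix(0, nr, nc); p2 <- matrix(0, nr, nc)
  lin <- matrix(seq_len(nr * nc), nr, nc)
  row_i <- row(z); col_j <- col(z)
  for (k in 1:8) {
    sel <- live & drains & !is.na(best_k) & best_k == k
    if (!any(sel)) next
    angle[sel] <- (f$tab$af[k] * best_r[sel] + f$tab$ac[k] * pi / 2) %% (2 * pi)
    o1 <- f$nb[[f$tab$e1[k]]]; o2 <- f$nb[[f$tab$e2[k]]]
    pr2 <- best_r[sel] / (pi / 4)
    p1[sel] <- 1 - pr2; p2[sel] <- pr2
    rec1[sel] <- lin[cbind(row_i[sel] + o1[1], col_j[sel] + o1[2])]
    rec2[sel] <- lin[cbind(row_i[sel] + o2[1], col_j[sel] + o2[2])]
  }
  structure(list(grid = dtm_filled$grid, elev = z, angle = angle,
                 rec1 = rec1, rec2 = rec2, p1 = p1, p2 = p2),
            class = "bc_flowfield")
}

#' D-infinity contributing area
#'
#' Accumulates each cell's own area plus proportional upslope contributions,
#' processed in decreasing-elevation order (a topological order because
#' D-infinity receivers are strictly lower than their donors). Reported as
#' specific catchment area, accumulated area / cell width (m). The total area
#' leaving the grid through outlet cells is attached as attribute `outflow`
#' (m^2).
#'
#' @param flow A `bc_flowfield` from [dinf_flow()].
#' @param grid Optional grid (defaults to the flow field's).
#' @return A `bc_raster` of specific catchment area with attribute `outflow`.
#' @export
dinf_area <- function(flow, grid = flow$grid) {
  z <- flow$elev
  nr <- nrow(z); nc <- ncol(z)
  h <- grid$cell_size
  acc <- matrix(h^2, nr, nc)
  acc[is.na(z)] <- NA
  ord <- order(z, decreasing = TRUE, na.last = NA)
  outflow <- 0
  rec1 <- flow$rec1; rec2 <- flow$rec2; p1 <- flow$p1; p2 <- flow$p2
  for (c0 in ord) {
    a <- acc[c0]
    q1 <- p1[c0]; q2 <- p2[c0]
    if (q1 == 0 && q2 == 0) { outflow <- outflow + a; next }
    if (q1 > 0) {
      r <- rec1[c0]
      if (z[r] >= z[c0]) stop("cycle detected: receiver not lower than donor")
      acc[r] <- acc[r] + a * q1
    }
    if (q2 > 0) {
      r <- rec2[c0]
      if (z[r] >= z[c0]) stop("cycle detected: receiver not lower than donor")
      acc[r] <- acc[r] + a * q2
    }
  }
  out <- bc_raster(grid, acc / h)
  attr(out, "outflow") <- outflow
  out
}
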