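#' Surface-cover class labels
#'
#' The seven surface covers mapped by the pipeline, in their fixed integer
#' coding: bare soil, bright lichens (BL), bright lichens with moss (BLM),
#' moss, *Fulgensia* with moss (Fulg), green vegetation and dry vegetation.
#'
#' @format Character vector of length 7; integer code `i` means
#'   `cover_classes()[i]`.
#' @export
cover_classes <- function() {
  c("Soil", "BL", "BLM", "Moss", "Fulg", "GreenVeg", "DryVeg")
}

#' Grid header for a georeferenced raster
#'
#' Row 1 is the northernmost row, values refer to cell centres, all distances
#' are metres, and cells are square. `origin` is the (easting, northing) of
#' the upper-left *corner* of the grid.
#'
#' @param nrows,ncols Grid dimensions (>= 1).
#' @param cell_size Cell side length in metres (> 0).
#' @param origin Numeric length-2, (easting, northing) of the upper-left corner.
#' @param nodata Sentinel used on disk for missing cells. In memory missing
#'   cells are always `NA`.
#' @return An object of class `bc_grid`.
#' @export
bc_grid <- function(nrows, ncols, cell_size, origin = c(0, 0), nodata = -9999) {
  stopifnot(nrows >= 1, ncols >= 1, cell_size > 0, length(origin) == 2)
  structure(
    list(nrows = as.integer(nrows), ncols = as.integer(ncols),
         cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "bc_grid"
  )
}

#' Single-band raster
#'
#' @param grid A [bc_grid()].
#' @param values Numeric matrix of dimension `nrows x ncols`; `NA` marks
#'   missing cells (the nodata mask is explicit, never a magic number).
#' @return An object of class `bc_raster`.
#' @export
bc_raster <- function(grid, values) {
  stopifnot(inherits(grid, "bc_grid"))
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$nrows, grid$ncols)))
    stop("value matrix dimensions (", nrow(values), "x", ncol(values),
         ") do not match grid (", grid$nrows, "x", grid$ncols, ")")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "bc_raster")
}

#' Four-band multispectral raster
#'
#' Bands are fixed to green (550 nm), red (660 nm), red-edge (735 nm) and
#' NIR (790 nm), in that order.
#'
#' @param grid A [bc_grid()].
#' @param bands Named list of four matrices `green`, `red`, `red_edge`, `nir`.
#' @return An object of class `bc_multiband`.
#' @export
bc_multiband <- function(grid, bands) {
  stopifnot(inherits(grid, "bc_grid"))
  if (!identical(names(bands), band_names()))
    stop("bands must be exactly ", paste(band_names(), collapse = ", "),
         " in that order")
  bands <- lapply(bands, function(v) {
    v <- as.matrix(v)
    if (!identical(dim(v), c(grid$nrows, grid$ncols)))
      stop("band dimensions do not match grid")
    storage.mode(v) <- "double"
    v
  })
  structure(list(grid = grid, bands = bands), class = "bc_multiband")
}

#' @rdname bc_multiband
#' @export
band_names <- function() c("green", "red", "red_edge", "nir")

#' Band centre wavelengths (nm) of the four-band camera
#' @export
band_centres <- function() c(green = 550, red = 660, red_edge = 735, nir = 790)

#' Integer surface-cover raster
#'
#' @param grid A [bc_grid()].
#' @param labels Integer matrix over `1:7` coding [cover_classes()]; `NA` for
#'   missing cells.
#' @return An object of class `bc_classraster`.
#' @export
bc_classraster <- function(grid, labels) {
  stopifnot(inherits(grid, "bc_grid"))
  labels <- as.matrix(labels)
  if (!identical(dim(labels), c(grid$nrows, grid$ncols)))
    stop("label matrix dimensions do not match grid")
  ok <- is.na(labels) | (labels %in% seq_along(cover_classes()))
  if (!all(ok)) stop("labels must be NA or integer codes 1..7")
  storage.mode(labels) <- "integer"
  structure(list(grid = grid, labels = labels), class = "bc_classraster")
}

grid_of <- function(x) {
  if (inherits(x, "bc_grid")) x else x$grid
}

#' Assert that two rasters share one grid
#'
#' Grids must agree in origin, cell size and dimensions to within 1e-6 m.
#' Downstream operations call this instead of silently resampling.
#'
#' @param a,b Rasters (any of the `bc_*` raster classes) or grids.
#' @return Invisibly `TRUE`; otherwise an error naming the differing field.
#' @export
assert_aligned <- function(a, b) {
  ga <- grid_of(a); gb <- grid_of(b)
  if (ga$nrows != gb$nrows) stop("misaligned rasters: nrows differ (",
                                 ga$nrows, " vs ", gb$nrows, ")")
  if (ga$ncols != gb$ncols) stop("misaligned rasters: ncols differ (",
                                 ga$ncols, " vs ", gb$ncols, ")")
  if (abs(ga$cell_size - gb$cell_size) > 1e-6)
    stop("misaligned rasters: cell_size differs (", ga$cell_size, " vs ",
         gb$cell_size, ")")
  if (any(abs(ga$origin - gb$origin) > 1e-6))
    stop("misaligned rasters: origin differs")
  invisible(TRUE)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [bc_grid()].
#' @return List with `x` (length ncols, eastings) and `y` (length nrows,
#'   northings, decreasing because row 1 is northernmost).
#' @export
cell_centres <- function(grid) {
  h <- grid$cell_size
  list(x = grid$origin[1] + (seq_len(grid$ncols) - 0.5) * h,
       y = grid$origin[2] - (seq_len(grid$nrows) - 0.5) * h)
}

#' @export
print.bc_grid <- function(x, ...) {
  cat("<bc_grid> ", x$nrows, "x", x$ncols, " cells, ", x$cell_size,
      " m, origin (", x$origin[1], ", ", x$origin[2], ")\n", sep = "")
  invisible(x)
}

#' @export
print.bc_raster <- function(x, ...) {
  v <- x$values
  cat("<bc_raster> ", x$grid$nrows, "x", x$grid$ncols, " @ ",
      x$grid$cell_size, " m; range [",
      signif(suppressWarnings(min(v, na.rm = TRUE)), 5), ", ",
      signif(suppressWarnings(max(v, na.rm = TRUE)), 5), "]; ",
      sum(is.na(v)), " nodata cells\n", sep = "")
  invisible(x)
}

#' @export
print.bc_multiband <- function(x, ...) {
  cat("<bc_multiband> ", x$grid$nrows, "x", x$grid$ncols, " @ ",
      x$grid$cell_size, " m; bands ", paste(band_names(), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.bc_classraster <- function(x, ...) {
  tab <- table(factor(cover_classes()[x$labels], levels = cover_classes()))
  cat("<bc_classraster> ", x$grid$nrows, "x", x$grid$ncols, " cells\n", sep = "")
  print(tab)
  invisible(x)
}
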