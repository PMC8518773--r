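# Raster file I/O. All rasters are stored as ESRI ASCII grids (.asc): a
# plain-text header (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value)
# followed by row-major values, row 1 = northernmost. Multiband images are a
# set of single-band files "<stem>_<band>.asc". No reprojection: all inputs
# are assumed to share one planar CRS.

write_asc_one <- function(values, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  yll <- grid$origin[2] - grid$nrows * grid$cell_size
  writeLines(c(
    paste("ncols", grid$ncols),
    paste("nrows", grid$nrows),
    paste("xllcorner", formatC(grid$origin[1], format = "g", digits = 17)),
    paste("yllcorner", formatC(yll, format = "g", digits = 17)),
    paste("cellsize", formatC(grid$cell_size, format = "g", digits = 17)),
    paste("NODATA_value", formatC(grid$nodata, format = "g", digits = 17))
  ), con)
  v <- values
  v[is.na(v)] <- grid$nodata
  for (i in seq_len(grid$nrows))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 17),
                     collapse = " "), con)
  invisible(path)
}

read_asc_one <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                    "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not a valid ASCII grid header in ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("value count does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  g <- bc_grid(hdr$nrows, hdr$ncols, hdr$cellsize,
               origin = c(hdr$xllcorner,
                          hdr$yllcorner + hdr$nrows * hdr$cellsize),
               nodata = nodata)
  bc_raster(g, m)
}

multiband_paths <- function(path) {
  stem <- sub("\\.asc$", "", path)
  stats::setNames(paste0(stem, "_", band_names(), ".asc"), band_names())
}

#' Write a raster to disk
#'
#' Single-band rasters and class rasters are written as one ESRI ASCII grid;
#' a multiband raster is written as four grids `<stem>_<band>.asc`.
#'
#' @param x A `bc_raster`, `bc_classraster` or `bc_multiband`.
#' @param path Output path (`.asc`); for multiband, the stem of the band files.
#' @return Invisibly, the path(s) written.
#' @export
write_raster <- function(x, path) {
  if (inherits(x, "bc_raster")) return(write_asc_one(x$values, x$grid, path))
  if (inherits(x, "bc_classraster")) {
    v <- x$labels
    storage.mode(v) <- "double"
    return(write_asc_one(v, x$grid, path))
  }
  if (inherits(x, "bc_multiband")) {
    paths <- multiband_paths(path)
    for (b in band_names()) write_asc_one(x$bands[[b]], x$grid, paths[[b]])
    return(invisible(paths))
  }
  stop("not a raster object")
}

#' Read a raster from disk
#'
#' @param path Path written by [write_raster()].
#' @param expected_bands 1 for a single-band raster, 4 for a multiband image.
#' @return A `bc_raster` (`expected_bands = 1`) or `bc_multiband` (4).
#' @export
read_raster <- function(path, expected_bands = 1) {
  if (expected_bands == 1) {
    paths <- multiband_paths(path)
    if (!file.exists(path) && all(file.exists(paths)))
      stop("found a 4-band image at ", sub("\\.asc$", "", path),
           " but expected_bands = 1")
    if (!file.exists(path)) stop("file not found: ", path)
    return(read_asc_one(path))
  }
  if (expected_bands == 4) {
    paths <- multiband_paths(path)
    if (!all(file.exists(paths))) {
      if (file.exists(path))
        stop("found a single-band raster at ", path, " but expected_bands = 4")
      stop("band files not found: ", paste(paths[!file.exists(paths)],
                                           collapse = ", "))
    }
    rs <- lapply(paths, read_asc_one)
    for (r in rs[-1]) assert_aligned(rs[[1]], r)
    return(bc_multiband(rs[[1]]$grid, lapply(rs, function(r) r$values)))
  }
  stop("expected_bands must be 1 or 4")
}

#' Read a class raster from disk
#'
#' @param path Path to an ASCII grid of integer codes 1..7.
#' @return A `bc_classraster`.
#' @export
read_class_raster <- function(path) {
  r <- read_raster(path, 1)
  bc_classraster(r$grid, r$values)
}
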