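# Digital elevation model: a regular grid raster with square cells,
# elevations in metres, used to convert GPS altitude to altitude above ground.

#' Create a DEM grid
#'
#' @param z elevation matrix; `z[iy, ix]` is the elevation at the centre of
#'   the cell in column `ix` (west to east) and row `iy` (south to north).
#' @param xll,yll coordinates of the lower-left corner of the grid (metres).
#' @param cellsize cell edge length in metres.
#' @return An object of class `dem_grid`.
#' @export
dem_grid <- function(z, xll, yll, cellsize) {
  z <- as.matrix(z)
  stopifnot(cellsize > 0, all(is.finite(z)))
  structure(list(z = z, xll = xll, yll = yll, cellsize = cellsize,
                 nrows = nrow(z), ncols = ncol(z)),
            class = "dem_grid")
}

#' Ground elevation at arbitrary points (bilinear interpolation)
#'
#' Interpolates bilinearly between cell centres; points within the half-cell
#' margin of the grid edge are clamped to the edge cells. Points outside the
#' grid extent return `NA`.
#'
#' @param dem a `dem_grid`.
#' @param x,y point coordinates (metres), vectorized.
#' @return elevations in metres (`NA` outside the DEM extent).
#' @export
dem_elevation <- function(dem, x, y) {
  cs <- dem$cellsize
  inside <- x >= dem$xll & x <= dem$xll + dem$ncols * cs &
            y >= dem$yll & y <= dem$yll + dem$nrows * cs
  # fractional cell-centre coordinates
  gx <- (x - dem$xll) / cs - 0.5
  gy <- (y - dem$yll) / cs - 0.5
  gx <- pmin(pmax(gx, 0), dem$ncols - 1)
  gy <- pmin(pmax(gy, 0), dem$nrows - 1)
  ix0 <- pmin(floor(gx), dem$ncols - 2); ix0 <- pmax(ix0, 0)
  iy0 <- pmin(floor(gy), dem$nrows - 2); iy0 <- pmax(iy0, 0)
  if (dem$ncols == 1) ix0 <- rep(0, length(x))
  if (dem$nrows == 1) iy0 <- rep(0, length(y))
  tx <- gx - ix0; ty <- gy - iy0
  z <- dem$z
  idx <- function(iy, ix) z[cbind(iy + 1L, ix + 1L)]
  ix1 <- pmin(ix0 + 1, dem$ncols - 1); iy1 <- pmin(iy0 + 1, dem$nrows - 1)
  v <- (1 - tx) * (1 - ty) * idx(iy0, ix0) + tx * (1 - ty) * idx(iy0, ix1) +
       (1 - tx) * ty * idx(iy1, ix0) + tx * ty * idx(iy1, ix1)
  v[!inside] <- NA_real_
  v
}

#' Write a DEM as an ESRI ASCII grid
#'
#' @param dem a `dem_grid`.
#' @param path output file path.
#' @export
write_dem_asc <- function(dem, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", dem$ncols),
    paste("nrows", dem$nrows),
    paste("xllcorner", format(dem$xll, scientific = FALSE)),
    paste("yllcorner", format(dem$yll, scientific = FALSE)),
    paste("cellsize", format(dem$cellsize, scientific = FALSE)),
    "NODATA_value -9999"), con)
  # ESRI ASCII rows run north to south
  for (iy in dem$nrows:1)
    writeLines(paste(format(dem$z[iy, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid DEM
#'
#' @param path file path.
#' @return a `dem_grid`.
#' @export
read_dem_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  z_ns <- do.call(rbind, vals)
  stopifnot(nrow(z_ns) == hdr$nrows, ncol(z_ns) == hdr$ncols)
  z <- z_ns[nrow(z_ns):1, , drop = FALSE]  # back to south-to-north rows
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  dem_grid(z, xll, yll, hdr$cellsize)
}
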