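## Raster I/O. Grids are stored as ESRI ASCII grids (.asc): a plain-text,
## single-band format readable by every GIS. The CRS identifier travels in a
## sidecar "<path>.prj" text file when it is not the default "local".
## Multi-band products are written one file per band.

#' Read a raster band from an ESRI ASCII grid
#'
#' @param path `.asc` file.
#' @param bandLabel semantics to attach to the values (`"B2_490"`,
#'   `"B3_560"`, `"B4_665"`, `"DEPTH"`, `"CLASS"`, `"CHANGE"`).
#' @return a [BandGrid-class]; cells equal to the file's `NODATA_value` are
#'   NA.
#' @export
readRasterGrid <- function(path, bandLabel) {
  if (!file.exists(path)) stopData("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stopData("missing georeference header in ", path,
             " (need ncols/nrows/cellsize and an ll corner)")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) {
    x0 <- hdr$xllcorner; yTop <- hdr$yllcorner + nr * cs
  } else if (!is.null(hdr$xllcenter)) {
    x0 <- hdr$xllcenter - cs / 2
    yTop <- (hdr$yllcenter - cs / 2) + nr * cs
  } else stopData("missing georeference header in ", path)
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stopData("raster body of ", path, " has ", length(vals),
             " values; expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  crs <- "local"
  prj <- paste0(path, ".prj")
  if (file.exists(prj)) crs <- trimws(readLines(prj, warn = FALSE)[1])
  g <- GridGeoref(x0, yTop, cs, nr, nc, crs)
  BandGrid(m, g, bandLabel)
}

#' Write a raster band as an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so that
#' `readRasterGrid(writeRasterGrid(g))` round-trips exactly in double
#' precision; `CLASS`/`CHANGE` grids are written as integers. NA cells are
#' written as the nodata sentinel.
#'
#' @param grid a [BandGrid-class].
#' @param path output `.asc` file.
#' @param nodata on-disk nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
writeRasterGrid <- function(grid, path, nodata = -9999) {
  g <- grid@georef
  con <- tryCatch(file(path, "w"), error = function(e)
    stopData("cannot write raster to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  yll <- g@originY - g@nRows * g@pixelSize
  writeLines(c(sprintf("ncols %d", g@nCols),
               sprintf("nrows %d", g@nRows),
               sprintf("xllcorner %.17g", g@originX),
               sprintf("yllcorner %.17g", yll),
               sprintf("cellsize %.17g", g@pixelSize),
               sprintf("NODATA_value %g", nodata)), con)
  v <- grid@values
  integerBand <- grid@bandLabel %in% c("CLASS", "CHANGE")
  fmt <- if (integerBand) "%d" else "%.17g"
  for (r in seq_len(g@nRows)) {
    row <- v[r, ]
    out <- ifelse(is.na(row), sprintf("%g", nodata),
                  sprintf(fmt, if (integerBand) as.integer(row) else row))
    writeLines(paste(out, collapse = " "), con)
  }
  if (!identical(g@crs, "local"))
    writeLines(g@crs, paste0(path, ".prj"))
  invisible(path)
}

#' Read a full Scene from per-band raster files
#'
#' @param b2,b3,b4,depth paths to the blue/green/red reflectance and
#'   bathymetry `.asc` files; all must share one grid.
#' @return a [Scene-class].
#' @export
readScene <- function(b2, b3, b4, depth) {
  Scene(readRasterGrid(b2, "B2_490"), readRasterGrid(b3, "B3_560"),
        readRasterGrid(b4, "B4_665"), readRasterGrid(depth, "DEPTH"))
}

#' Write a Scene as per-band raster files
#'
#' Creates `B2_490.asc`, `B3_560.asc`, `B4_665.asc` and `DEPTH.asc` under
#' `dir`. Cells outside the scene's valid mask are written as nodata in the
#' reflectance bands.
#'
#' @param scene a [Scene-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(B2_490 = file.path(dir, "B2_490.asc"),
             B3_560 = file.path(dir, "B3_560.asc"),
             B4_665 = file.path(dir, "B4_665.asc"),
             DEPTH = file.path(dir, "DEPTH.asc"))
  for (lab in names(scene@bands))
    writeRasterGrid(scene@bands[[lab]], paths[[lab]])
  writeRasterGrid(scene@bathymetry, paths[["DEPTH"]])
  paths
}
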