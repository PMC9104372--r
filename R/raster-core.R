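## Constructors, accessors and grid geometry for the raster data model.

#' Construct a GridGeoref
#'
#' @param originX,originY map coordinates (m) of the top-left grid corner.
#' @param pixelSize square pixel edge in metres.
#' @param nRows,nCols grid dimensions.
#' @param crs CRS identifier string; all geometries are assumed to be
#'   expressed in this CRS (the package never reprojects).
#' @return a [GridGeoref-class].
#' @examples
#' g <- GridGeoref(0, 1000, pixelSize = 10, nRows = 4, nCols = 6)
#' pixelCenters(g)[1, ]   # centre of pixel (1, 1)
#' @export
GridGeoref <- function(originX = 0, originY = 0, pixelSize = 10,
                       nRows, nCols, crs = "local") {
  new("GridGeoref", originX = as.numeric(originX),
      originY = as.numeric(originY), pixelSize = as.numeric(pixelSize),
      nRows = as.integer(nRows), nCols = as.integer(nCols), crs = crs)
}

#' Construct a BandGrid
#'
#' @param values numeric matrix (NA = nodata).
#' @param georef a [GridGeoref-class]; if missing, a default georef matching
#'   `dim(values)` at 10 m is used.
#' @param bandLabel band semantics: `"B2_490"`, `"B3_560"`, `"B4_665"`
#'   (reflectance), `"DEPTH"`, `"CLASS"` or `"CHANGE"`.
#' @return a [BandGrid-class].
#' @export
BandGrid <- function(values, georef = NULL, bandLabel) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(georef))
    georef <- GridGeoref(nRows = nrow(values), nCols = ncol(values))
  new("BandGrid", georef = georef, values = values, bandLabel = bandLabel)
}

#' Assemble a Scene from three reflectance bands and bathymetry
#'
#' The validity mask is derived: a cell is valid iff all three bands and the
#' bathymetry are non-NA there.
#'
#' @param b2,b3,b4 reflectance [BandGrid-class]s (blue, green, red).
#' @param depth `DEPTH` [BandGrid-class] on the same georef.
#' @return a [Scene-class].
#' @export
Scene <- function(b2, b3, b4, depth) {
  bands <- list(B2_490 = b2, B3_560 = b3, B4_665 = b4)
  mask <- !(is.na(b2@values) | is.na(b3@values) | is.na(b4@values) |
              is.na(depth@values))
  new("Scene", bands = bands, bathymetry = depth, validMask = mask)
}

## Exact georef equality (co-registration test).
sameGeoref <- function(a, b) {
  isTRUE(a@originX == b@originX) && isTRUE(a@originY == b@originY) &&
    isTRUE(a@pixelSize == b@pixelSize) && a@nRows == b@nRows &&
    a@nCols == b@nCols && identical(a@crs, b@crs)
}

#' Pixel-centre coordinates of a grid
#'
#' Returns the map coordinates of every pixel centre in row-major order
#' (row 1 first). Used by every vector-on-raster test in the package: a pixel
#' belongs to a polygon iff its centre does.
#'
#' @param g a [GridGeoref-class].
#' @return (nRows*nCols) x 2 matrix with columns `x`, `y`.
#' @export
pixelCenters <- function(g) {
  s <- g@pixelSize
  xs <- g@originX + (seq_len(g@nCols) - 0.5) * s
  ys <- g@originY - (seq_len(g@nRows) - 0.5) * s
  cbind(x = rep(xs, times = g@nRows), y = rep(ys, each = g@nCols))
}

## row-major centre grid, vectorized (rows vary slowest)
pixelCenterGrid <- function(g) {
  s <- g@pixelSize
  xs <- g@originX + (seq_len(g@nCols) - 0.5) * s
  ys <- g@originY - (seq_len(g@nRows) - 0.5) * s
  list(x = matrix(rep(xs, each = g@nRows), g@nRows, g@nCols),
       y = matrix(rep(ys, times = g@nCols), g@nRows, g@nCols))
}

#' @describeIn GridGeoref-class accessor for the pixel size in metres.
#' @param x object.
#' @export
setMethod("pixelSize", "GridGeoref", function(x) x@pixelSize)

#' @export
setMethod("pixelSize", "BandGrid", function(x) x@georef@pixelSize)

#' @export
setMethod("georef", "BandGrid", function(x) x@georef)

#' @export
setMethod("georef", "Scene", function(x) x@bands[[1]]@georef)

#' @export
setMethod("gridValues", "BandGrid", function(x) x@values)

#' @export
setMethod("bandLabel", "BandGrid", function(x) x@bandLabel)

#' @export
setMethod("sceneBands", "Scene", function(x) x@bands)

#' @export
setMethod("bathymetry", "Scene", function(x) x@bathymetry)

#' @export
setMethod("bathymetry", "SceneTruth", function(x) x@bathymetry)

#' @export
setMethod("validMask", "Scene", function(x) x@validMask)

#' @export
setMethod("classMap", "SceneTruth", function(x) x@classMap)

setMethod("show", "GridGeoref", function(object) {
  cat(sprintf("GridGeoref: %d x %d pixels @ %g m, origin (%g, %g), crs '%s'\n",
              object@nRows, object@nCols, object@pixelSize, object@originX,
              object@originY, object@crs))
})

setMethod("show", "BandGrid", function(object) {
  v <- object@values
  n <- sum(!is.na(v))
  cat(sprintf("BandGrid '%s': %d x %d pixels @ %g m (%d valid)\n",
              object@bandLabel, nrow(v), ncol(v), object@georef@pixelSize, n))
  if (n > 0)
    cat(sprintf("  range of valid values: [%g, %g]\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "Scene", function(object) {
  g <- georef(object)
  cat(sprintf("Scene: %d x %d pixels @ %g m, %d valid cells\n",
              g@nRows, g@nCols, g@pixelSize, sum(object@validMask)))
  d <- object@bathymetry@values[object@validMask]
  if (length(d))
    cat(sprintf("  depth range over valid cells: %.2f - %.2f m\n",
                min(d), max(d)))
})

## Replace band/bathymetry values while keeping georef and label; revalidates.
updateGridValues <- function(grid, values) {
  grid@values <- values
  validObject(grid)
  grid
}

## Apply a logical "drop" matrix to a scene: dropped cells become NA in all
## reflectance bands; bathymetry is kept (it is auxiliary data, not signal)
## but the valid mask excludes dropped cells.
dropCells <- function(scene, drop) {
  bands <- lapply(scene@bands, function(b) {
    v <- b@values
    v[drop] <- NA_real_
    b@values <- v
    b
  })
  mask <- scene@validMask & !drop
  new("Scene", bands = bands, bathymetry = scene@bathymetry, validMask = mask)
}
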