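## Minimal vector-geometry support: GeoJSON reading/writing and the even-odd
## point-in-polygon test used for every vector-on-raster operation. Geometries
## are assumed to be in the raster CRS already; no reprojection.
##
## Internal polygon representation: a list of "features", each a list with
##   $type     "Polygon" | "MultiPolygon" | "Point"
##   $rings    list of 2-column coordinate matrices (outer + holes, flattened
##             across parts for MultiPolygon); absent for points
##   $coords   length-2 numeric for points
##   $class    optional class label from the "class" property

#' Read vector features from a GeoJSON file
#'
#' Supports FeatureCollection / Feature / bare geometry documents with
#' Polygon, MultiPolygon and Point geometries. A `class` property, when
#' present, is attached to each feature (used for training data).
#'
#' @param path GeoJSON file.
#' @return list of feature lists (internal representation).
#' @export
readVectorFeatures <- function(path) {
  if (!file.exists(path)) stopData("vector file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(doc$type %||% "",
    FeatureCollection = doc$features,
    Feature = list(doc),
    Polygon = , MultiPolygon = , Point = list(list(geometry = doc)),
    stopData("unsupported GeoJSON document in ", path))
  lapply(feats, parseFeature)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parseFeature <- function(f) {
  geom <- f$geometry
  cls <- f$properties$class %||% NULL
  ringMat <- function(ring)
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  if (geom$type == "Polygon") {
    list(type = "Polygon", rings = lapply(geom$coordinates, ringMat),
         class = cls)
  } else if (geom$type == "MultiPolygon") {
    rings <- unlist(lapply(geom$coordinates,
                           function(part) lapply(part, ringMat)),
                    recursive = FALSE)
    list(type = "MultiPolygon", rings = rings, class = cls)
  } else if (geom$type == "Point") {
    list(type = "Point", coords = c(geom$coordinates[[1]],
                                    geom$coordinates[[2]]), class = cls)
  } else stopData("unsupported geometry type: ", geom$type)
}

#' Write polygon/point features to GeoJSON
#'
#' @param features list in the internal feature representation (as returned
#'   by [readVectorFeatures()]), or a single rectangle created with
#'   [rectangleFeature()].
#' @param path output file.
#' @export
writeVectorFeatures <- function(features, path) {
  if (!is.null(features$type)) features <- list(features)
  asFeature <- function(f) {
    props <- if (is.null(f$class)) setNames(list(), character(0))
             else list(class = f$class)
    geom <- if (f$type == "Point") {
      list(type = "Point", coordinates = as.numeric(f$coords))
    } else {
      list(type = "Polygon",
           coordinates = lapply(f$rings, function(r)
             lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))))
    }
    list(type = "Feature", properties = props, geometry = geom)
  }
  doc <- list(type = "FeatureCollection", features = lapply(features, asFeature))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Axis-aligned rectangle feature
#'
#' Convenience constructor for calibration-zone and mask polygons.
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds in map units.
#' @param class optional class label.
#' @return a polygon feature (internal representation).
#' @export
rectangleFeature <- function(xmin, xmax, ymin, ymax, class = NULL) {
  ring <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                c(xmin, ymax), c(xmin, ymin))
  list(type = "Polygon", rings = list(ring), class = class)
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the even-odd rule over all rings of a polygon, so holes
#' are handled without ring-orientation bookkeeping. Points exactly on a
#' horizontal edge follow the half-open convention of the crossing test.
#'
#' @param px,py point coordinates (vectors).
#' @param rings list of 2-column ring matrices.
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring)
    if (x[1] == x[n] && y[1] == y[n]) n <- n - 1L  # drop duplicated closure
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

## Membership of every pixel centre of georef g in a set of features
## (polygons only); returns a logical matrix in grid layout.
centersInFeatures <- function(g, features) {
  ctr <- pixelCenterGrid(g)
  inside <- matrix(FALSE, g@nRows, g@nCols)
  for (f in features) {
    if (f$type == "Point") next
    inside <- inside | matrix(pointInPolygon(as.vector(ctr$x),
                                             as.vector(ctr$y), f$rings),
                              g@nRows, g@nCols)
  }
  inside
}

#' Rasterize class-labelled polygons to a CLASS grid
#'
#' Pixel-centre rule: a pixel takes the class of the first feature containing
#' its centre (first-feature-wins on overlap). Pixels in no feature are
#' nodata.
#'
#' @param features feature list with `class` labels (`"seagrass"` mapped to
#'   1, anything else to 0).
#' @param g target [GridGeoref-class].
#' @return a `CLASS` [BandGrid-class].
#' @export
rasterizeFeatures <- function(features, g) {
  vals <- matrix(NA_real_, g@nRows, g@nCols)
  ctr <- pixelCenterGrid(g)
  for (f in features) {
    if (f$type == "Point") next
    inside <- matrix(pointInPolygon(as.vector(ctr$x), as.vector(ctr$y),
                                    f$rings), g@nRows, g@nCols)
    code <- if (identical(f$class, "seagrass")) 1 else 0
    take <- inside & is.na(vals)
    vals[take] <- code
  }
  BandGrid(vals, g, "CLASS")
}
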