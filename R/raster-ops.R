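## Masking and resampling operations on scenes and grids. Masking never
## alters valid values — it only changes which cells are valid.

#' Mask a scene with polygons
#'
#' Cells whose centres fall on the discarded side of the polygon set become
#' nodata in all reflectance bands and the validity mask; the georeference is
#' unchanged. Typical use: clipping out the mainland with a coastline
#' polygon.
#'
#' @param scene a [Scene-class].
#' @param polygons feature list (see [readVectorFeatures()]) in the scene
#'   CRS.
#' @param keepInside if `TRUE` (default) keep cells inside the polygons and
#'   discard the rest; if `FALSE`, the converse.
#' @return the masked [Scene-class].
#' @export
applyPolygonMask <- function(scene, polygons, keepInside = TRUE) {
  polys <- Filter(function(f) f$type != "Point", polygons)
  if (length(polys) == 0) {
    warning("empty geometry set: mask is a no-op")
    return(scene)
  }
  inside <- centersInFeatures(georef(scene), polys)
  drop <- if (keepInside) !inside else inside
  dropCells(scene, drop)
}

#' Clip a scene to a maximum depth
#'
#' Cells deeper than `maxDepth` become nodata. The default of 20 m reflects
#' the working limit beyond which reliable quantitative seafloor estimates
#' are difficult to derive from visible-band imagery.
#'
#' @param scene a [Scene-class].
#' @param maxDepth metres (default 20).
#' @return the clipped [Scene-class].
#' @export
clipByDepth <- function(scene, maxDepth = 20) {
  z <- scene@bathymetry@values
  drop <- !is.na(z) & z > maxDepth
  dropCells(scene, drop)
}

#' Resample a bathymetry grid onto a target georef
#'
#' Bilinear (default, for continuous depth) or nearest-neighbour
#' interpolation of source pixel-centre values at the target pixel centres.
#' Target cells outside the source coverage are nodata: bilinear requires all
#' four surrounding source centres, nearest requires the centre to fall
#' within the source extent.
#'
#' @param src source [BandGrid-class] (any resolution).
#' @param target target [GridGeoref-class].
#' @param method `"bilinear"` or `"nearest"`.
#' @return a [BandGrid-class] on `target` with the source's band label.
#' @export
resampleBathymetry <- function(src, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  sg <- src@georef
  if (sameGeoref(sg, target) ) return(src)
  ## extent overlap check
  sxmin <- sg@originX; sxmax <- sg@originX + sg@nCols * sg@pixelSize
  symax <- sg@originY; symin <- sg@originY - sg@nRows * sg@pixelSize
  txmin <- target@originX; txmax <- target@originX + target@nCols * target@pixelSize
  tymax <- target@originY; tymin <- target@originY - target@nRows * target@pixelSize
  if (txmin >= sxmax || txmax <= sxmin || tymin >= symax || tymax <= symin)
    stopData("source and target extents are disjoint")
  ctr <- pixelCenterGrid(target)
  ## fractional source pixel indices of the target centres (1-based, centre
  ## of source pixel k at index k)
  fc <- (as.vector(ctr$x) - sg@originX) / sg@pixelSize + 0.5
  fr <- (sg@originY - as.vector(ctr$y)) / sg@pixelSize + 0.5
  out <- rep(NA_real_, length(fc))
  V <- src@values
  if (method == "nearest") {
    r <- round(fr); c <- round(fc)
    ok <- r >= 1 & r <= sg@nRows & c >= 1 & c <= sg@nCols
    out[ok] <- V[cbind(r[ok], c[ok])]
  } else {
    r0 <- floor(fr); c0 <- floor(fc)
    ok <- r0 >= 1 & r0 + 1 <= sg@nRows & c0 >= 1 & c0 + 1 <= sg@nCols
    wr <- fr[ok] - r0[ok]; wc <- fc[ok] - c0[ok]
    i00 <- cbind(r0[ok], c0[ok]);     i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- (1 - wr) * ((1 - wc) * V[i00] + wc * V[i01]) +
      wr * ((1 - wc) * V[i10] + wc * V[i11])
  }
  BandGrid(matrix(out, target@nRows, target@nCols), target, src@bandLabel)
}
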