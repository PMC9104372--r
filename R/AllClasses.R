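## S4 class definitions for the whole package. Raster grids are kept as plain
## numeric matrices inside lightweight georeferenced containers; nodata is NA.

BAND_LABELS <- c("B2_490", "B3_560", "B4_665", "DEPTH", "CLASS", "CHANGE")
REFLECTANCE_LABELS <- c("B2_490", "B3_560", "B4_665")

#' GridGeoref: raster grid georeferencing
#'
#' Describes a north-up regular grid: the map coordinate of the top-left
#' corner, a square pixel size in metres, the grid dimensions and a free-text
#' CRS identifier. Pixel (r, c) (1-based) covers the half-open square
#' \eqn{[x_0 + (c-1)s, x_0 + cs) \times (y_0 - rs, y_0 - (r-1)s]} with row 1
#' at the top; its centre is at \eqn{(x_0 + (c - 1/2)s,\; y_0 - (r - 1/2)s)}.
#'
#' @slot originX,originY map coordinates (m) of the top-left grid corner.
#' @slot pixelSize square pixel edge in metres (default 10, the visible-band
#'   resolution of Sentinel-2).
#' @slot nRows,nCols grid dimensions.
#' @slot crs CRS identifier string (not interpreted; compared for equality).
#' @exportClass GridGeoref
setClass("GridGeoref",
  representation(originX = "numeric", originY = "numeric",
                 pixelSize = "numeric", nRows = "integer", nCols = "integer",
                 crs = "character"),
  prototype(originX = 0, originY = 0, pixelSize = 10, nRows = 1L, nCols = 1L,
            crs = "local"))

setValidity("GridGeoref", function(object) {
  msg <- character(0)
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (!is.finite(object@originX) || !is.finite(object@originY))
    msg <- c(msg, "origin coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' BandGrid: one georeferenced raster band
#'
#' A single 2-D raster layer with a [GridGeoref-class] and a band label.
#' Reflectance bands (`B2_490`, `B3_560`, `B4_665`) hold unitless surface or
#' bottom reflectance in \[0, 1.5\] (minor over-unity from noise tolerated);
#' `DEPTH` holds water depth in metres, positive downward; `CLASS` holds
#' integer class codes (1 = seagrass, 0 = other); `CHANGE` holds change
#' categories (0 stable other, 1 stable seagrass, 2 loss, 3 gain).
#' Nodata cells are `NA`.
#'
#' @slot georef a [GridGeoref-class].
#' @slot values numeric matrix, dimensions matching the georef.
#' @slot bandLabel one of `"B2_490"`, `"B3_560"`, `"B4_665"`, `"DEPTH"`,
#'   `"CLASS"`, `"CHANGE"`.
#' @exportClass BandGrid
setClass("BandGrid",
  representation(georef = "GridGeoref", values = "matrix",
                 bandLabel = "character"))

setValidity("BandGrid", function(object) {
  msg <- character(0)
  g <- object@georef
  if (!identical(dim(object@values), c(g@nRows, g@nCols)))
    msg <- c(msg, "values dimensions do not match georef")
  if (length(object@bandLabel) != 1 || !object@bandLabel %in% BAND_LABELS)
    msg <- c(msg, paste0("bandLabel must be one of: ",
                         paste(BAND_LABELS, collapse = ", ")))
  v <- object@values[!is.na(object@values)]
  if (length(v)) {
    if (object@bandLabel %in% REFLECTANCE_LABELS &&
        (min(v) < 0 || max(v) > 1.5))
      msg <- c(msg, "reflectance values must lie in [0, 1.5]")
    if (object@bandLabel == "DEPTH" && min(v) < 0)
      msg <- c(msg, "depth values must be >= 0 (positive-down metres)")
    if (object@bandLabel %in% c("CLASS", "CHANGE") && any(v != round(v)))
      msg <- c(msg, "class/change values must be integers")
  }
  if (length(msg)) msg else TRUE
})

#' Scene: co-registered multispectral stack with bathymetry
#'
#' Three reflectance [BandGrid-class] layers (blue, green, red) plus a
#' bathymetry layer, all on one shared [GridGeoref-class] (the
#' co-registration contract: temporal comparisons are only meaningful on the
#' same grid). The validity mask is `FALSE` wherever any band or the
#' bathymetry is nodata.
#'
#' @slot bands list of exactly three `BandGrid`s named `B2_490`, `B3_560`,
#'   `B4_665`.
#' @slot bathymetry `DEPTH` `BandGrid` on the same georef.
#' @slot validMask logical matrix.
#' @exportClass Scene
setClass("Scene",
  representation(bands = "list", bathymetry = "BandGrid",
                 validMask = "matrix"))

setValidity("Scene", function(object) {
  msg <- character(0)
  if (length(object@bands) != 3 ||
      !identical(names(object@bands), REFLECTANCE_LABELS))
    msg <- c(msg, "bands must be a list named B2_490, B3_560, B4_665")
  else {
    g <- object@bands[[1]]@georef
    for (b in object@bands)
      if (!sameGeoref(b@georef, g))
        msg <- c(msg, "all bands must share one GridGeoref")
    if (!sameGeoref(object@bathymetry@georef, g))
      msg <- c(msg, "bathymetry must share the bands' GridGeoref")
    if (object@bathymetry@bandLabel != "DEPTH")
      msg <- c(msg, "bathymetry must carry bandLabel DEPTH")
    if (!identical(dim(object@validMask), dim(object@bands[[1]]@values)))
      msg <- c(msg, "validMask dimensions must match the grids")
    anyNA <- Reduce(`|`, lapply(object@bands, function(b) is.na(b@values)),
                    is.na(object@bathymetry@values))
    if (any(object@validMask & anyNA))
      msg <- c(msg, "validMask must be FALSE wherever any layer is nodata")
  }
  if (length(msg)) msg else TRUE
})

#' ScenarioConfig: synthetic coastal scene description
#'
#' Fully specifies the stated world of the synthetic generator: grid size and
#' resolution, the shore-to-offshore depth range, the optical constants of the
#' forward model (deep-water reflectance and diffuse attenuation per band),
#' per-class bottom spectra, seagrass patch layout, sensor noise and the seed.
#' Optical defaults are the study-area estimates for Sentinel-2 bands 2/3/4:
#' R_inf = (0.0200, 0.0136, 0.0045), K_d = (0.0197, 0.0303, 0.1046) m^-1.
#'
#' @slot nRows,nCols grid dimensions.
#' @slot pixelSize metres (default 10).
#' @slot depthRange c(min, max) depth in metres (default c(0, 45)).
#' @slot rInf per-band deep-water reflectance.
#' @slot kd per-band diffuse attenuation coefficients (m^-1).
#' @slot bottomSpectra 2x3 matrix, rows `sand` and `seagrass`.
#' @slot patchCount number of seagrass patches.
#' @slot patchFraction target fraction of the 1-11 m habitat belt covered by
#'   seagrass.
#' @slot noiseSd additive reflectance noise standard deviation.
#' @slot seed integer seed.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(nRows = "integer", nCols = "integer", pixelSize = "numeric",
                 depthRange = "numeric", rInf = "numeric", kd = "numeric",
                 bottomSpectra = "matrix", patchCount = "integer",
                 patchFraction = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character(0)
  if (length(object@depthRange) != 2 ||
      object@depthRange[1] < 0 || diff(object@depthRange) <= 0)
    msg <- c(msg, "depthRange must be c(min, max) with 0 <= min < max")
  if (length(object@rInf) != 3 || any(object@rInf < 0))
    msg <- c(msg, "rInf must be 3 nonnegative per-band values")
  if (length(object@kd) != 3 || any(object@kd <= 0))
    msg <- c(msg, "kd must be 3 positive per-band values (m^-1)")
  if (!identical(rownames(object@bottomSpectra), c("sand", "seagrass")) ||
      ncol(object@bottomSpectra) != 3)
    msg <- c(msg, "bottomSpectra must be a 2x3 matrix with rows sand, seagrass")
  else if (any(object@bottomSpectra["sand", ] <= object@rInf))
    msg <- c(msg, "sand must be brighter than deep water in every band")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@patchFraction < 0 || object@patchFraction > 1)
    msg <- c(msg, "patchFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SceneTruth: generating truth of a synthetic scene
#'
#' The true benthic class map (1 = seagrass, 0 = other) and bathymetry behind
#' a synthetic scene, with the generating [ScenarioConfig-class]. Stands in
#' for a field-mapped baseline (e.g. a sonar survey product) in tests of
#' classification and change analysis.
#'
#' @slot classMap `CLASS` [BandGrid-class].
#' @slot bathymetry `DEPTH` [BandGrid-class].
#' @slot config the generating [ScenarioConfig-class].
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(classMap = "BandGrid", bathymetry = "BandGrid",
                 config = "ScenarioConfig"))

setValidity("SceneTruth", function(object) {
  bad <- is.na(object@classMap@values) & !is.na(object@bathymetry@values)
  if (any(bad)) "classMap must be defined wherever bathymetry is valid"
  else TRUE
})

#' LabeledSamples: labelled pixel feature vectors
#'
#' Per-sample 3-band reflectance features with a two-level class label
#' (`seagrass` / `other`), the pixel location each sample came from, and its
#' provenance (training polygon or ground-control point).
#'
#' @slot features n x 3 numeric matrix (columns B2_490, B3_560, B4_665).
#' @slot labels factor with levels `other`, `seagrass`.
#' @slot source character, `"polygon"` or `"point"` per sample.
#' @slot location n x 2 integer matrix of (row, col) pixel indices.
#' @exportClass LabeledSamples
setClass("LabeledSamples",
  representation(features = "matrix", labels = "factor",
                 source = "character", location = "matrix"))

setValidity("LabeledSamples", function(object) {
  msg <- character(0)
  n <- nrow(object@features)
  if (n < 1) msg <- c(msg, "at least one sample required")
  if (ncol(object@features) != 3) msg <- c(msg, "features must have 3 columns")
  if (!identical(levels(object@labels), c("other", "seagrass")))
    msg <- c(msg, "labels must be a factor with levels other, seagrass")
  if (length(object@labels) != n || nrow(object@location) != n)
    msg <- c(msg, "features, labels and location lengths must agree")
  if (any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite")
  if (length(msg)) msg else TRUE
})

#' SampleSplit: stratified train/test partition
#'
#' @slot train,test [LabeledSamples-class] partitions.
#' @slot trainFraction requested training fraction (default 0.4, the
#'   40/60 train/assessment convention).
#' @slot seed integer seed used for the draw.
#' @exportClass SampleSplit
setClass("SampleSplit",
  representation(train = "LabeledSamples", test = "LabeledSamples",
                 trainFraction = "numeric", seed = "integer"))

#' MLCModel: Gaussian maximum-likelihood classifier
#'
#' Per-class multivariate normal model: sample mean, regularized sample
#' covariance and prior. The discriminant of class i at feature x is
#' \deqn{g_i(x) = -\tfrac12 \log|\Sigma_i| - \tfrac12 (x-\mu_i)^T
#'   \Sigma_i^{-1} (x-\mu_i) + \log p_i.}
#'
#' @slot classes class names (`other`, `seagrass`).
#' @slot means 2 x 3 matrix of class means.
#' @slot covariances list of 3 x 3 covariance matrices (after adding
#'   `regularizationEpsilon` times the identity).
#' @slot priors per-class priors summing to 1.
#' @slot regularizationEpsilon ridge added to each covariance diagonal.
#' @exportClass MLCModel
setClass("MLCModel",
  representation(classes = "character", means = "matrix",
                 covariances = "list", priors = "numeric",
                 regularizationEpsilon = "numeric"))

setValidity("MLCModel", function(object) {
  msg <- character(0)
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1")
  for (S in object@covariances) {
    if (any(abs(S - t(S)) > 1e-10)) msg <- c(msg, "covariances must be symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      msg <- c(msg, "covariances must be positive-definite after regularization")
  }
  if (length(msg)) msg else TRUE
})

#' DeepWaterEstimate: deep-water reflectance
#'
#' Per-band median surface reflectance over pixels deeper than a threshold —
#' the asymptotic signal of an infinitely deep water column, R_inf.
#'
#' @slot rInf per-band reflectance (B2_490, B3_560, B4_665).
#' @slot nPixels number of qualifying deep pixels.
#' @slot depthThreshold metres (default 40).
#' @exportClass DeepWaterEstimate
setClass("DeepWaterEstimate",
  representation(rInf = "numeric", nPixels = "integer",
                 depthThreshold = "numeric"))

setValidity("DeepWaterEstimate", function(object) {
  msg <- character(0)
  if (length(object@rInf) != 3 || any(object@rInf < 0))
    msg <- c(msg, "rInf must be 3 nonnegative values")
  if (object@nPixels <= 0) msg <- c(msg, "nPixels must be > 0")
  if (length(msg)) msg else TRUE
})

#' AttenuationFit: diffuse attenuation regression
#'
#' Per-band ordinary least squares of log-transformed reflectance against
#' depth over the sandy calibration zone. The slope estimates -2 K_d, so
#' `kd = -slope / 2` in m^-1.
#'
#' @slot kd per-band diffuse attenuation coefficients (m^-1).
#' @slot slope,intercept,rSquared per-band regression diagnostics.
#' @slot nPoints number of calibration cells used.
#' @slot transform `"log_contrast"` (ln(R_w - R_inf), the exact linearization
#'   of the shallow-water model) or `"log_raw"` (ln R_w).
#' @exportClass AttenuationFit
setClass("AttenuationFit",
  representation(kd = "numeric", slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", nPoints = "integer",
                 transform = "character"))

setValidity("AttenuationFit", function(object) {
  msg <- character(0)
  if (!object@transform %in% c("log_contrast", "log_raw"))
    msg <- c(msg, "transform must be log_contrast or log_raw")
  if (any(object@rSquared < -1e-12 | object@rSquared > 1 + 1e-12,
          na.rm = TRUE))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ConfusionSummary: contingency table with accuracy metrics
#'
#' A k x k confusion matrix with rows = classified, columns = reference
#' (user accuracy on rows, producer accuracy on columns), plus overall
#' accuracy and Cohen's kappa. Per-class metrics whose denominator is zero
#' are `NA` ("undefined"), never 0.
#'
#' @slot counts k x k integer matrix (rows classified, columns reference).
#' @slot classOrder class labels ordering rows and columns.
#' @slot userAccuracy,producerAccuracy per-class accuracies
#'   (commission = 1 - user, omission = 1 - producer).
#' @slot overallAccuracy trace / total.
#' @slot kappa Cohen's chance-corrected agreement.
#' @exportClass ConfusionSummary
setClass("ConfusionSummary",
  representation(counts = "matrix", classOrder = "character",
                 userAccuracy = "numeric", producerAccuracy = "numeric",
                 overallAccuracy = "numeric", kappa = "numeric"))

#' ChangeSummary: stable/loss/gain area bookkeeping
#'
#' Pixel counts and hectare areas per change category, with derived epoch
#' totals: epoch-1 seagrass = stable + loss, epoch-2 seagrass = stable + gain.
#' At 10 m pixels one pixel is 0.01 ha.
#'
#' @slot pixelCounts named integer vector
#'   (stable_seagrass, loss, gain, stable_other).
#' @slot areaHa same categories in hectares.
#' @slot pixelSize metres.
#' @slot epoch1SeagrassHa,epoch2SeagrassHa derived epoch totals (ha).
#' @exportClass ChangeSummary
setClass("ChangeSummary",
  representation(pixelCounts = "integer", areaHa = "numeric",
                 pixelSize = "numeric", epoch1SeagrassHa = "numeric",
                 epoch2SeagrassHa = "numeric"))
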