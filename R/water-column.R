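## Water-column correction: estimate the optical constants of the
## optically-shallow-water model from the scene itself, then invert the model
## to a bottom-reflectance composite.
##
## Model: R_w = R_inf + (R_b - R_inf) exp(-2 Kd Z). Taking logs of the
## contrast gives ln(R_w - R_inf) = ln(R_b - R_inf) - 2 Kd Z, so over a
## uniform substrate the slope of ln(R_w - R_inf) against depth is exactly
## -2 Kd.

#' Estimate deep-water reflectance
#'
#' Per-band median surface reflectance over valid pixels deeper than
#' `depthThreshold` — at such depths the bottom contribution is negligible
#' and the residual signal approximates the reflectance of an infinitely
#' deep water column (R_inf). The median is robust to stray bottom signal
#' and sensor outliers.
#'
#' @param scene a [Scene-class].
#' @param depthThreshold metres (default 40).
#' @param minDeepPixels minimum qualifying pixels (default 100) before the
#'   estimate is considered meaningful.
#' @return a [DeepWaterEstimate-class].
#' @export
estimateDeepWaterReflectance <- function(scene, depthThreshold = 40,
                                         minDeepPixels = 100) {
  z <- scene@bathymetry@values
  deep <- scene@validMask & !is.na(z) & z > depthThreshold
  n <- sum(deep)
  if (n < minDeepPixels)
    stopData("only ", n, " valid pixels deeper than ", depthThreshold,
             " m (need at least ", minDeepPixels,
             "); deep-water reflectance cannot be estimated")
  rInf <- vapply(scene@bands, function(b) stats::median(b@values[deep]),
                 numeric(1))
  new("DeepWaterEstimate", rInf = unname(rInf), nPixels = as.integer(n),
      depthThreshold = as.numeric(depthThreshold))
}

#' Fit diffuse attenuation coefficients over a sandy calibration zone
#'
#' Ordinary least squares of log-transformed surface reflectance on depth,
#' per band, over the valid cells whose centres fall in the calibration
#' polygon and whose depth lies in \[`depthMin`, `depthMax`\] (defaults 1 and
#' 5 m — a uniform bright sandy area with a gradual depth increase). The
#' regression slope estimates -2 Kd, so `kd = -slope / 2`.
#'
#' The default transform `log_contrast`, X = ln(R_w - R_inf), is the exact
#' linearization of the shallow-water model; `log_raw`, X = ln(R_w), is
#' retained for literal replication of workflows that regress raw
#' log-reflectance. Cells with R_w <= R_inf (no measurable bottom signal)
#' are dropped with a message; if more than half the candidate cells drop,
#' the zone is rejected as unsuitable.
#'
#' @param scene a [Scene-class].
#' @param calibrationZone polygon feature (see [readVectorFeatures()],
#'   [rectangleFeature()]).
#' @param rInf a [DeepWaterEstimate-class] (or 3 numeric values).
#' @param depthMin,depthMax calibration depth window in metres.
#' @param transform `"log_contrast"` (default) or `"log_raw"`.
#' @param minCells minimum usable cells (default 10).
#' @return an [AttenuationFit-class].
#' @export
fitAttenuation <- function(scene, calibrationZone, rInf, depthMin = 1,
                           depthMax = 5,
                           transform = c("log_contrast", "log_raw"),
                           minCells = 10) {
  transform <- match.arg(transform)
  if (is(rInf, "DeepWaterEstimate")) rInf <- rInf@rInf
  zone <- if (!is.null(calibrationZone$type)) list(calibrationZone)
          else calibrationZone
  inZone <- centersInFeatures(georef(scene), zone)
  z <- scene@bathymetry@values
  use <- scene@validMask & inZone & !is.na(z) & z >= depthMin & z <= depthMax
  if (sum(use) < minCells)
    stopData("only ", sum(use), " valid calibration cells in the 1-5 m ",
             "window (need at least ", minCells, ")")
  zv <- z[use]
  if (stats::var(zv) == 0)
    stopData("calibration zone has constant depth; the attenuation slope ",
             "is undefined")
  slope <- intercept <- r2 <- numeric(3)
  nUsed <- integer(3)
  for (b in 1:3) {
    rw <- scene@bands[[b]]@values[use]
    if (transform == "log_contrast") {
      keep <- rw > rInf[b]
      if (sum(!keep) > 0)
        message(sum(!keep), " cells with R_w <= R_inf dropped from band ",
                names(scene@bands)[b], " attenuation fit")
      if (sum(!keep) > 0.5 * length(rw))
        stopData("more than half the calibration cells have R_w <= R_inf ",
                 "in band ", names(scene@bands)[b],
                 "; the zone is unsuitable")
      x <- log(rw[keep] - rInf[b]); zz <- zv[keep]
    } else {
      keep <- rw > 0
      x <- log(rw[keep]); zz <- zv[keep]
    }
    if (stats::var(zz) == 0)
      stopData("calibration cells have constant depth after filtering")
    fit <- stats::lm.fit(cbind(1, zz), x)
    slope[b] <- fit$coefficients[2]
    intercept[b] <- fit$coefficients[1]
    ssRes <- sum(fit$residuals^2)
    ssTot <- sum((x - mean(x))^2)
    r2[b] <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
    nUsed[b] <- length(x)
  }
  new("AttenuationFit", kd = -slope / 2, slope = slope,
      intercept = intercept, rSquared = r2, nPoints = min(nUsed),
      transform = transform)
}

#' Invert the water-column effect to bottom reflectance
#'
#' Per valid cell and band,
#' \deqn{R_b = R_\infty + (R_w - R_\infty)\, e^{+2 K_d Z},}
#' the exact inversion of the forward model. Cells deeper than `maxDepth`
#' (default 20 m, the standard working clip) become nodata: the exponential
#' amplifies sensor noise as \eqn{e^{2 K_d Z}}, so deep corrections are
#' unreliable. Cells with \eqn{R_w \le R_\infty} carry no measurable bottom
#' signal and are set to \eqn{R_\infty}; output is clipped to \[0, 1.5\].
#' Both adjustments are reported via `message()` with cell counts.
#'
#' @param scene a [Scene-class] (surface reflectance plus bathymetry).
#' @param rInf a [DeepWaterEstimate-class] (or 3 numeric values).
#' @param fit an [AttenuationFit-class] (or 3 numeric Kd values, m^-1).
#' @param maxDepth metres (default 20).
#' @return list of 3 bottom-reflectance [BandGrid-class]s
#'   (B2_490/B3_560/B4_665).
#' @export
correctWaterColumn <- function(scene, rInf, fit, maxDepth = 20) {
  if (is(rInf, "DeepWaterEstimate")) rInf <- rInf@rInf
  kd <- if (is(fit, "AttenuationFit")) fit@kd else fit
  if (any(kd <= 0))
    stopValidation("all Kd must be positive; got ",
                   paste(signif(kd, 4), collapse = ", "))
  z <- scene@bathymetry@values
  if (all(is.na(z))) stopData("scene has no bathymetry values")
  out <- vector("list", 3)
  nFloor <- nClip <- 0L
  for (b in 1:3) {
    rw <- scene@bands[[b]]@values
    rb <- rInf[b] + (rw - rInf[b]) * exp(2 * kd[b] * z)
    noSignal <- !is.na(rw) & rw <= rInf[b]
    rb[noSignal] <- rInf[b]
    nFloor <- nFloor + sum(noSignal)
    over <- !is.na(rb) & (rb > 1.5 | rb < 0)
    nClip <- nClip + sum(over)
    rb <- pmin(pmax(rb, 0), 1.5)
    rb[!scene@validMask | is.na(z) | z > maxDepth] <- NA_real_
    out[[b]] <- BandGrid(rb, georef(scene), REFLECTANCE_LABELS[b])
  }
  if (nFloor > 0)
    message(nFloor, " band-cells with R_w <= R_inf set to R_inf")
  if (nClip > 0)
    message(nClip, " band-cells clipped to [0, 1.5] after correction")
  names(out) <- REFLECTANCE_LABELS
  out
}

#' @export
setMethod("deepWaterRInf", "DeepWaterEstimate", function(x) x@rInf)

#' @export
setMethod("attenuationKd", "AttenuationFit", function(x) x@kd)

setMethod("show", "DeepWaterEstimate", function(object) {
  cat(sprintf(
    "DeepWaterEstimate: R_inf = (%.4f, %.4f, %.4f) from %d pixels > %g m\n",
    object@rInf[1], object@rInf[2], object@rInf[3], object@nPixels,
    object@depthThreshold))
})

setMethod("show", "AttenuationFit", function(object) {
  cat(sprintf("AttenuationFit (%s, n = %d):\n", object@transform,
              object@nPoints))
  for (b in 1:3)
    cat(sprintf("  %s: Kd = %.4f m^-1 (slope %.4f, R^2 %.3f)\n",
                REFLECTANCE_LABELS[b], object@kd[b], object@slope[b],
                object@rSquared[b]))
})

#' Write an attenuation-fit diagnostics report
#'
#' CSV with one row per band: slope, intercept, Kd, R^2, n.
#'
#' @param fit an [AttenuationFit-class].
#' @param path output CSV path.
#' @export
writeFitReport <- function(fit, path) {
  df <- data.frame(band = REFLECTANCE_LABELS,
                   slope = fit@slope, intercept = fit@intercept,
                   kd = fit@kd, r_squared = fit@rSquared,
                   n_points = fit@nPoints, transform = fit@transform)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
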