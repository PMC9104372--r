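## Synthetic coastal scene generator. Emulates the structure of a shallow
## coastal study area: a shore-to-offshore depth gradient, a non-vegetated
## sandy calibration strip at 1-5 m, seagrass patches in the 1-11 m habitat
## belt, a deep (> 40 m) zone for deep-water reflectance estimation, and
## surface reflectance produced by the optically-shallow-water forward model
## with additive Gaussian sensor noise.

#' Construct a ScenarioConfig
#'
#' Defaults encode the stated world: 10 m pixels, depth 0-45 m,
#' per-band deep-water reflectance (0.0200, 0.0136, 0.0045), per-band diffuse
#' attenuation (0.0197, 0.0303, 0.1046) m^-1 — the study-area values for
#' Sentinel-2 bands 2/3/4 — and bottom spectra with bright sand
#' (0.12, 0.10, 0.08) over darker seagrass (0.035, 0.045, 0.020).
#'
#' @param nRows,nCols grid size (default 120 x 160).
#' @param pixelSize metres (default 10).
#' @param depthRange c(min, max) metres (default c(0, 45)).
#' @param rInf per-band deep-water reflectance.
#' @param kd per-band diffuse attenuation coefficients (m^-1).
#' @param bottomSpectra 2 x 3 matrix, rows `sand`, `seagrass`.
#' @param patchCount number of seagrass patches (default 6).
#' @param patchFraction target seagrass fraction of the 1-11 m habitat belt
#'   (default 0.2).
#' @param noiseSd additive reflectance noise sd (default 0.002).
#' @param seed integer seed (default 1).
#' @return a [ScenarioConfig-class].
#' @export
ScenarioConfig <- function(nRows = 120, nCols = 160, pixelSize = 10,
                           depthRange = c(0, 45),
                           rInf = c(0.0200, 0.0136, 0.0045),
                           kd = c(0.0197, 0.0303, 0.1046),
                           bottomSpectra = rbind(
                             sand = c(0.12, 0.10, 0.08),
                             seagrass = c(0.035, 0.045, 0.020)),
                           patchCount = 6, patchFraction = 0.2,
                           noiseSd = 0.002, seed = 1) {
  new("ScenarioConfig", nRows = as.integer(nRows), nCols = as.integer(nCols),
      pixelSize = as.numeric(pixelSize), depthRange = as.numeric(depthRange),
      rInf = as.numeric(rInf), kd = as.numeric(kd),
      bottomSpectra = bottomSpectra, patchCount = as.integer(patchCount),
      patchFraction = as.numeric(patchFraction),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Optically-shallow-water forward model
#'
#' Per cell and band, surface reflectance is
#' \deqn{R_w = R_\infty + (R_b - R_\infty)\, e^{-2 K_d Z} + \varepsilon,}
#' \eqn{\varepsilon \sim N(0, \sigma^2)}: the deep-water signal plus the
#' bottom contrast attenuated along the two-way water path, plus sensor
#' noise. Values are clipped below at 0 (and above at 1.5, the container's
#' tolerance for over-unity noise).
#'
#' @param rb list of 3 bottom-reflectance matrices (or `BandGrid`s), order
#'   B2/B3/B4.
#' @param depth `DEPTH` [BandGrid-class].
#' @param rInf,kd per-band deep-water reflectance and attenuation (m^-1).
#' @param noiseSd additive noise sd (0 = deterministic).
#' @param seed seed for the noise draw (ignored when `noiseSd = 0`).
#' @return list of 3 reflectance [BandGrid-class]s named B2_490/B3_560/B4_665.
#' @examples
#' z <- BandGrid(matrix(10, 1, 1), bandLabel = "DEPTH")
#' fw <- forwardModel(list(matrix(0.10, 1, 1), matrix(0.10, 1, 1),
#'                         matrix(0.10, 1, 1)), z,
#'                    rInf = rep(0.02, 3), kd = rep(0.05, 3), noiseSd = 0)
#' gridValues(fw$B2_490)  # 0.02 + 0.08 * exp(-1)
#' @export
forwardModel <- function(rb, depth, rInf, kd, noiseSd = 0, seed = NULL) {
  if (any(kd <= 0)) stopValidation("kd must be positive")
  z <- depth@values
  mats <- lapply(rb, function(b) if (is(b, "BandGrid")) b@values else b)
  if (!all(vapply(mats, function(m) identical(dim(m), dim(z)), logical(1))))
    stopValidation("bottom-reflectance grids and depth must share dimensions")
  withSeed(seed, {
    out <- vector("list", 3)
    for (b in 1:3) {
      rw <- rInf[b] + (mats[[b]] - rInf[b]) * exp(-2 * kd[b] * z)
      if (noiseSd > 0)
        rw <- rw + matrix(stats::rnorm(length(rw), 0, noiseSd),
                          nrow(rw), ncol(rw))
      rw <- pmin(pmax(rw, 0), 1.5)
      out[[b]] <- BandGrid(rw, depth@georef, REFLECTANCE_LABELS[b])
    }
    names(out) <- REFLECTANCE_LABELS
    out
  })
}

## Columns of the sandy calibration strip: where the noise-free depth
## gradient sits inside 1.3-4.7 m, so noisy depths stay near the 1-5 m
## calibration window. Shared by generateScene and generateEpochPair.
calibStripMask <- function(config) {
  gradRow <- seq(config@depthRange[1], config@depthRange[2],
                 length.out = config@nCols)
  calCols <- which(gradRow >= 1.3 & gradRow <= 4.7)
  m <- matrix(FALSE, config@nRows, config@nCols)
  m[, calCols] <- TRUE
  m
}

## Per-band bottom reflectance from a class map. Beyond 40 m the seafloor is
## rendered optically dark (bottom reflectance = R_inf, i.e. zero contrast):
## deep bottoms contribute no measurable signal, which is what makes the
## >40 m zone usable for deep-water reflectance estimation.
DEEP_DARK_DEPTH <- 40

bottomReflectance <- function(config, cls, z) {
  lapply(1:3, function(b) {
    m <- matrix(config@bottomSpectra["sand", b], nrow(cls), ncol(cls))
    m[cls == 1] <- config@bottomSpectra["seagrass", b]
    m[z > DEEP_DARK_DEPTH] <- config@rInf[b]
    m
  })
}

## Separable Gaussian-ish smoothing with edge renormalization; used to give
## the bathymetry a correlated noise field.
smoothMatrix <- function(m, radius = 3) {
  k <- stats::dnorm(seq(-radius, radius), sd = radius / 2)
  k <- k / sum(k)
  pad <- function(v) c(rep(v[1], radius), v, rep(v[length(v)], radius))
  conv1 <- function(v) stats::filter(pad(v), k, sides = 2)[(radius + 1):(radius + length(v))]
  m <- t(apply(m, 1, conv1))   # smooth along rows
  apply(m, 2, conv1)           # then along columns
}

## Grow `target` cells as `nPatches` contiguous blobs over the eligible set.
## Returns a logical matrix. Deterministic given the RNG state.
growPatches <- function(eligible, nPatches, target) {
  sel <- matrix(FALSE, nrow(eligible), ncol(eligible))
  if (target <= 0) return(sel)
  idx <- which(eligible)
  if (length(idx) == 0) return(sel)
  target <- min(target, length(idx))
  nPatches <- max(1L, min(nPatches, target))
  nr <- nrow(eligible)
  seeds <- sample(idx, nPatches)
  sel[seeds] <- TRUE
  frontier <- seeds
  nSel <- nPatches
  neighbours <- function(i) {
    r <- (i - 1L) %% nr + 1L
    cands <- c(if (r > 1L) i - 1L, if (r < nr) i + 1L, i - nr, i + nr)
    cands[cands >= 1L & cands <= length(eligible)]
  }
  while (nSel < target && length(frontier) > 0) {
    grow <- frontier[sample.int(length(frontier), 1L)]
    nb <- neighbours(grow)
    nb <- nb[eligible[nb] & !sel[nb]]
    if (length(nb) == 0) {
      frontier <- frontier[frontier != grow]
      next
    }
    add <- nb[sample.int(length(nb), 1L)]
    sel[add] <- TRUE
    frontier <- c(frontier, add)
    nSel <- nSel + 1L
  }
  if (nSel < target) {  # eligible set fragmented: top up anywhere eligible
    rest <- setdiff(which(eligible), which(sel))
    sel[sample(rest, target - nSel)] <- TRUE
  }
  sel
}

#' Generate a synthetic coastal scene
#'
#' Builds bathymetry as a smooth shore-to-offshore gradient spanning the
#' configured depth range plus low-amplitude spatially correlated noise; a
#' contiguous non-vegetated sandy calibration strip inside 1-5 m depth
#' (returned as a polygon); seagrass patches in the 1-11 m habitat belt; a
#' deep (> 40 m) zone; surface reflectance via [forwardModel()]; and labelled
#' samples drawn from the truth map. Deterministic under the config seed.
#'
#' @param config a [ScenarioConfig-class].
#' @param nSamples number of labelled samples to draw (default 600, balanced
#'   between classes, restricted to cells shallower than 20 m so they survive
#'   the standard depth clip).
#' @return list with elements `scene` ([Scene-class]), `truth`
#'   ([SceneTruth-class]), `samples` ([LabeledSamples-class], features taken
#'   from the surface-reflectance bands) and `calibrationZone` (polygon
#'   feature for [fitAttenuation()]).
#' @export
generateScene <- function(config, nSamples = 600) {
  validObject(config)
  if (config@depthRange[2] <= 40)
    stopValidation("depthRange maximum must exceed 40 m so a deep-water ",
                   "zone exists; widen the range or skip deep-water ",
                   "estimation")
  nr <- config@nRows; nc <- config@nCols; s <- config@pixelSize
  g <- GridGeoref(0, nr * s, s, nr, nc, "local")
  withSeed(config@seed, {
    ## bathymetry: linear west-east gradient + smoothed noise, clamped
    grad <- matrix(rep(seq(config@depthRange[1], config@depthRange[2],
                           length.out = nc), each = nr), nr, nc)
    noise <- smoothMatrix(matrix(stats::rnorm(nr * nc, 0, 1.5), nr, nc))
    z <- pmin(pmax(grad + noise, config@depthRange[1]), config@depthRange[2])
    ## calibration strip: forced to bare sand with depths held in 1-5 m
    calib <- calibStripMask(config)
    if (!any(calib))
      stopValidation("depthRange leaves no room for a 1-5 m sandy ",
                     "calibration strip")
    calCols <- which(calib[1, ])
    z[calib] <- pmin(pmax(z[calib], 1), 5)
    ## seagrass patches in the 1-11 m belt, outside the calibration strip
    belt <- z >= 1 & z <= 11 & !calib
    target <- roundHalfAwayFromZero(config@patchFraction * sum(belt))
    classVals <- matrix(0, nr, nc)
    classVals[growPatches(belt, config@patchCount, target)] <- 1
    depthGrid <- BandGrid(z, g, "DEPTH")
    classGrid <- BandGrid(classVals, g, "CLASS")
    ## bottom reflectance per band from the class map
    rb <- bottomReflectance(config, classVals, z)
    bands <- forwardModel(rb, depthGrid, config@rInf, config@kd,
                          config@noiseSd,
                          seed = childSeed(config@seed, 101L))
    scene <- Scene(bands[[1]], bands[[2]], bands[[3]], depthGrid)
    truth <- new("SceneTruth", classMap = classGrid, bathymetry = depthGrid,
                 config = config)
    ## calibration polygon in map coordinates (covers the full strip)
    xmin <- (min(calCols) - 1) * s; xmax <- max(calCols) * s
    zone <- rectangleFeature(xmin, xmax, 0, nr * s, class = "other")
    ## balanced labelled samples from cells shallower than 20 m
    usable <- scene@validMask & z <= 20
    samples <- drawSamples(scene, classVals, usable, nSamples,
                           seed = childSeed(config@seed, 202L))
    list(scene = scene, truth = truth, samples = samples,
         calibrationZone = zone)
  })
}

## Draw a balanced labelled sample set from the truth map.
drawSamples <- function(scene, classVals, usable, nSamples, seed) {
  withSeed(seed, {
    perClass <- roundHalfAwayFromZero(nSamples / 2)
    pick <- function(code) {
      pool <- which(usable & classVals == code)
      sample(pool, min(perClass, length(pool)))
    }
    idx <- c(pick(1), pick(0))
    nr <- nrow(classVals)
    loc <- cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
    feats <- matrix(vapply(scene@bands, function(b) b@values[idx],
                           numeric(length(idx))), ncol = 3)
    labs <- factor(ifelse(classVals[idx] == 1, "seagrass", "other"),
                   levels = c("other", "seagrass"))
    new("LabeledSamples", features = unname(feats), labels = labs,
        source = rep("point", length(idx)), location = loc)
  })
}

#' Render a scene (and samples) from a truth map
#'
#' Produces the surface-reflectance scene a sensor would observe over a given
#' truth: per-band bottom reflectance from the class map and the configured
#' bottom spectra, pushed through [forwardModel()] with the configured noise.
#' Used to image the second epoch of a [generateEpochPair()] truth pair.
#'
#' @param truth a [SceneTruth-class].
#' @param nSamples labelled samples to draw from the truth (default 600).
#' @param seed seed for noise + sample draws (default derived from the
#'   config seed, offset so it differs from the epoch-1 scene's noise).
#' @return list with `scene` and `samples`.
#' @export
sceneFromTruth <- function(truth, nSamples = 600,
                           seed = childSeed(truth@config@seed, 404L)) {
  config <- truth@config
  cls <- truth@classMap@values
  z <- truth@bathymetry@values
  rb <- bottomReflectance(config, cls, z)
  bands <- forwardModel(rb, truth@bathymetry, config@rInf, config@kd,
                        config@noiseSd, seed = childSeed(seed, 1L))
  scene <- Scene(bands[[1]], bands[[2]], bands[[3]], truth@bathymetry)
  usable <- scene@validMask & !is.na(z) & z <= 20
  samples <- drawSamples(scene, cls, usable, nSamples,
                         seed = childSeed(seed, 2L))
  list(scene = scene, samples = samples)
}

#' Generate a two-epoch truth pair with planted change
#'
#' Derives an epoch-2 truth from an epoch-1 truth by removing
#' `roundHalfAwayFromZero(lossFraction * n1)` seagrass cells as contiguous
#' blocks and adding `roundHalfAwayFromZero(gainFraction * n1)` new seagrass
#' cells elsewhere in the habitat belt (`n1` = epoch-1 seagrass count), so
#' stable/loss/gain areas are known exactly.
#'
#' @param config a [ScenarioConfig-class] (epoch 1 is generated from it).
#' @param lossFraction,gainFraction fractions in \[0, 1\] of the epoch-1
#'   seagrass count.
#' @param seed seed for the change draw (default derived from the config
#'   seed).
#' @return list with `t1`, `t2` ([SceneTruth-class]) and `planted`, a named
#'   integer vector of the exact stable/loss/gain cell counts.
#' @export
generateEpochPair <- function(config, lossFraction, gainFraction,
                              seed = childSeed(config@seed, 303L)) {
  if (lossFraction < 0 || lossFraction > 1 || gainFraction < 0 ||
      gainFraction > 1)
    stopValidation("lossFraction and gainFraction must lie in [0, 1]")
  t1 <- generateScene(config, nSamples = 10)$truth
  cls1 <- t1@classMap@values
  z <- t1@bathymetry@values
  n1 <- sum(cls1 == 1)
  nLoss <- min(roundHalfAwayFromZero(lossFraction * n1), n1)
  nGain <- roundHalfAwayFromZero(gainFraction * n1)
  withSeed(seed, {
    lossSel <- growPatches(cls1 == 1, max(1L, config@patchCount %/% 2L), nLoss)
    gainElig <- cls1 == 0 & z >= 1 & z <= 11 & !calibStripMask(config)
    nGain <- min(nGain, sum(gainElig))
    gainSel <- growPatches(gainElig, max(1L, config@patchCount %/% 2L), nGain)
    cls2 <- cls1
    cls2[lossSel] <- 0
    cls2[gainSel] <- 1
    t2 <- new("SceneTruth",
              classMap = BandGrid(cls2, t1@classMap@georef, "CLASS"),
              bathymetry = t1@bathymetry, config = config)
    list(t1 = t1, t2 = t2,
         planted = c(stable = n1 - as.integer(sum(lossSel)),
                     loss = as.integer(sum(lossSel)),
                     gain = as.integer(sum(gainSel))))
  })
}
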