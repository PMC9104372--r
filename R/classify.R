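## Supervised two-class benthic classification on bottom-reflectance
## composites. The Gaussian maximum-likelihood classifier is implemented from
## first principles; margin/ensemble alternatives are provided behind the
## same contract (see classify-alt.R).

#' Extract labelled samples from class-labelled vector features
#'
#' One sample per valid pixel whose centre falls inside a labelled polygon
#' (or at a labelled point), with features taken from the three reflectance
#' grids. Label conflicts between overlapping features are resolved
#' first-feature-wins, with a warning giving the conflict count. Points
#' landing on nodata pixels are skipped with a warning.
#'
#' @param features feature list with `class` properties (`"seagrass"` /
#'   `"other"`), see [readVectorFeatures()].
#' @param grids list of 3 reflectance [BandGrid-class]s on one georef.
#' @return a [LabeledSamples-class].
#' @export
extractSamples <- function(features, grids) {
  g <- grids[[1]]@georef
  valid <- !(is.na(grids[[1]]@values) | is.na(grids[[2]]@values) |
               is.na(grids[[3]]@values))
  lab <- matrix(NA_character_, g@nRows, g@nCols)
  src <- matrix(NA_character_, g@nRows, g@nCols)
  conflicts <- 0L
  skippedPoints <- 0L
  ctr <- pixelCenterGrid(g)
  for (f in features) {
    cls <- f$class %||% "other"
    if (f$type == "Point") {
      cc <- floor((f$coords[1] - g@originX) / g@pixelSize) + 1
      rr <- floor((g@originY - f$coords[2]) / g@pixelSize) + 1
      if (rr < 1 || rr > g@nRows || cc < 1 || cc > g@nCols || !valid[rr, cc]) {
        skippedPoints <- skippedPoints + 1L
        next
      }
      if (!is.na(lab[rr, cc])) {
        if (lab[rr, cc] != cls) conflicts <- conflicts + 1L
        next
      }
      lab[rr, cc] <- cls; src[rr, cc] <- "point"
    } else {
      inside <- matrix(pointInPolygon(as.vector(ctr$x), as.vector(ctr$y),
                                      f$rings), g@nRows, g@nCols)
      hit <- inside & valid
      clash <- hit & !is.na(lab) & lab != cls
      conflicts <- conflicts + sum(clash)
      take <- hit & is.na(lab)
      lab[take] <- cls; src[take] <- "polygon"
    }
  }
  if (skippedPoints > 0)
    warning(skippedPoints, " point(s) on nodata pixels skipped")
  if (conflicts > 0)
    warning(conflicts,
            " label conflict(s) resolved first-feature-wins")
  idx <- which(!is.na(lab))
  if (length(idx) == 0) stopData("no labelled features overlap valid pixels")
  nr <- g@nRows
  loc <- cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
  feats <- vapply(grids, function(b) b@values[idx],
                  numeric(length(idx)))
  feats <- matrix(feats, ncol = 3)
  new("LabeledSamples", features = unname(feats),
      labels = factor(lab[idx], levels = c("other", "seagrass")),
      source = src[idx], location = loc)
}

#' Re-extract sample features from other grids at the same locations
#'
#' Used to carry truth-derived sample locations onto a corrected
#' bottom-reflectance composite. Samples falling on nodata cells are dropped
#' with a message.
#'
#' @param samples a [LabeledSamples-class].
#' @param grids list of 3 reflectance [BandGrid-class]s.
#' @return a [LabeledSamples-class].
#' @export
samplesFromGrids <- function(samples, grids) {
  idx <- samples@location
  feats <- matrix(vapply(grids, function(b) b@values[idx],
                         numeric(nrow(idx))), ncol = 3)
  ok <- rowSums(!is.finite(feats)) == 0
  if (sum(!ok) > 0)
    message(sum(!ok), " samples on nodata cells dropped")
  if (!any(ok)) stopData("no samples fall on valid cells")
  new("LabeledSamples", features = unname(feats[ok, , drop = FALSE]),
      labels = samples@labels[ok], source = samples@source[ok],
      location = samples@location[ok, , drop = FALSE])
}

#' Stratified train/test split
#'
#' Per class, `roundHalfAwayFromZero(trainFraction * n_class)` samples go to
#' training; the rest form the assessment set. Deterministic under `seed`.
#' The default 0.4 follows the common 40/60 training/assessment convention.
#'
#' @param samples a [LabeledSamples-class] with at least 2 samples per class.
#' @param trainFraction fraction in (0, 1) (default 0.4).
#' @param seed integer seed.
#' @return a [SampleSplit-class].
#' @export
splitSamples <- function(samples, trainFraction = 0.4, seed = 1) {
  counts <- table(samples@labels)
  if (any(counts < 2))
    stopValidation("each class needs at least 2 samples; got ",
                   paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", "))
  withSeed(seed, {
    trainIdx <- integer(0)
    for (cl in levels(samples@labels)) {
      idx <- which(samples@labels == cl)
      nTrain <- roundHalfAwayFromZero(trainFraction * length(idx))
      nTrain <- min(max(nTrain, 1L), length(idx) - 1L)
      trainIdx <- c(trainIdx, sample(idx, nTrain))
    }
    subsetSamples <- function(i)
      new("LabeledSamples",
          features = samples@features[i, , drop = FALSE],
          labels = samples@labels[i], source = samples@source[i],
          location = samples@location[i, , drop = FALSE])
    new("SampleSplit", train = subsetSamples(sort(trainIdx)),
        test = subsetSamples(setdiff(seq_along(samples@labels), trainIdx)),
        trainFraction = trainFraction, seed = as.integer(seed))
  })
}

#' Train a Gaussian maximum-likelihood classifier
#'
#' Per class: sample mean, sample covariance (denominator n - 1) with
#' `regularizationEpsilon * I` added, and priors equal to class frequencies
#' (or equal, a common GIS default).
#'
#' @param train a [LabeledSamples-class] with at least 4 samples per class.
#' @param regularizationEpsilon ridge added to covariance diagonals
#'   (default 1e-8).
#' @param priors `"frequency"` (default) or `"equal"`.
#' @return an [MLCModel-class].
#' @export
trainMLC <- function(train, regularizationEpsilon = 1e-8,
                     priors = c("frequency", "equal")) {
  priors <- match.arg(priors)
  counts <- table(train@labels)
  if (any(counts < 4))
    stopValidation("each class needs at least 4 training samples to ",
                   "estimate a 3x3 covariance; got ",
                   paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", "))
  classes <- levels(train@labels)
  means <- matrix(0, length(classes), 3,
                  dimnames = list(classes, REFLECTANCE_LABELS))
  covs <- vector("list", length(classes)); names(covs) <- classes
  for (cl in classes) {
    X <- train@features[train@labels == cl, , drop = FALSE]
    means[cl, ] <- colMeans(X)
    S <- stats::cov(X) + diag(regularizationEpsilon, 3)
    if (inherits(try(chol(S), silent = TRUE), "try-error"))
      stopData("covariance of class '", cl, "' is singular even after ",
               "regularization; increase regularizationEpsilon")
    covs[[cl]] <- S
  }
  p <- if (priors == "equal") rep(1 / length(classes), length(classes))
       else as.numeric(counts) / sum(counts)
  names(p) <- classes
  new("MLCModel", classes = classes, means = means, covariances = covs,
      priors = p, regularizationEpsilon = regularizationEpsilon)
}

#' Per-class Gaussian discriminants
#'
#' \eqn{g_i(x) = -\frac12 \log|\Sigma_i| - \frac12 (x-\mu_i)^T \Sigma_i^{-1}
#' (x-\mu_i) + \log p_i} for each row of `X`.
#'
#' @param model an [MLCModel-class].
#' @param X n x 3 feature matrix.
#' @return n x k matrix of discriminant values (columns in `model@classes`
#'   order).
#' @export
mlcDiscriminants <- function(model, X) {
  X <- matrix(X, ncol = 3)
  out <- matrix(NA_real_, nrow(X), length(model@classes),
                dimnames = list(NULL, model@classes))
  for (cl in model@classes) {
    S <- model@covariances[[cl]]
    ch <- chol(S)
    logDet <- 2 * sum(log(diag(ch)))
    D <- sweep(X, 2, model@means[cl, ])
    ## Mahalanobis via triangular solve: ||L^-T d||^2
    q <- colSums(backsolve(ch, t(D), transpose = TRUE)^2)
    out[, cl] <- unname(-0.5 * logDet - 0.5 * q +
                          log(model@priors[[cl]]))
  }
  out
}

#' Classify a bottom-reflectance composite with an MLC model
#'
#' Each valid pixel gets the class with the highest Gaussian discriminant.
#' Exact ties are broken toward `other` — conservative with respect to
#' seagrass area claims. Nodata propagates.
#'
#' @param model an [MLCModel-class].
#' @param grids list of 3 reflectance [BandGrid-class]s.
#' @return a `CLASS` [BandGrid-class] (1 = seagrass, 0 = other).
#' @export
predictMLC <- function(model, grids) {
  valid <- !(is.na(grids[[1]]@values) | is.na(grids[[2]]@values) |
               is.na(grids[[3]]@values))
  idx <- which(valid)
  out <- matrix(NA_real_, nrow(valid), ncol(valid))
  if (length(idx)) {
    X <- sapply(grids, function(b) b@values[idx])
    gdisc <- mlcDiscriminants(model, X)
    ## seagrass only on a strict win: ties fall to "other"
    out[idx] <- as.numeric(gdisc[, "seagrass"] > gdisc[, "other"])
  }
  BandGrid(out, grids[[1]]@georef, "CLASS")
}

setMethod("show", "MLCModel", function(object) {
  cat("MLCModel (Gaussian maximum likelihood), classes:",
      paste(object@classes, collapse = ", "), "\n")
  for (cl in object@classes)
    cat(sprintf("  %s: prior %.3f, mean (%s)\n", cl, object@priors[[cl]],
                paste(sprintf("%.4f", object@means[cl, ]), collapse = ", ")))
})

#' @export
setMethod("sampleFeatures", "LabeledSamples", function(x) x@features)

#' @export
setMethod("sampleLabels", "LabeledSamples", function(x) x@labels)

#' @export
setMethod("sampleLocations", "LabeledSamples", function(x) x@location)

setMethod("show", "LabeledSamples", function(object) {
  tab <- table(object@labels)
  cat(sprintf("LabeledSamples: %d samples (%s)\n", length(object@labels),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})
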