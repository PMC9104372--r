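## Alternative classifiers behind the uniform contract: an RBF-kernel
## support vector machine trained with simplified SMO, and a bagged CART
## ensemble with random feature subsets ("random trees"). Both are compact
## from-scratch implementations: no SVM or tree package ships with this
## toolchain, and their internals are standard, not a contribution of this
## package.

## ---- CART (Gini) -----------------------------------------------------------

## Best binary axis-aligned split over a feature subset. Returns NULL when no
## split reduces impurity.
bestSplit <- function(X, y, featSubset) {
  n <- length(y)
  best <- NULL
  bestScore <- Inf
  for (f in featSubset) {
    o <- order(X[, f])
    xs <- X[o, f]; ys <- y[o]
    distinct <- which(diff(xs) > 0)
    if (length(distinct) == 0) next
    posLeft <- cumsum(ys)[distinct]
    nLeft <- distinct
    nRight <- n - nLeft
    posRight <- sum(y) - posLeft
    giniL <- 1 - (posLeft / nLeft)^2 - (1 - posLeft / nLeft)^2
    giniR <- 1 - (posRight / nRight)^2 - (1 - posRight / nRight)^2
    score <- (nLeft * giniL + nRight * giniR) / n
    k <- which.min(score)
    if (score[k] < bestScore - 1e-12) {
      bestScore <- score[k]
      best <- list(feature = f,
                   threshold = (xs[distinct[k]] + xs[distinct[k] + 1]) / 2,
                   score = score[k])
    }
  }
  best
}

buildTree <- function(X, y, depth, maxDepth, minSplit, mtry) {
  n <- length(y)
  pos <- sum(y)
  if (depth >= maxDepth || n < minSplit || pos == 0 || pos == n)
    return(list(leaf = TRUE, prob = pos / n))
  feats <- sample.int(ncol(X), mtry)
  sp <- bestSplit(X, y, feats)
  if (is.null(sp)) {
    sp <- bestSplit(X, y, seq_len(ncol(X)))  # fall back to all features
    if (is.null(sp)) return(list(leaf = TRUE, prob = pos / n))
  }
  left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = buildTree(X[left, , drop = FALSE], y[left], depth + 1,
                        maxDepth, minSplit, mtry),
       right = buildTree(X[!left, , drop = FALSE], y[!left], depth + 1,
                         maxDepth, minSplit, mtry))
}

predictTree <- function(tree, X) {
  out <- numeric(nrow(X))
  recurse <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) {
      out[idx] <<- node$prob
      return()
    }
    left <- X[idx, node$feature] <= node$threshold
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(tree, seq_len(nrow(X)))
  out
}

trainRandomTrees <- function(X, y, nTrees = 100, mtry = 2, maxDepth = 12,
                             minSplit = 5, sampleSize = NULL) {
  n <- nrow(X)
  if (is.null(sampleSize)) sampleSize <- min(n, 2000L)
  lapply(seq_len(nTrees), function(i) {
    idx <- sample.int(n, sampleSize, replace = TRUE)
    buildTree(X[idx, , drop = FALSE], y[idx], 0L, maxDepth, minSplit, mtry)
  })
}

predictRandomTrees <- function(forest, X) {
  votes <- rowMeans(vapply(forest, function(tr) predictTree(tr, X),
                           numeric(nrow(X))))
  as.numeric(votes > 0.5)  # exact tie falls to "other"
}

## ---- SVM (RBF kernel, simplified SMO) --------------------------------------

rbfKernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

trainSVM <- function(X, y01, C = 10, gamma = NULL, tol = 1e-3,
                     maxPasses = 8, maxIter = 20000) {
  ## standardize features; gamma defaults to 1 / (p * var) on the scaled data
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  if (is.null(gamma)) gamma <- 1 / (ncol(Xs) * max(mean(Xs^2) - mean(Xs)^2,
                                                   1e-12))
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(Xs)
  K <- rbfKernel(Xs, Xs, gamma)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L; iter <- 0L
  fcache <- function(i) sum(alpha * y * K[, i]) + b
  while (passes < maxPasses && iter < maxIter) {
    changed <- 0L
    for (i in seq_len(n)) {
      iter <- iter + 1L
      Ei <- fcache(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L); if (j >= i) j <- j + 1L
        Ej <- fcache(j) - y[j]
        ai <- alpha[i]; aj <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj - ai); H <- min(C, C + aj - ai)
        } else {
          L <- max(0, ai + aj - C); H <- min(C, ai + aj)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        ajNew <- min(max(aj - y[j] * (Ei - Ej) / eta, L), H)
        if (abs(ajNew - aj) < 1e-7) next
        aiNew <- ai + y[i] * y[j] * (aj - ajNew)
        b1 <- b - Ei - y[i] * (aiNew - ai) * K[i, i] -
          y[j] * (ajNew - aj) * K[i, j]
        b2 <- b - Ej - y[i] * (aiNew - ai) * K[i, j] -
          y[j] * (ajNew - aj) * K[j, j]
        alpha[i] <- aiNew; alpha[j] <- ajNew
        b <- if (aiNew > 0 && aiNew < C) b1
             else if (ajNew > 0 && ajNew < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  sv <- which(alpha > 1e-8)
  list(X = Xs[sv, , drop = FALSE], alphaY = alpha[sv] * y[sv], b = b,
       gamma = gamma, center = mu, scale = sdv)
}

predictSVM <- function(model, X, blockSize = 5000L) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  n <- nrow(Xs)
  out <- numeric(n)
  for (start in seq(1L, n, by = blockSize)) {
    idx <- start:min(start + blockSize - 1L, n)
    f <- rbfKernel(Xs[idx, , drop = FALSE], model$X, model$gamma) %*%
      model$alphaY + model$b
    out[idx] <- as.numeric(f > 0)  # decision boundary itself -> "other"
  }
  out
}

## ---- uniform contract ------------------------------------------------------

#' Train and apply an alternative classifier
#'
#' Fits a support vector machine (RBF kernel, simplified SMO) or a bagged
#' random-trees ensemble (CART with Gini impurity, random feature subsets per
#' split) on the training samples and classifies every valid pixel of the
#' grids. Deterministic under `seed`. Hyperparameters are reported via
#' `message()` so every run is auditable.
#'
#' Defaults (`svm`: C = 10, RBF gamma scaled to feature variance;
#' `random_trees`: 100 trees, mtry 2, max depth 12, training subsample cap
#' 2000) are pragmatic choices, overridable through `hyperparams`.
#'
#' @param train a [LabeledSamples-class].
#' @param grids list of 3 reflectance [BandGrid-class]s.
#' @param method `"svm"` or `"random_trees"`.
#' @param hyperparams named list overriding defaults (`svm`: `C`, `gamma`;
#'   `random_trees`: `nTrees`, `mtry`, `maxDepth`, `minSplit`,
#'   `sampleSize`).
#' @param seed integer seed.
#' @return a `CLASS` [BandGrid-class] (1 = seagrass, 0 = other).
#' @export
trainPredictAlt <- function(train, grids, method = c("svm", "random_trees"),
                            hyperparams = list(), seed = 1) {
  method <- tryCatch(match.arg(method),
                     error = function(e) stopValidation(
                       "unknown method '", paste(method, collapse = ","),
                       "'; use svm or random_trees"))
  X <- train@features
  y <- as.numeric(train@labels == "seagrass")
  valid <- !(is.na(grids[[1]]@values) | is.na(grids[[2]]@values) |
               is.na(grids[[3]]@values))
  idx <- which(valid)
  Xpix <- sapply(grids, function(b) b@values[idx])
  out <- matrix(NA_real_, nrow(valid), ncol(valid))
  withSeed(seed, {
    if (method == "svm") {
      hp <- utils::modifyList(list(C = 10, gamma = NULL, maxTrain = 800L),
                              hyperparams)
      if (nrow(X) > hp$maxTrain) {  # stratified cap keeps SMO tractable
        keep <- unlist(lapply(split(seq_len(nrow(X)), train@labels),
                              function(i) sample(i, min(length(i),
                                                        hp$maxTrain %/% 2))))
        X <- X[keep, , drop = FALSE]; y <- y[keep]
      }
      model <- trainSVM(X, y, C = hp$C, gamma = hp$gamma)
      message(sprintf("svm: C=%g gamma=%.4g support vectors=%d",
                      hp$C, model$gamma, nrow(model$X)))
      out[idx] <- predictSVM(model, Xpix)
    } else {
      hp <- utils::modifyList(list(nTrees = 100L, mtry = 2L, maxDepth = 12L,
                                   minSplit = 5L, sampleSize = NULL),
                              hyperparams)
      forest <- trainRandomTrees(X, y, hp$nTrees, hp$mtry, hp$maxDepth,
                                 hp$minSplit, hp$sampleSize)
      message(sprintf("random_trees: nTrees=%d mtry=%d maxDepth=%d minSplit=%d",
                      hp$nTrees, hp$mtry, hp$maxDepth, hp$minSplit))
      out[idx] <- predictRandomTrees(forest, Xpix)
    }
  })
  BandGrid(out, grids[[1]]@georef, "CLASS")
}
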