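## shared small composite: noiseless corrected scene + truth
classifyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tinyConfig(seed = 13, noiseSd = 0)
      gen <- generateScene(cfg, nSamples = 200)
      rb <- suppressMessages(correctWaterColumn(gen$scene, cfg@rInf, cfg@kd))
      cache <<- list(cfg = cfg, gen = gen, rb = rb,
                     samples = suppressMessages(
                       samplesFromGrids(gen$samples, rb)))
    }
    cache
  }
})

test_that("sample extraction follows the pixel-centre rule", {
  g <- GridGeoref(0, 40, 10, nRows = 4, nCols = 4)
  vals <- matrix(seq(0.01, 0.16, by = 0.01), 4, 4)
  grids <- list(BandGrid(vals, g, "B2_490"), BandGrid(vals, g, "B3_560"),
                BandGrid(vals, g, "B4_665"))

  ## polygon covering the 6 pixel centres of rows 1-2, columns 1-3
  poly <- rectangleFeature(0, 30, 20, 40, class = "seagrass")
  s <- extractSamples(list(poly), grids)
  expect_equal(length(sampleLabels(s)), 6)
  expect_true(all(sampleLabels(s) == "seagrass"))

  ## point on a nodata pixel is skipped with a warning
  vals2 <- vals; vals2[1, 1] <- NA
  grids2 <- list(BandGrid(vals2, g, "B2_490"), BandGrid(vals2, g, "B3_560"),
                 BandGrid(vals2, g, "B4_665"))
  pt <- list(type = "Point", coords = c(5, 35), class = "other")
  ptOk <- list(type = "Point", coords = c(15, 35), class = "other")
  expect_warning(s2 <- extractSamples(list(pt, ptOk), grids2), "nodata")
  expect_equal(length(sampleLabels(s2)), 1)

  ## overlapping polygons of different classes: first feature wins and the
  ## conflict count equals the brute-force overlap
  polyA <- rectangleFeature(0, 30, 20, 40, class = "seagrass")
  polyB <- rectangleFeature(10, 40, 20, 40, class = "other")
  ctr <- pixelCenters(g)
  overlap <- sum(pointInPolygon(ctr[, "x"], ctr[, "y"], polyA$rings) &
                   pointInPolygon(ctr[, "x"], ctr[, "y"], polyB$rings))
  expect_warning(s3 <- extractSamples(list(polyA, polyB), grids),
                 paste0(overlap, " label conflict"))
  expect_equal(sum(sampleLabels(s3) == "seagrass"), 6)  # A kept where both

  expect_error(extractSamples(list(rectangleFeature(500, 600, 500, 600)),
                              grids), "overlap")
})

test_that("stratified splitting is exact, seeded and rounds as documented", {
  feats <- matrix(runif(600), 200, 3)
  labs <- factor(rep(c("other", "seagrass"), each = 100),
                 levels = c("other", "seagrass"))
  s <- new("LabeledSamples", features = feats, labels = labs,
           source = rep("point", 200),
           location = cbind(rep(1:20, 10), rep(1:10, each = 20)))
  sp <- splitSamples(s, 0.4, seed = 5)
  expect_equal(as.vector(table(sampleLabels(sp@train))), c(40, 40))
  expect_equal(as.vector(table(sampleLabels(sp@test))), c(60, 60))
  ## disjoint and exhaustive
  expect_equal(length(sampleLabels(sp@train)) + length(sampleLabels(sp@test)),
               200)
  both <- rbind(sampleFeatures(sp@train), sampleFeatures(sp@test))
  expect_equal(nrow(unique(both)), 200)

  sp2 <- splitSamples(s, 0.4, seed = 5)
  expect_identical(sampleFeatures(sp2@train), sampleFeatures(sp@train))

  ## 7 samples per class at 0.4: rha(2.8) = 3 to training
  s7 <- new("LabeledSamples", features = matrix(runif(42), 14, 3),
            labels = factor(rep(c("other", "seagrass"), each = 7),
                            levels = c("other", "seagrass")),
            source = rep("point", 14), location = cbind(1:14, 1:14))
  sp7 <- splitSamples(s7, 0.4, seed = 1)
  expect_equal(as.vector(table(sampleLabels(sp7@train))), c(3, 3))

  sBad <- new("LabeledSamples", features = matrix(runif(9), 3, 3),
              labels = factor(c("other", "other", "seagrass"),
                              levels = c("other", "seagrass")),
              source = rep("point", 3), location = cbind(1:3, 1:3))
  expect_error(splitSamples(sBad), "at least 2")
})

test_that("MLC estimates match closed forms and the discriminant oracle", {
  set.seed(42)
  n <- 60
  X <- rbind(matrix(rnorm(n * 3, 0.10, 0.01), n, 3),
             matrix(rnorm(n * 3, 0.03, 0.01), n, 3))
  X <- pmax(X, 0)
  labs <- factor(rep(c("other", "seagrass"), each = n),
                 levels = c("other", "seagrass"))
  s <- new("LabeledSamples", features = X, labels = labs,
           source = rep("point", 2 * n), location = cbind(1:(2 * n), 1))
  m <- trainMLC(s)
  expect_equal(m@means["other", ], colMeans(X[1:n, ]), ignore_attr = TRUE)
  expect_equal(m@priors, c(other = 0.5, seagrass = 0.5))

  ## hand-computed discriminant at a held-out vector
  x0 <- c(0.08, 0.09, 0.1)
  S <- m@covariances[["other"]]
  gOracle <- -0.5 * log(det(S)) -
    0.5 * t(x0 - m@means["other", ]) %*% solve(S) %*%
      (x0 - m@means["other", ]) + log(m@priors[["other"]])
  expect_equal(unname(mlcDiscriminants(m, x0)[1, "other"]),
               as.numeric(gOracle), tolerance = 1e-10)

  ## degenerate spread: identical samples -> covariance = epsilon I
  sameX <- matrix(rep(c(0.1, 0.2, 0.3), each = 10), 10, 3)
  sDeg <- new("LabeledSamples",
              features = rbind(sameX, matrix(runif(30), 10, 3)),
              labels = factor(rep(c("other", "seagrass"), each = 10),
                              levels = c("other", "seagrass")),
              source = rep("point", 20), location = cbind(1:20, 1))
  mDeg <- trainMLC(sDeg, regularizationEpsilon = 1e-8)
  expect_equal(mDeg@covariances[["other"]], diag(1e-8, 3),
               tolerance = 1e-20, ignore_attr = TRUE)

  expect_error(trainMLC(s, priors = "bogus"), "arg")
})

test_that("MLC agrees with an independent quadratic-discriminant fit", {
  skip_if_not_installed("MASS")
  set.seed(7)
  n <- 80
  X <- rbind(matrix(rnorm(n * 3, 0.10, 0.015), n, 3),
             matrix(rnorm(n * 3, 0.05, 0.010), n, 3))
  X <- pmax(pmin(X, 1.4), 0)
  labs <- factor(rep(c("other", "seagrass"), each = n),
                 levels = c("other", "seagrass"))
  s <- new("LabeledSamples", features = X, labels = labs,
           source = rep("point", 2 * n), location = cbind(1:(2 * n), 1))
  m <- trainMLC(s)
  Xnew <- matrix(runif(300, 0, 0.15), 100, 3)
  mine <- apply(mlcDiscriminants(m, Xnew), 1, function(r)
    colnames(mlcDiscriminants(m, Xnew))[which.max(r)])
  qd <- MASS::qda(X, grouping = labs)
  ref <- as.character(stats::predict(qd, Xnew)$class)
  expect_gte(mean(mine == ref), 0.99)
})

test_that("MLC prediction applies the tie rule and recovers clean scenes", {
  f <- classifyFixture()
  sp <- splitSamples(f$samples, 0.4, seed = 3)
  model <- trainMLC(sp@train)

  ## pixel at a class mean with equal covariance/priors -> that class
  mEq <- new("MLCModel", classes = c("other", "seagrass"),
             means = rbind(other = c(0.1, 0.1, 0.1),
                           seagrass = c(0.03, 0.04, 0.02)),
             covariances = list(other = diag(1e-4, 3),
                                seagrass = diag(1e-4, 3)),
             priors = c(other = 0.5, seagrass = 0.5),
             regularizationEpsilon = 0)
  g1 <- GridGeoref(nRows = 1, nCols = 2)
  mk <- function(v) BandGrid(matrix(v, 1, 2), g1, "B2_490")
  grids <- list(
    BandGrid(matrix(c(0.03, 0.1), 1, 2), g1, "B2_490"),
    BandGrid(matrix(c(0.04, 0.1), 1, 2), g1, "B3_560"),
    BandGrid(matrix(c(0.02, 0.1), 1, 2), g1, "B4_665"))
  pred <- predictMLC(mEq, grids)
  expect_equal(gridValues(pred)[1, ], c(1, 0))

  ## identical class models -> every pixel ties -> "other"
  mTie <- mEq
  mTie@means["seagrass", ] <- mTie@means["other", ]
  predTie <- predictMLC(mTie, grids)
  expect_true(all(gridValues(predTie) == 0))

  ## noiseless separable scene: exact truth recovery
  pred <- predictMLC(model, f$rb)
  expect_equal(pixelAccuracy(pred, gridValues(classMap(f$gen$truth))), 1)
  ## nodata propagates
  expect_identical(is.na(gridValues(pred)), is.na(gridValues(f$rb[[1]])))
})

test_that("MLC labels are invariant under affine feature maps", {
  f <- classifyFixture()
  sp <- splitSamples(f$samples, 0.4, seed = 3)
  base <- predictMLC(trainMLC(sp@train), f$rb)
  set.seed(99)
  for (rep in 1:3) {
    ## nonnegative, diagonally dominant map keeps reflectance in range
    A <- matrix(runif(9, 0, 0.2), 3, 3) + diag(runif(3, 0.5, 1.5))
    b <- runif(3, 0, 0.1)
    tr <- sp@train
    tr@features <- sweep(tr@features %*% t(A), 2, b, "+")
    rbT <- lapply(seq_along(f$rb), function(k) {
      v <- sapply(1:3, function(j) gridValues(f$rb[[j]])) # n x 3
      w <- sweep(v %*% t(A), 2, b, "+")[, k]
      grid <- f$rb[[k]]
      m <- matrix(w, nrow(gridValues(grid)), ncol(gridValues(grid)))
      new("BandGrid", georef = georef(grid), values = m,
          bandLabel = bandLabel(grid))
    })
    predT <- predictMLC(trainMLC(tr), rbT)
    expect_identical(gridValues(predT), gridValues(base))
  }
})

test_that("alternative classifiers honour the uniform contract", {
  f <- classifyFixture()
  sp <- splitSamples(f$samples, 0.4, seed = 3)
  truthVals <- gridValues(classMap(f$gen$truth))

  expect_error(trainPredictAlt(sp@train, f$rb, "boosting"), "unknown method")

  ## svm separates a linearly separable training set perfectly
  svmMap <- suppressMessages(trainPredictAlt(sp@train, f$rb, "svm", seed = 1))
  svmAtTrain <- gridValues(svmMap)[sampleLocations(sp@train)]
  expect_equal(mean(svmAtTrain ==
                      as.numeric(sampleLabels(sp@train) == "seagrass")), 1)
  expect_equal(pixelAccuracy(svmMap, truthVals), 1)

  ## random trees: deterministic under seed, exact on the separable scene
  rt1 <- suppressMessages(trainPredictAlt(sp@train, f$rb, "random_trees",
                                          seed = 7))
  rt2 <- suppressMessages(trainPredictAlt(sp@train, f$rb, "random_trees",
                                          seed = 7))
  expect_identical(gridValues(rt1), gridValues(rt2))
  expect_equal(pixelAccuracy(rt1, truthVals), 1)

  ## hyperparameter overrides are respected
  expect_message(trainPredictAlt(sp@train, f$rb, "random_trees",
                                 hyperparams = list(nTrees = 15L), seed = 1),
                 "nTrees=15")
})
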