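test_that("published two-class confusion tables reproduce their metrics", {
  ## support-vector machine assessment table
  svm <- metricsFromCounts(rbind(c(324, 21), c(60, 97)))
  expect_equal(paperRound(overallAccuracy(svm)), 0.84)
  expect_equal(paperRound(kappaIndex(svm)), 0.60)
  expect_equal(paperRound(userAccuracy(svm)[["seagrass"]]), 0.94)
  expect_equal(overallAccuracy(svm), 421 / 502, tolerance = 1e-12)

  ## maximum-likelihood table
  mlc <- metricsFromCounts(rbind(c(319, 20), c(63, 97)))
  expect_equal(paperRound(overallAccuracy(mlc)), 0.83)
  expect_equal(paperRound(kappaIndex(mlc)), 0.59)
  expect_equal(overallAccuracy(mlc), 416 / 499, tolerance = 1e-12)

  ## random-trees table
  rtc <- metricsFromCounts(rbind(c(303, 15), c(79, 102)))
  expect_equal(paperRound(overallAccuracy(rtc)), 0.81)
  expect_equal(paperRound(kappaIndex(rtc)), 0.56)
  expect_equal(paperRound(userAccuracy(rtc)[["other"]]), 0.56)
  expect_equal(paperRound(producerAccuracy(rtc)[["other"]]), 0.87)
  expect_equal(userAccuracy(rtc)[["other"]], 102 / 181, tolerance = 1e-12)
  expect_equal(producerAccuracy(rtc)[["other"]], 102 / 117,
               tolerance = 1e-12)
})

test_that("kappa and accuracy behave at the analytic limits", {
  ## perfect agreement
  ident <- metricsFromCounts(rbind(c(37, 0), c(0, 13)))
  expect_equal(overallAccuracy(ident), 1)
  expect_equal(kappaIndex(ident), 1)

  ## chance agreement: p_o = p_e -> kappa = 0
  chance <- metricsFromCounts(rbind(c(25, 25), c(25, 25)))
  expect_equal(kappaIndex(chance), 0)

  ## kappa invariant to scaling all counts
  a <- metricsFromCounts(rbind(c(30, 10), c(5, 55)))
  b <- metricsFromCounts(rbind(c(30, 10), c(5, 55)) * 7)
  expect_equal(kappaIndex(a), kappaIndex(b), tolerance = 1e-12)

  ## permuting class order permutes per-class metrics, fixes the rest
  m1 <- metricsFromCounts(rbind(c(30, 10), c(5, 55)),
                          classOrder = c("seagrass", "other"))
  m2 <- metricsFromCounts(rbind(c(55, 5), c(10, 30)),
                          classOrder = c("other", "seagrass"))
  expect_equal(overallAccuracy(m1), overallAccuracy(m2), tolerance = 1e-12)
  expect_equal(kappaIndex(m1), kappaIndex(m2), tolerance = 1e-12)
  expect_equal(userAccuracy(m1)[["seagrass"]],
               userAccuracy(m2)[["seagrass"]], tolerance = 1e-12)

  ## undefined per-class metrics are NA, never 0
  z <- metricsFromCounts(rbind(c(0, 0), c(10, 30)))
  expect_true(is.na(userAccuracy(z)[1]))
  expect_false(is.na(producerAccuracy(z)[1]))

  ## kappa <= overall accuracy whenever chance agreement is positive
  set.seed(1)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 40), 2, 2)
    if (sum(tab) == 0) next
    m <- metricsFromCounts(tab)
    expect_lte(kappaIndex(m), overallAccuracy(m) + 1e-12)
    expect_gte(kappaIndex(m), -1 - 1e-12)
  }

  expect_error(metricsFromCounts(rbind(c(0, 0), c(0, 0))), "all zero")
  expect_error(metricsFromCounts(matrix(1, 2, 3)), "square")
  expect_error(metricsFromCounts(rbind(c(-1, 2), c(3, 4))), "nonnegative")
})

test_that("confusion building tallies predictions against reference", {
  ## perfect prediction -> diagonal matrix
  g <- GridGeoref(nRows = 10, nCols = 10)
  predVals <- matrix(rep(c(1, 0), each = 50), 10, 10)
  pred <- BandGrid(predVals, g, "CLASS")
  loc <- cbind(rep(1:10, 5), rep(1:5, each = 10))
  labs <- factor(ifelse(predVals[loc] == 1, "seagrass", "other"),
                 levels = c("other", "seagrass"))
  ref <- new("LabeledSamples", features = matrix(0.1, 50, 3), labels = labs,
             source = rep("point", 50), location = loc)
  cs <- buildConfusion(pred, ref)
  expect_equal(sum(confusionCounts(cs)) - sum(diag(confusionCounts(cs))), 0)
  expect_equal(overallAccuracy(cs), 1)

  ## all predicted seagrass, reference half and half
  predAll <- BandGrid(matrix(1, 10, 10), g, "CLASS")
  labsHalf <- factor(rep(c("seagrass", "other"), 25),
                     levels = c("other", "seagrass"))
  refHalf <- new("LabeledSamples", features = matrix(0.1, 50, 3),
                 labels = labsHalf, source = rep("point", 50),
                 location = loc)
  csHalf <- buildConfusion(predAll, refHalf)
  expect_equal(userAccuracy(csHalf)[["seagrass"]], 0.5)

  ## random scene: counts equal a brute-force per-sample tally
  set.seed(8)
  pv <- matrix(rbinom(100, 1, 0.4), 10, 10)
  pv[1, 1] <- NA
  predR <- BandGrid(pv, g, "CLASS")
  locR <- cbind(sample(1:10, 60, TRUE), sample(1:10, 60, TRUE))
  labsR <- factor(sample(c("other", "seagrass"), 60, TRUE),
                  levels = c("other", "seagrass"))
  refR <- new("LabeledSamples", features = matrix(0.1, 60, 3),
              labels = labsR, source = rep("point", 60), location = locR)
  csR <- suppressMessages(buildConfusion(predR, refR))
  oracle <- matrix(0L, 2, 2)  # rows classified (sg, other), cols reference
  for (i in 1:60) {
    p <- pv[locR[i, 1], locR[i, 2]]
    if (is.na(p)) next
    r <- ifelse(labsR[i] == "seagrass", 1, 2)
    oracle[ifelse(p == 1, 1, 2), r] <- oracle[ifelse(p == 1, 1, 2), r] + 1L
  }
  expect_equal(unname(confusionCounts(csR)), oracle, ignore_attr = TRUE)

  ## reference samples that all fall on nodata cells are a data error
  pvNA <- matrix(NA_real_, 10, 10)
  expect_error(
    suppressMessages(buildConfusion(BandGrid(pvNA, g, "CLASS"), refR)),
    "no reference samples")
})

test_that("confusion reports round-trip through CSV", {
  cs <- metricsFromCounts(rbind(c(324, 21), c(60, 97)))
  path <- file.path(tempdir(), "conf.csv")
  writeConfusionReport(cs, path)
  rep <- utils::read.csv(path)
  expect_equal(rep$value[rep$metric == "overall_accuracy"], 421 / 502,
               tolerance = 1e-12)
  expect_equal(rep$rounded_2dp[rep$metric == "kappa"], 0.60)
  expect_equal(sum(rep$value[grepl("^count_", rep$metric)]), 502)
})
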