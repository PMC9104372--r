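test_that("grid georeferencing enforces its invariants", {
  expect_error(GridGeoref(pixelSize = 0, nRows = 2, nCols = 2), "pixelSize")
  expect_error(GridGeoref(nRows = 0, nCols = 2), "nRows")
  g <- GridGeoref(100, 200, 10, nRows = 2, nCols = 3)
  ctr <- pixelCenters(g)
  ## row-major: first row of pixels first, x varying fastest
  expect_equal(ctr[1, ], c(x = 105, y = 195))
  expect_equal(ctr[2, ], c(x = 115, y = 195))
  expect_equal(ctr[4, ], c(x = 105, y = 185))
})

test_that("BandGrid validity catches bad values", {
  g <- GridGeoref(nRows = 2, nCols = 2)
  expect_error(BandGrid(matrix(2.0, 2, 2), g, "B2_490"), "reflectance")
  expect_error(BandGrid(matrix(-1, 2, 2), g, "DEPTH"), "depth")
  expect_error(BandGrid(matrix(0.5, 2, 2), g, "CLASS"), "integers")
  expect_error(BandGrid(matrix(0.1, 3, 2), g, "B2_490"), "dimensions")
  expect_s4_class(BandGrid(matrix(c(0.1, NA, 1.5, 0), 2, 2), g, "B2_490"),
                  "BandGrid")
})

test_that("ASCII-grid raster I/O round-trips values, georef and nodata", {
  g <- GridGeoref(500000, 5000000, 10, nRows = 2, nCols = 2, crs = "EPSG:32633")
  vals <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  grid <- BandGrid(vals, g, "B2_490")
  path <- file.path(tempdir(), "rt.asc")
  writeRasterGrid(grid, path)
  back <- readRasterGrid(path, "B2_490")
  expect_identical(gridValues(back), gridValues(grid))
  expect_equal(georef(back)@originX, 500000)
  expect_equal(georef(back)@originY, 5000000)
  expect_equal(georef(back)@crs, "EPSG:32633")

  ## nodata propagation
  vals[2, 1] <- NA
  writeRasterGrid(BandGrid(vals, g, "B2_490"), path)
  expect_true(is.na(gridValues(readRasterGrid(path, "B2_490"))[2, 1]))

  ## CLASS grids are written as integer text
  cpath <- file.path(tempdir(), "cls.asc")
  writeRasterGrid(BandGrid(matrix(c(1, 0, 1, 0), 2, 2), g, "CLASS"), cpath)
  body <- readLines(cpath)[-(1:6)]
  expect_false(any(grepl("\\.", body)))

  expect_error(readRasterGrid(file.path(tempdir(), "missing.asc"), "DEPTH"),
               "not found")
})

test_that("raster reader agrees with an independent line-level parse", {
  cfg <- tinyConfig(seed = 5)
  gen <- generateScene(cfg, nSamples = 20)
  path <- file.path(tempdir(), "b3.asc")
  writeRasterGrid(sceneBands(gen$scene)$B3_560, path)
  ## independent parse: skip the 6 header lines, read whitespace table
  raw <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(raw) <- NULL
  raw[raw == -9999] <- NA
  expect_equal(raw, gridValues(sceneBands(gen$scene)$B3_560),
               tolerance = 1e-15)
  hdr <- readLines(path, n = 6)
  expect_equal(as.numeric(sub(".* ", "", hdr[5])), 10)  # cellsize
})

test_that("polygon masking follows the pixel-centre rule and partitions", {
  g <- GridGeoref(0, 40, 10, nRows = 4, nCols = 4)
  vals <- matrix(0.1, 4, 4)
  sc <- Scene(BandGrid(vals, g, "B2_490"), BandGrid(vals, g, "B3_560"),
              BandGrid(vals, g, "B4_665"), BandGrid(matrix(5, 4, 4), g, "DEPTH"))

  whole <- rectangleFeature(-1, 41, -1, 41)
  expect_identical(validMask(applyPolygonMask(sc, list(whole))),
                   validMask(sc))

  none <- rectangleFeature(100, 110, 100, 110)
  expect_equal(sum(validMask(applyPolygonMask(sc, list(none)))), 0)

  ## left half-plane: pixel centres at x = 5,15,25,35; cut at x = 20 keeps
  ## exactly the 8 cells of columns 1-2
  half <- rectangleFeature(-1, 20, -1, 41)
  kept <- applyPolygonMask(sc, list(half), keepInside = TRUE)
  expect_equal(sum(validMask(kept)), 8)
  expect_true(all(validMask(kept)[, 1:2]))
  ## oracle: explicit centre-in-rectangle test per pixel
  ctr <- pixelCenters(g)
  oracle <- matrix(ctr[, "x"] < 20, 4, 4, byrow = TRUE)
  expect_identical(validMask(kept), oracle)

  ## keepInside TRUE/FALSE partition the valid set
  dropped <- applyPolygonMask(sc, list(half), keepInside = FALSE)
  expect_equal(validMask(kept) & validMask(dropped),
               matrix(FALSE, 4, 4))
  expect_identical(validMask(kept) | validMask(dropped), validMask(sc))

  ## masking never alters surviving values
  expect_identical(gridValues(sceneBands(kept)$B2_490)[validMask(kept)],
                   gridValues(sceneBands(sc)$B2_490)[validMask(kept)])

  expect_warning(applyPolygonMask(sc, list()), "empty")
})

test_that("depth clipping masks exactly the too-deep cells", {
  depth <- matrix(c(10, 25, 5, 20), 2, 2)
  vals <- matrix(0.1, 2, 2)
  sc <- makeScene(vals, depth = depth)
  clipped <- clipByDepth(sc, 20)
  expect_identical(validMask(clipped), depth <= 20)

  cfg <- tinyConfig(seed = 3)
  gen <- generateScene(cfg, nSamples = 20)
  z <- gridValues(bathymetry(gen$scene))
  clipped <- clipByDepth(gen$scene, 20)
  ## counting oracle
  expect_equal(sum(validMask(gen$scene)) - sum(validMask(clipped)),
               sum(z > 20, na.rm = TRUE))
  expect_identical(georef(clipped), georef(gen$scene))
})

test_that("bathymetry resampling is exact on planes and degenerate cases", {
  g <- GridGeoref(0, 100, 10, nRows = 10, nCols = 10)
  src <- BandGrid(matrix(7, 10, 10), g, "DEPTH")
  expect_identical(resampleBathymetry(src, g), src)  # identical georefs

  ## constant source at coarse resolution -> constant output
  gc <- GridGeoref(0, 100, 25, nRows = 4, nCols = 4)
  srcC <- BandGrid(matrix(7, 4, 4), gc, "DEPTH")
  out <- resampleBathymetry(srcC, g)
  expect_true(all(gridValues(out)[!is.na(gridValues(out))] == 7))

  ## plane z = a x + b y + c sampled at 100 m, resampled to 10 m: bilinear
  ## interpolation of a plane is the plane
  gs <- GridGeoref(0, 1000, 100, nRows = 10, nCols = 10)
  plane <- function(x, y) 0.01 * x + 0.02 * y + 3
  ctrS <- pixelCenters(gs)
  srcP <- BandGrid(matrix(plane(ctrS[, "x"], ctrS[, "y"]), 10, 10,
                          byrow = TRUE), gs, "DEPTH")
  gt <- GridGeoref(100, 900, 10, nRows = 40, nCols = 40)
  outP <- resampleBathymetry(srcP, gt)
  ctrT <- pixelCenters(gt)
  expected <- matrix(plane(ctrT[, "x"], ctrT[, "y"]), 40, 40, byrow = TRUE)
  ok <- !is.na(gridValues(outP))
  expect_true(all(ok))  # target sits inside the source centre hull
  expect_lt(max(abs(gridValues(outP) - expected)), 1e-9)

  ## nearest-neighbour keeps source values
  outN <- resampleBathymetry(srcP, gt, method = "nearest")
  expect_true(all(gridValues(outN)[!is.na(gridValues(outN))] %in%
                    gridValues(srcP)))

  gFar <- GridGeoref(1e6, 1e6, 10, nRows = 4, nCols = 4)
  expect_error(resampleBathymetry(srcP, gFar), "disjoint")
})
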