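## Shared fixtures, built in code at test time.

## Small fast scenario for most tests (keeps the >40 m zone and the 1-5 m
## calibration strip of the default world at reduced size).
tinyConfig <- function(...) {
  ScenarioConfig(nRows = 40, nCols = 80, ...)
}

## Hand-built 1-band scene on an n x m grid with constant or given depth.
makeScene <- function(b2, b3 = b2, b4 = b2, depth) {
  g <- GridGeoref(0, nrow(b2) * 10, 10, nRows = nrow(b2), nCols = ncol(b2))
  Scene(BandGrid(b2, g, "B2_490"), BandGrid(b3, g, "B3_560"),
        BandGrid(b4, g, "B4_665"), BandGrid(depth, g, "DEPTH"))
}

## Overall pixel accuracy of a classified raster against a truth class map.
pixelAccuracy <- function(pred, truthVals) {
  pv <- gridValues(pred)
  ok <- !is.na(pv)
  mean(pv[ok] == truthVals[ok])
}

## Expected bottom reflectance of a generated truth: bottom spectra by class,
## optically dark (R_inf) beyond 40 m.
expectedBottom <- function(truth, band) {
  cfg <- truth@config
  cls <- gridValues(classMap(truth))
  z <- gridValues(bathymetry(truth))
  m <- ifelse(cls == 1, cfg@bottomSpectra["seagrass", band],
              cfg@bottomSpectra["sand", band])
  m[z > 40] <- cfg@rInf[band]
  m
}
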