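## Two-epoch categorical change analysis: overlay a baseline seagrass map
## with a later classification, label each pixel stable/loss/gain/other and
## summarize areas in hectares.

CHANGE_CODES <- c(stable_other = 0, stable_seagrass = 1, loss = 2, gain = 3)

#' Overlay two epoch class maps into a change raster
#'
#' Per-pixel mapping on the pair (baseline, current):
#' (1,1) stable seagrass, (1,0) loss, (0,1) gain, (0,0) stable other; nodata
#' in either input propagates. Both maps must be on the identical grid — the
#' function refuses to resample silently, since temporal comparisons are only
#' meaningful over the same co-registered area.
#'
#' @param baseline,current `CLASS` [BandGrid-class]s on one georef
#'   (1 = seagrass, 0 = other).
#' @return a `CHANGE` [BandGrid-class]
#'   (0 stable other, 1 stable seagrass, 2 loss, 3 gain).
#' @export
overlayChange <- function(baseline, current) {
  if (!sameGeoref(baseline@georef, current@georef))
    stopValidation("baseline and current grids are not co-registered ",
                   "(georefs differ); change analysis over different grids ",
                   "biases surface-cover estimates - resample explicitly ",
                   "first")
  b <- baseline@values; c2 <- current@values
  out <- matrix(NA_real_, nrow(b), ncol(b))
  ok <- !is.na(b) & !is.na(c2)
  out[ok & b == 1 & c2 == 1] <- CHANGE_CODES[["stable_seagrass"]]
  out[ok & b == 1 & c2 == 0] <- CHANGE_CODES[["loss"]]
  out[ok & b == 0 & c2 == 1] <- CHANGE_CODES[["gain"]]
  out[ok & b == 0 & c2 == 0] <- CHANGE_CODES[["stable_other"]]
  BandGrid(out, baseline@georef, "CHANGE")
}

#' Summarize a change raster into pixel counts and hectares
#'
#' One hectare is 10,000 m^2, so at 10 m pixels one pixel is 0.01 ha.
#' Derived totals: epoch-1 seagrass = stable + loss; epoch-2 seagrass =
#' stable + gain (exact integer identities on the counts).
#'
#' @param change a `CHANGE` [BandGrid-class] from [overlayChange()].
#' @return a [ChangeSummary-class].
#' @export
summarizeChange <- function(change) {
  if (change@bandLabel != "CHANGE")
    stopValidation("summarizeChange expects a CHANGE raster")
  v <- change@values
  counts <- vapply(CHANGE_CODES, function(code) sum(v == code, na.rm = TRUE),
                   numeric(1))
  haPerPixel <- change@georef@pixelSize^2 / 1e4
  area <- counts * haPerPixel
  new("ChangeSummary", pixelCounts = setNames(as.integer(counts),
                                              names(CHANGE_CODES)),
      areaHa = area, pixelSize = change@georef@pixelSize,
      epoch1SeagrassHa = unname(area[["stable_seagrass"]] + area[["loss"]]),
      epoch2SeagrassHa = unname(area[["stable_seagrass"]] + area[["gain"]]))
}

#' @export
setMethod("pixelCounts", "ChangeSummary", function(x) x@pixelCounts)

#' @export
setMethod("areaHa", "ChangeSummary", function(x) x@areaHa)

setMethod("show", "ChangeSummary", function(object) {
  cat("ChangeSummary (pixel size", object@pixelSize, "m):\n")
  for (nm in names(object@pixelCounts))
    cat(sprintf("  %-16s %8d px  %10.2f ha\n", nm, object@pixelCounts[[nm]],
                object@areaHa[[nm]]))
  cat(sprintf("  epoch-1 seagrass %10.2f ha; epoch-2 seagrass %10.2f ha\n",
              object@epoch1SeagrassHa, object@epoch2SeagrassHa))
})

#' Write a change summary as CSV
#'
#' @param summary a [ChangeSummary-class].
#' @param path output CSV path.
#' @export
writeChangeReport <- function(summary, path) {
  df <- data.frame(category = names(summary@pixelCounts),
                   pixels = summary@pixelCounts,
                   area_ha = summary@areaHa)
  df <- rbind(df,
              data.frame(category = c("epoch1_seagrass", "epoch2_seagrass"),
                         pixels = c(summary@pixelCounts[["stable_seagrass"]] +
                                      summary@pixelCounts[["loss"]],
                                    summary@pixelCounts[["stable_seagrass"]] +
                                      summary@pixelCounts[["gain"]]),
                         area_ha = c(summary@epoch1SeagrassHa,
                                     summary@epoch2SeagrassHa)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
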