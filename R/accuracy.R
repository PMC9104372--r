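## Confusion-matrix accuracy assessment: user/producer/overall accuracy,
## omission/commission errors and Cohen's kappa, with rows = classified and
## columns = reference (user accuracy lives on rows, producer on columns).

#' Derive accuracy metrics from a confusion matrix
#'
#' For a k x k table of counts (rows = classified, columns = reference):
#' overall accuracy is trace / N; user accuracy of class i is
#' `counts[i,i] / rowSum[i]` (1 - commission); producer accuracy of class j
#' is `counts[j,j] / colSum[j]` (1 - omission); Cohen's kappa is
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e), \qquad
#'       p_e = \sum_i \mathrm{rowSum}_i \cdot \mathrm{colSum}_i / N^2.}
#' Per-class metrics with zero denominators are `NA` (undefined), never 0.
#' Metrics are stored at full precision; [paperRound()] gives 2-dp display
#' rounding.
#'
#' @param counts square matrix of nonnegative counts.
#' @param classOrder optional class labels (defaults to dimnames or
#'   `other`/`seagrass` for 2 x 2).
#' @return a [ConfusionSummary-class].
#' @export
metricsFromCounts <- function(counts, classOrder = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stopValidation("confusion counts must be square")
  if (any(counts < 0) || any(counts != round(counts)))
    stopValidation("confusion counts must be nonnegative integers")
  N <- sum(counts)
  if (N == 0) stopData("confusion table is all zero")
  if (is.null(classOrder))
    classOrder <- rownames(counts) %||%
      (if (nrow(counts) == 2) c("seagrass", "other")
       else paste0("class", seq_len(nrow(counts))))
  dimnames(counts) <- list(classified = classOrder, reference = classOrder)
  rowTot <- rowSums(counts); colTot <- colSums(counts)
  user <- ifelse(rowTot > 0, diag(counts) / rowTot, NA_real_)
  producer <- ifelse(colTot > 0, diag(counts) / colTot, NA_real_)
  po <- sum(diag(counts)) / N
  pe <- sum(rowTot * colTot) / N^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  new("ConfusionSummary", counts = counts, classOrder = classOrder,
      userAccuracy = setNames(user, classOrder),
      producerAccuracy = setNames(producer, classOrder),
      overallAccuracy = po, kappa = kappa)
}

#' Build a confusion matrix from a classified raster and reference samples
#'
#' Each reference sample is compared with the classified value at its pixel;
#' samples on nodata pixels are dropped with a message. `counts[i, j]` is the
#' number of reference samples of class j classified as i.
#'
#' @param predicted a `CLASS` [BandGrid-class].
#' @param reference a [LabeledSamples-class] (locations + labels).
#' @return a [ConfusionSummary-class].
#' @export
buildConfusion <- function(predicted, reference) {
  if (length(reference@labels) == 0) stopData("empty reference sample set")
  pv <- predicted@values[reference@location]
  ok <- !is.na(pv)
  if (sum(!ok) > 0)
    message(sum(!ok), " reference samples on nodata pixels dropped")
  if (!any(ok)) stopData("no reference samples fall on classified pixels")
  classOrder <- c("seagrass", "other")
  predLab <- factor(ifelse(pv[ok] == 1, "seagrass", "other"),
                    levels = classOrder)
  refLab <- factor(as.character(reference@labels[ok]), levels = classOrder)
  metricsFromCounts(unclass(table(predLab, refLab)), classOrder)
}

#' Round a proportion the way accuracy tables are usually printed
#'
#' Two decimal places, half away from zero (0.835 -> 0.84).
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @export
paperRound <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @export
setMethod("confusionCounts", "ConfusionSummary", function(x) x@counts)

#' @export
setMethod("overallAccuracy", "ConfusionSummary",
          function(x) x@overallAccuracy)

#' @export
setMethod("kappaIndex", "ConfusionSummary", function(x) x@kappa)

#' @export
setMethod("userAccuracy", "ConfusionSummary", function(x) x@userAccuracy)

#' @export
setMethod("producerAccuracy", "ConfusionSummary",
          function(x) x@producerAccuracy)

setMethod("show", "ConfusionSummary", function(object) {
  cat("ConfusionSummary (rows = classified, columns = reference)\n")
  print(object@counts)
  fmtPct <- function(v) ifelse(is.na(v), "undefined", sprintf("%.4f", v))
  cat("User accuracy:     ",
      paste(sprintf("%s %s", object@classOrder,
                    fmtPct(object@userAccuracy)), collapse = ", "), "\n")
  cat("Producer accuracy: ",
      paste(sprintf("%s %s", object@classOrder,
                    fmtPct(object@producerAccuracy)), collapse = ", "), "\n")
  cat(sprintf("Overall accuracy:   %.4f (%.2f)\n", object@overallAccuracy,
              paperRound(object@overallAccuracy)))
  cat(sprintf("Kappa:              %.4f (%.2f)\n", object@kappa,
              paperRound(object@kappa)))
})

#' Write a confusion report as CSV
#'
#' Counts plus full-precision and 2-dp-rounded metrics side by side, so
#' rounding discrepancies in published tables remain auditable.
#'
#' @param summary a [ConfusionSummary-class].
#' @param path output CSV path.
#' @export
writeConfusionReport <- function(summary, path) {
  k <- length(summary@classOrder)
  rows <- data.frame(
    metric = c(paste0("count_classified_", rep(summary@classOrder, each = k),
                      "_ref_", rep(summary@classOrder, k)),
               paste0("user_accuracy_", summary@classOrder),
               paste0("producer_accuracy_", summary@classOrder),
               "overall_accuracy", "kappa"),
    value = c(as.vector(t(summary@counts)), summary@userAccuracy,
              summary@producerAccuracy, summary@overallAccuracy,
              summary@kappa))
  rows$rounded_2dp <- ifelse(grepl("^count_", rows$metric), rows$value,
                             paperRound(rows$value))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
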