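#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' PQRDataSet: a quantitative proteomics matrix with sample groups and a
#' stable-interaction pair list
#'
#' `PQRDataSet` extends [SummarizedExperiment::SummarizedExperiment] with one
#' assay, `logAbundance`, holding log-scale protein abundances (rows =
#' proteins, columns = samples; `NA` marks unmeasured values), a `group`
#' column in `colData()` assigning each sample to the `reference` or `test`
#' cohort (optionally a `subtype` column with finer labels), and a table of
#' unordered protein pairs expected to form stable interactions (e.g.
#' co-members of a CORUM complex). The pair list is stored deduplicated with
#' a fixed alphabetical orientation so that downstream log-ratios are
#' deterministic.
#'
#' @slot interactionPairs A [S4Vectors::DataFrame] with columns `protein1`,
#'   `protein2` (alphabetical order), `pairKey`, `source` and `measured`
#'   (whether both proteins are present in the matrix).
#'
#' @seealso [PQRDataSet()] (constructor), [runPQR()], [corShift()]
#' @export
setClass("PQRDataSet",
  contains = "SummarizedExperiment",
  representation(interactionPairs = "DataFrame"))

setValidity("PQRDataSet", function(object) {
  msg <- character(0)
  if (!"logAbundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'logAbundance' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "protein identifiers (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be unique")
  if (nrow(object) < 1L || ncol(object) < 2L)
    msg <- c(msg, "need at least 1 protein and 2 samples")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    grp <- as.character(cd$group)
    bad <- setdiff(unique(grp[!is.na(grp)]), c("reference", "test"))
    if (length(bad))
      msg <- c(msg, paste0("unknown group token(s): ",
                           paste(bad, collapse = ", "),
                           " (allowed: reference, test)"))
    if (sum(grp == "reference", na.rm = TRUE) < 2L)
      msg <- c(msg, "at least 2 reference samples are required")
    if (sum(grp == "test", na.rm = TRUE) < 1L)
      msg <- c(msg, "at least 1 test sample is required")
  }
  ip <- object@interactionPairs
  need <- c("protein1", "protein2", "pairKey", "measured")
  if (!all(need %in% colnames(ip))) {
    msg <- c(msg, paste0("interactionPairs must have columns: ",
                         paste(need, collapse = ", ")))
  } else if (nrow(ip)) {
    if (any(ip$protein1 == ip$protein2))
      msg <- c(msg, "self-pairs are not allowed in interactionPairs")
    if (anyDuplicated(ip$pairKey))
      msg <- c(msg, "interactionPairs must be deduplicated (unordered)")
  }
  if (length(msg)) msg else TRUE
})

#' Background score distribution for PQR significance
#'
#' Holds the scores of randomly formed protein pairs evaluated on resampled
#' reference measurements, together with the shape and rate of the gamma
#' distribution fitted to them by matching moments. When the background is
#' degenerate (more than 95% zero scores) the gamma fit is replaced by a
#' rank-based empirical tail and `empirical` is set.
#'
#' @slot scores Numeric vector of background pair scores (>= 0).
#' @slot shape,rate Fitted gamma parameters (`NA` when `empirical`).
#' @slot nPairs Number of random pairs drawn.
#' @slot seed Integer seed used for the resampling.
#' @slot empirical Logical; `TRUE` when the rank-based fallback is in use.
#' @slot zeroFraction Fraction of retained background scores equal to zero.
#' @export
setClass("PQRBackground",
  representation(scores = "numeric", shape = "numeric", rate = "numeric",
                 nPairs = "integer", seed = "integer",
                 empirical = "logical", zeroFraction = "numeric"))

setValidity("PQRBackground", function(object) {
  msg <- character(0)
  if (any(object@scores < 0)) msg <- c(msg, "background scores must be >= 0")
  if (!object@empirical) {
    if (!length(object@shape) || is.na(object@shape) || object@shape <= 0)
      msg <- c(msg, "gamma shape must be positive")
    if (!length(object@rate) || is.na(object@rate) || object@rate <= 0)
      msg <- c(msg, "gamma rate must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Results of a PQR outlier screen
#'
#' A [S4Vectors::DataFrame] subclass returned by [runPQR()], one row per
#' interaction pair, carrying reference statistics, outlier calls, scores,
#' gamma p-values, BH-adjusted p-values, filter status and redundancy
#' resolution. The fitted [PQRBackground] and the thresholds in effect are
#' stored in `metadata()`.
#'
#' @export
setClass("PQRResults", contains = "DFrame")

#' @describeIn PQRDataSet-class Compact display.
#' @param object A `PQRDataSet`.
#' @export
setMethod("show", "PQRDataSet", function(object) {
  grp <- as.character(SummarizedExperiment::colData(object)$group)
  cat("class: PQRDataSet\n")
  cat("proteins:", nrow(object), " samples:", ncol(object),
      sprintf("(%d reference, %d test)\n",
              sum(grp == "reference", na.rm = TRUE),
              sum(grp == "test", na.rm = TRUE)))
  ip <- object@interactionPairs
  cat("interaction pairs:", nrow(ip),
      sprintf("(%d with both proteins measured)\n", sum(ip$measured)))
})

setMethod("show", "PQRBackground", function(object) {
  cat("class: PQRBackground\n")
  cat("random pairs:", object@nPairs,
      " retained scores:", length(object@scores), "\n")
  cat(sprintf("zero-score fraction: %.3f\n", object@zeroFraction))
  if (object@empirical) {
    cat("model: empirical tail (rank-based fallback)\n")
  } else {
    cat(sprintf("model: gamma(shape = %.4g, rate = %.4g) by matching moments\n",
                object@shape, object@rate))
  }
  cat("seed:", object@seed, "\n")
})
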