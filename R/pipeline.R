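#' Run the full PQR outlier screen
#'
#' End-to-end pipeline over a [PQRDataSet-class]:
#' \enumerate{
#'   \item pair log-ratios and reference median/MAD
#'        ([pairLogRatios()], [referenceStats()]);
#'   \item annotation exclusions ([annotationFilter()]) and, optionally,
#'        the reference-variability filter
#'        ([referenceVariabilityFilter()]);
#'   \item modified z outlier calls and pair scores over the remaining
#'        testable pairs ([callOutliers()]);
#'   \item randomized background and matching-moments gamma
#'        ([buildBackground()]), gamma p-values, BH adjustment, top-1%
#'        advisory flag ([significanceTable()]);
#'   \item single-protein contribution test and representative-pair
#'        redundancy resolution on the significant pairs
#'        ([contributionTest()], [selectRepresentativePairs()]).
#' }
#'
#' @param object A [PQRDataSet-class].
#' @param zThreshold Pair outlier threshold on `|Mi|` (default 3.5,
#'   strict).
#' @param minRefObs Minimum non-missing reference ratios per pair
#'   (default 5).
#' @param adjPThreshold Adjusted-p significance threshold (default 0.1).
#' @param nBackgroundPairs Number of random background pairs; default
#'   `max(1000, 10 * n_testable)`.
#' @param seed Integer seed for the background resampling (mandatory).
#' @param exclusions Optional exclusion list(s) (see
#'   [readExclusionList()]).
#' @param variabilityFilter Apply the reference-variability filter
#'   (default `TRUE`).
#' @param maxRefOutliers,proteinMADMult Variability-filter parameters (see
#'   [referenceVariabilityFilter()]).
#' @param singleZThreshold Single-protein contribution threshold
#'   (default 2).
#' @param runLog Optional run-log environment from the CLI; `NULL` to
#'   skip logging.
#' @return A [PQRResults-class] (a DataFrame, one row per measured pair)
#'   with reference statistics, `score`, `nOutliers`, `outlierSamples`,
#'   `p`, `adjP`, `percentile`, `significant`, `top1pct`, `filterStatus`,
#'   `filterReason`, `status` (final fate: `representative`,
#'   `merged_into_representative`, `not_significant`, `untestable` or a
#'   removal reason), `representative` and `contributors`.
#'   `metadata()` carries `background` (the [PQRBackground-class]),
#'   `miMatrix`, `thresholds` and `seed`.
#' @examples
#' sim <- simulatePQRData(nProteins = 60, nRef = 8, nTest = 10,
#'                        nComplexes = 10, seed = 11)
#' res <- runPQR(sim$dataset, seed = 1, nBackgroundPairs = 500)
#' head(res[order(res$adjP), c("score", "p", "adjP", "status")])
#' @export
runPQR <- function(object, zThreshold = 3.5, minRefObs = 5,
                   adjPThreshold = 0.1, nBackgroundPairs = NULL, seed,
                   exclusions = NULL, variabilityFilter = TRUE,
                   maxRefOutliers = 3, proteinMADMult = 2,
                   singleZThreshold = 2, runLog = NULL) {
  stopifnot(is(object, "PQRDataSet"))
  if (missing(seed)) stop("seed is mandatory")
  mat <- quantMatrix(object)
  refIds <- referenceSamples(object)
  testIds <- testSamples(object)

  nUnmeasured <- sum(!interactionPairs(object)$measured)
  logLine(runLog, "pairs skipped as unmeasured: ", nUnmeasured)
  ratios <- pairLogRatios(object)
  st <- referenceStats(ratios, refIds, minRefObs = minRefObs)

  filterStatus <- rep("kept", nrow(st))
  filterReason <- rep(NA_character_, nrow(st))
  names(filterStatus) <- names(filterReason) <- st$pairKey

  af <- annotationFilter(st, exclusions)
  hit <- af$status != "kept"
  filterStatus[hit] <- af$status[hit]
  filterReason[hit] <- af$reason[hit]
  logLine(runLog, "pairs removed by annotation filter: ", sum(hit))

  if (variabilityFilter) {
    vf <- referenceVariabilityFilter(ratios, st, mat, refIds,
                                     zThreshold = zThreshold,
                                     maxRefOutliers = maxRefOutliers,
                                     proteinMADMult = proteinMADMult)
    hit <- vf$status != "kept" & filterStatus == "kept"
    filterStatus[hit] <- vf$status[hit]
    filterReason[hit] <- vf$reason[hit]
    logLine(runLog, "pairs removed by variability filter: ", sum(hit))
  }

  eligible <- st$testable & filterStatus == "kept"
  logLine(runLog, "untestable pairs (few observations / degenerate MAD): ",
          sum(!st$testable))
  stEl <- st[eligible, , drop = FALSE]
  co <- callOutliers(ratios[eligible, , drop = FALSE], stEl, testIds,
                     zThreshold = zThreshold)

  analyzed <- unique(c(stEl$protein1, stEl$protein2))
  nTestable <- nrow(stEl)
  if (nTestable < 1L) stop("no testable pairs after filtering")
  if (is.null(nBackgroundPairs))
    nBackgroundPairs <- max(1000L, 10L * nTestable)
  bg <- buildBackground(object, analyzedProteins = analyzed,
                        nPairs = nBackgroundPairs, seed = seed,
                        zThreshold = zThreshold, minRefObs = minRefObs)
  if (bg@empirical)
    logLine(runLog, "background gamma degenerate (",
            sprintf("%.1f%%", 100 * bg@zeroFraction),
            " zeros); using empirical tail fallback")
  sig <- significanceTable(co$calls, bg, adjPThreshold = adjPThreshold)

  # contribution + redundancy on the significant pairs
  prof <- proteinOutlierProfiles(mat, refIds, testIds)
  sigIdx <- which(sig$significant)
  contributors <- list()
  for (i in sigIdx) {
    key <- sig$pairKey[i]
    pp <- c(stEl$protein1[i], stEl$protein2[i])
    contributors[[key]] <- contributionTest(sig$outlierSamples[[i]],
                                            prof$mi, pp,
                                            singleZThreshold = singleZThreshold)
  }
  rep_ <- if (length(sigIdx))
    selectRepresentativePairs(sig[sigIdx, , drop = FALSE], contributors)
  else S4Vectors::DataFrame(pairKey = character(0), status = character(0),
                            representative = character(0),
                            contributors = character(0))

  # assemble the per-pair result over all measured pairs
  out <- S4Vectors::DataFrame(st)
  out$filterStatus <- filterStatus
  out$filterReason <- filterReason
  for (col in c("score", "nOutliers", "p", "adjP", "percentile"))
    out[[col]] <- rep(NA_real_, nrow(out))
  out$nOutliers <- rep(NA_integer_, nrow(out))
  out$outlierSamples <- I(vector("list", nrow(out)))
  out$significant <- rep(NA, nrow(out))
  out$top1pct <- rep(NA, nrow(out))
  idx <- match(sig$pairKey, out$pairKey)
  out$score[idx] <- sig$score
  out$nOutliers[idx] <- sig$nOutliers
  out$outlierSamples[idx] <- sig$outlierSamples
  out$p[idx] <- sig$p
  out$adjP[idx] <- sig$adjP
  out$percentile[idx] <- sig$percentile
  out$significant[idx] <- sig$significant
  out$top1pct[idx] <- sig$top1pct

  status <- rep(NA_character_, nrow(out))
  status[filterStatus != "kept"] <- filterStatus[filterStatus != "kept"]
  status[filterStatus == "kept" & !st$testable] <- "untestable"
  status[which(out$significant == FALSE)] <- "not_significant"
  if (nrow(rep_)) {
    ridx <- match(rep_$pairKey, out$pairKey)
    status[ridx] <- ifelse(rep_$status == "kept", "representative",
                           rep_$status)
    out$representative <- rep(NA_character_, nrow(out))
    out$contributors <- rep(NA_character_, nrow(out))
    out$representative[ridx] <- rep_$representative
    out$contributors[ridx] <- rep_$contributors
  } else {
    out$representative <- rep(NA_character_, nrow(out))
    out$contributors <- rep(NA_character_, nrow(out))
  }
  out$status <- status

  logLine(runLog, "testable pairs: ", nTestable,
          "; significant (adjP < ", adjPThreshold, "): ", length(sigIdx),
          "; representatives: ", sum(status == "representative", na.rm = TRUE))

  res <- new("PQRResults", out)
  S4Vectors::metadata(res) <- list(
    background = bg, miMatrix = co$mi, seed = as.integer(seed),
    thresholds = list(zThreshold = zThreshold, minRefObs = minRefObs,
                      adjPThreshold = adjPThreshold,
                      nBackgroundPairs = nBackgroundPairs,
                      variabilityFilter = variabilityFilter,
                      maxRefOutliers = maxRefOutliers,
                      proteinMADMult = proteinMADMult,
                      singleZThreshold = singleZThreshold))
  res
}
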