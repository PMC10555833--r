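#' Modified z-score
#'
#' Robust standardized deviation `0.6745 * (x - center) / scale`, where
#' `center` is the reference median of the quantity and `scale` its raw
#' (unscaled) median absolute deviation. The constant 0.6745 (approximately
#' the third quartile of the standard normal) makes the score comparable to
#' an ordinary z-score under normality; because it already supplies the
#' normal-consistency correction, `scale` must be the *raw* MAD, not a
#' 1.4826-scaled one.
#'
#' @param x Numeric vector of observations (log-ratios or log quantities).
#' @param center Reference median.
#' @param scale Reference raw MAD; must be strictly positive.
#' @return Numeric vector of modified z-scores; `NA` where `x` is `NA`.
#' @examples
#' modifiedZ(1.5, center = 1.0, scale = 0.05) # 6.745
#' @export
modifiedZ <- function(x, center, scale) {
  if (any(!is.na(scale) & scale <= 0))
    stop("modifiedZ requires a strictly positive scale (raw MAD); ",
         "degenerate pairs must be filtered before scoring")
  MZ_CONST * (x - center) / scale
}

#' Pair log-ratios
#'
#' For every measured interaction pair, the per-sample log-ratio of the two
#' proteins' quantities: log quantity of the first-alphabetical protein
#' minus that of the second (a subtraction, since the matrix is log-scale).
#' The ratio is missing in a sample iff either protein is unmeasured there.
#'
#' @param object A [PQRDataSet-class], or a numeric log-scale matrix.
#' @param pairs When `object` is a bare matrix, a `data.frame`/`DataFrame`
#'   with columns `protein1`, `protein2` (ignored for a `PQRDataSet`).
#' @return A numeric matrix (pairs x samples) whose rownames are pair keys
#'   (`"A::B"`, alphabetical). Unmeasured pairs are skipped.
#' @export
pairLogRatios <- function(object, pairs = NULL) {
  if (is(object, "PQRDataSet")) {
    mat <- quantMatrix(object)
    ip <- interactionPairs(object)
    ip <- ip[ip$measured, , drop = FALSE]
  } else {
    mat <- object
    stopifnot(!is.null(pairs))
    ip <- as.data.frame(pairs)
    if (!all(c("protein1", "protein2") %in% colnames(ip)))
      colnames(ip)[1:2] <- c("protein1", "protein2")
    ord <- ip$protein1 > ip$protein2
    tmp <- ip$protein1[ord]
    ip$protein1[ord] <- ip$protein2[ord]
    ip$protein2[ord] <- tmp
    meas <- ip$protein1 %in% rownames(mat) & ip$protein2 %in% rownames(mat)
    ip <- ip[meas, , drop = FALSE]
  }
  ratios <- mat[ip$protein1, , drop = FALSE] - mat[ip$protein2, , drop = FALSE]
  rownames(ratios) <- pairKey(ip$protein1, ip$protein2)
  ratios
}

#' Reference statistics for pair ratios
#'
#' The reference-sample ratios of each pair estimate the expected PQR
#' distribution: their median and raw MAD. Pairs with fewer than
#' `minRefObs` non-missing reference ratios, or with a zero MAD (constant
#' reference ratios, which cannot be standardized), are marked untestable.
#'
#' @param ratios Pair x sample ratio matrix from [pairLogRatios()].
#' @param refIds Character vector of reference sample identifiers.
#' @param minRefObs Minimum non-missing reference observations (default 5).
#' @return A [S4Vectors::DataFrame] with one row per pair: `pairKey`,
#'   `protein1`, `protein2`, `nRefObs`, `refMedian`, `refMAD`, `testable`,
#'   `status`.
#' @export
referenceStats <- function(ratios, refIds, minRefObs = 5) {
  stopifnot(minRefObs >= 3)
  ref <- ratios[, refIds, drop = FALSE]
  n <- rowSums(!is.na(ref))
  med <- rowMedianNA(ref)
  mad <- rowRawMADNA(ref, med)
  testable <- n >= minRefObs & !is.na(mad) & mad > 0
  status <- rep("testable", nrow(ref))
  status[n < minRefObs] <- "too_few_reference_observations"
  status[n >= minRefObs & (is.na(mad) | mad == 0)] <- "degenerate_reference_mad"
  pp <- splitPairKey(rownames(ratios))
  S4Vectors::DataFrame(pairKey = rownames(ratios),
                       protein1 = pp$protein1, protein2 = pp$protein2,
                       nRefObs = unname(as.integer(n)),
                       refMedian = unname(med), refMAD = unname(mad),
                       testable = unname(testable), status = unname(status),
                       row.names = rownames(ratios))
}

#' Outlier calls and pair scores
#'
#' Modified z-scores for every non-missing test-sample ratio of each
#' testable pair; a sample is flagged an outlier iff strictly
#' `|Mi| > zThreshold`, and the pair score is the sum of `|Mi|` over flagged
#' samples (0 when none are flagged).
#'
#' @param ratios Pair x sample ratio matrix.
#' @param stats Reference statistics from [referenceStats()].
#' @param testIds Character vector of test sample identifiers.
#' @param zThreshold Outlier threshold on `|Mi|` (default 3.5, strict).
#' @return A list with `calls`, a [S4Vectors::DataFrame] (per testable pair:
#'   `score`, `nOutliers`, `outlierSamples` as a comma-free character list
#'   column), and `mi`, the testable-pair x test-sample modified z matrix.
#' @export
callOutliers <- function(ratios, stats, testIds, zThreshold = 3.5) {
  keep <- stats$testable
  r <- ratios[keep, testIds, drop = FALSE]
  mi <- MZ_CONST * (r - stats$refMedian[keep]) / stats$refMAD[keep]
  flag <- !is.na(mi) & abs(mi) > zThreshold
  score <- rowSums(abs(mi) * flag, na.rm = TRUE)
  outlierSamples <- lapply(seq_len(nrow(mi)), function(i)
    colnames(mi)[flag[i, ]])
  calls <- S4Vectors::DataFrame(
    pairKey = rownames(r),
    score = unname(score),
    nOutliers = unname(as.integer(rowSums(flag))),
    outlierSamples = I(outlierSamples),
    row.names = rownames(r))
  list(calls = calls, mi = mi)
}

#' Normality diagnostic for reference ratios
#'
#' The modified z-score assumes approximately normal reference ratios; this
#' diagnostic applies the Shapiro-Wilk test to every pair's non-missing
#' reference ratios and reports the fraction of pairs whose p-value exceeds
#' `alpha` (i.e. pairs with no evidence against normality). Pairs with
#' constant reference ratios or fewer than 3 observations are excluded from
#' the fraction and counted separately.
#'
#' @param ratios Pair x sample ratio matrix.
#' @param refIds Reference sample identifiers.
#' @param alpha Significance level (default 0.05).
#' @return A list: `fraction` (of tested pairs with p > alpha), `pvalues`
#'   (named per tested pair), `nConstant`, `nTooFew`, `nTested`.
#' @export
normalityDiagnostic <- function(ratios, refIds, alpha = 0.05) {
  ref <- ratios[, refIds, drop = FALSE]
  p <- rep(NA_real_, nrow(ref))
  names(p) <- rownames(ref)
  nConstant <- 0L; nTooFew <- 0L
  for (i in seq_len(nrow(ref))) {
    v <- ref[i, ]
    v <- v[!is.na(v)]
    if (length(v) < 3L) { nTooFew <- nTooFew + 1L; next }
    if (max(v) - min(v) == 0) { nConstant <- nConstant + 1L; next }
    p[i] <- stats::shapiro.test(v)$p.value
  }
  tested <- !is.na(p)
  list(fraction = if (any(tested)) mean(p[tested] > alpha) else NA_real_,
       pvalues = p[tested], nConstant = nConstant, nTooFew = nTooFew,
       nTested = sum(tested))
}
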