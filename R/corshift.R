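#' Pairwise-complete Pearson correlation within a sample subset
#'
#' @param mat Log-scale protein x sample matrix.
#' @param protein1,protein2 Protein identifiers.
#' @param sampleIds Samples defining the group.
#' @return A list: `r` (Pearson correlation over samples where both
#'   proteins are measured; `NA` when degenerate) and `n` (number of paired
#'   non-missing observations).
#' @export
groupCorrelation <- function(mat, protein1, protein2, sampleIds) {
  x <- mat[protein1, sampleIds]
  y <- mat[protein2, sampleIds]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  r <- if (n >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
    stats::cor(x[ok], y[ok]) else NA_real_
  list(r = r, n = as.integer(n))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact-null t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' with `n - 2` degrees of freedom, the same reference distribution as
#' `cor.test(..., method = "pearson")`. `|r| = 1` returns p = 0.
#'
#' @param r Pearson correlation(s), `|r| <= 1`.
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value(s).
#' @examples
#' correlationPValue(0.76, 18) # ~2e-4
#' @export
correlationPValue <- function(r, n) {
  stopifnot(all(n >= 3), all(abs(r[!is.na(r)]) <= 1))
  p <- rep(NA_real_, length(r))
  exact1 <- !is.na(r) & abs(r) == 1
  p[exact1] <- 0
  ok <- !is.na(r) & abs(r) < 1
  tstat <- r[ok] * sqrt(n[ok] - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(abs(tstat), df = n[ok] - 2, lower.tail = FALSE)
  p
}

#' Classify a between-group correlation shift
#'
#' A pair gains correlation in group B iff it is significantly correlated
#' there (`r_B > rThreshold` and BH-adjusted `p_B <= pThreshold`), is *not*
#' significantly correlated in group A by the same rule, and the shift is
#' clearly evident (`|r_B - r_A| > deltaThreshold`); symmetrically for a
#' gain in A. Everything else is `no_shift`; pairs untestable in either
#' group are `untestable`.
#'
#' @param rA,rB Group correlations.
#' @param adjPA,adjPB Within-group BH-adjusted correlation p-values.
#' @param rThreshold Correlation threshold (default 0.6, strict).
#' @param pThreshold Adjusted-p threshold (default 0.05, inclusive).
#' @param deltaThreshold Threshold on `|r_B - r_A|` (default 0.6, strict).
#' @return Character vector of classifications.
#' @export
classifyShift <- function(rA, rB, adjPA, adjPB, rThreshold = 0.6,
                          pThreshold = 0.05, deltaThreshold = 0.6) {
  out <- rep("no_shift", length(rA))
  unt <- is.na(rA) | is.na(rB)
  sigA <- !unt & rA > rThreshold & adjPA <= pThreshold
  sigB <- !unt & rB > rThreshold & adjPB <= pThreshold
  delta <- abs(rB - rA) > deltaThreshold
  out[sigB & !sigA & delta] <- "gain_in_B"
  out[sigA & !sigB & delta] <- "gain_in_A"
  out[unt] <- "untestable"
  out
}

#' Differential-correlation screen (correlation gain/loss between groups)
#'
#' For every measured interaction pair, Pearson correlations are computed
#' separately in two sample groups (pairwise-complete observations, no
#' imputation), tested with the exact-null t transform, BH-adjusted within
#' each group across all testable pairs, and classified with
#' [classifyShift()]. A marked correlation gain in one group is read as
#' complex assembly there (or disassembly in the other).
#'
#' @param object A [PQRDataSet-class].
#' @param groups Length-2 character vector naming the two groups to
#'   compare. Values are matched first against the `group` column
#'   (`reference`/`test`), then against the optional `subtype` column of
#'   `colData`. Default `c("reference", "test")`; group A is the first
#'   element.
#' @param rThreshold,pThreshold,deltaThreshold Classification thresholds
#'   (defaults 0.6, 0.05, 0.6).
#' @param minObs Minimum paired non-missing observations per group
#'   (default 8); below it a pair is untestable in that group.
#' @param exclusions Optional exclusion list(s) applied before testing.
#' @return A [S4Vectors::DataFrame], one row per pair: `pairKey`,
#'   `protein1`, `protein2`, `rA`, `rB`, `nA`, `nB`, `pA`, `pB`, `adjPA`,
#'   `adjPB`, `deltaR` (`rB - rA`), `classification`; sorted so that
#'   gain-classified pairs come first, ordered by the gaining group's
#'   p-value.
#' @export
corShift <- function(object, groups = c("reference", "test"),
                     rThreshold = 0.6, pThreshold = 0.05,
                     deltaThreshold = 0.6, minObs = 8, exclusions = NULL) {
  stopifnot(is(object, "PQRDataSet"), length(groups) == 2L)
  mat <- quantMatrix(object)
  cd <- SummarizedExperiment::colData(object)
  pickGroup <- function(g) {
    ids <- rownames(cd)[!is.na(cd$group) & cd$group == g]
    if (!length(ids) && "subtype" %in% colnames(cd))
      ids <- rownames(cd)[!is.na(cd$subtype) & cd$subtype == g]
    if (!length(ids)) stop("no samples in group '", g, "'")
    ids
  }
  idsA <- pickGroup(groups[1L])
  idsB <- pickGroup(groups[2L])
  if (length(idsA) < minObs || length(idsB) < minObs)
    stop("each group needs at least minObs = ", minObs, " samples")

  ip <- interactionPairs(object)
  ip <- ip[ip$measured, , drop = FALSE]
  if (!is.null(exclusions)) {
    af <- annotationFilter(ip, exclusions)
    ip <- ip[af$status == "kept", , drop = FALSE]
  }
  m <- nrow(ip)
  rA <- rB <- rep(NA_real_, m)
  nA <- nB <- integer(m)
  matA <- mat[, idsA, drop = FALSE]
  matB <- mat[, idsB, drop = FALSE]
  for (i in seq_len(m)) {
    gA <- groupCorrelation(matA, ip$protein1[i], ip$protein2[i], idsA)
    gB <- groupCorrelation(matB, ip$protein1[i], ip$protein2[i], idsB)
    nA[i] <- gA$n; nB[i] <- gB$n
    if (gA$n >= minObs) rA[i] <- gA$r
    if (gB$n >= minObs) rB[i] <- gB$r
  }
  pA <- rep(NA_real_, m); pB <- rep(NA_real_, m)
  okA <- !is.na(rA); okB <- !is.na(rB)
  pA[okA] <- correlationPValue(rA[okA], nA[okA])
  pB[okB] <- correlationPValue(rB[okB], nB[okB])
  adjPA <- rep(NA_real_, m); adjPB <- rep(NA_real_, m)
  # BH within each group across all testable pairs (p = 0 from |r| = 1 is
  # kept as 0; bhAdjust requires (0,1] so adjust manually via p.adjust)
  adjPA[okA] <- stats::p.adjust(pA[okA], method = "BH")
  adjPB[okB] <- stats::p.adjust(pB[okB], method = "BH")

  cls <- classifyShift(rA, rB, adjPA, adjPB, rThreshold, pThreshold,
                       deltaThreshold)
  res <- S4Vectors::DataFrame(
    pairKey = ip$pairKey, protein1 = ip$protein1, protein2 = ip$protein2,
    rA = rA, rB = rB, nA = nA, nB = nB, pA = pA, pB = pB,
    adjPA = adjPA, adjPB = adjPB, deltaR = rB - rA, classification = cls,
    row.names = ip$pairKey)
  sortKey <- ifelse(cls == "gain_in_B", pB,
                    ifelse(cls == "gain_in_A", pA, pmin(pA, pB, na.rm = TRUE)))
  sortKey[is.na(sortKey)] <- Inf
  gainFirst <- cls %in% c("gain_in_A", "gain_in_B")
  res[order(-gainFirst, sortKey, res$pairKey), , drop = FALSE]
}
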