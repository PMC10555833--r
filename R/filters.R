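#' Single-protein outlier profiles
#'
#' The same modified z machinery applied to individual protein log
#' quantities instead of pair ratios: per protein, the reference median and
#' raw MAD of its log quantity, and the modified z of every test sample.
#' Used by the contribution test and the protein-level variability filter.
#'
#' @param mat Log-scale protein x sample matrix.
#' @param refIds,testIds Sample identifiers.
#' @return A list: `stats` (DataFrame per protein: `refMedian`, `refMAD`,
#'   `nRefObs`, `testable`) and `mi` (protein x test-sample modified z
#'   matrix; rows of degenerate proteins are `NA`).
#' @export
proteinOutlierProfiles <- function(mat, refIds, testIds) {
  ref <- mat[, refIds, drop = FALSE]
  med <- rowMedianNA(ref)
  mad <- rowRawMADNA(ref, med)
  n <- rowSums(!is.na(ref))
  testable <- !is.na(mad) & mad > 0
  mi <- matrix(NA_real_, nrow(mat), length(testIds),
               dimnames = list(rownames(mat), testIds))
  if (any(testable)) {
    mi[testable, ] <- MZ_CONST *
      (mat[testable, testIds, drop = FALSE] - med[testable]) / mad[testable]
  }
  stats <- S4Vectors::DataFrame(protein = rownames(mat),
                                refMedian = med, refMAD = mad,
                                nRefObs = as.integer(n), testable = testable,
                                row.names = rownames(mat))
  list(stats = stats, mi = mi)
}

#' Reference-variability filter
#'
#' Removes pairs that are intrinsically noisy in the reference cohort, a
#' safeguard against small reference sets: (1) pairs whose *reference*
#' ratios are themselves outliers (`|Mi| > zThreshold` against the full
#' reference median/MAD) in at least `maxRefOutliers` reference samples;
#' (2) pairs containing a protein whose reference log quantity falls
#' outside `median +/- 1.4826 * proteinMADMult * MAD` in at least
#' `maxRefOutliers` reference samples (1.4826 scales the raw MAD to a
#' standard-deviation estimate; when the protein MAD is zero the band
#' collapses to the median, so any off-median sample counts).
#'
#' @param ratios Pair x sample ratio matrix.
#' @param stats Reference statistics from [referenceStats()].
#' @param mat Log-scale protein x sample matrix.
#' @param refIds Reference sample identifiers.
#' @param zThreshold Pair-level outlier threshold (default 3.5).
#' @param maxRefOutliers Number of offending reference samples that
#'   triggers removal (default 3); set to `"auto"` for
#'   `ceiling(0.3 * n_ref)` with other reference sizes.
#' @param proteinMADMult Multiplier of the SD-scaled MAD in the
#'   protein-level band (default 2).
#' @return A [S4Vectors::DataFrame]: `pairKey`, `status` (`kept`,
#'   `removed_variability_pair` or `removed_variability_protein`), `reason`.
#' @export
referenceVariabilityFilter <- function(ratios, stats, mat, refIds,
                                       zThreshold = 3.5,
                                       maxRefOutliers = 3,
                                       proteinMADMult = 2) {
  nRef <- length(refIds)
  if (identical(maxRefOutliers, "auto"))
    maxRefOutliers <- ceiling(0.3 * nRef)
  maxRefOutliers <- as.integer(maxRefOutliers)

  # (1) pair-level: reference ratios scored against the full reference
  # median/MAD (leave-none-out)
  ref <- ratios[, refIds, drop = FALSE]
  ok <- stats$testable
  nOut <- rep(0L, nrow(ratios))
  if (any(ok)) {
    mi <- MZ_CONST * (ref[ok, , drop = FALSE] - stats$refMedian[ok]) /
      stats$refMAD[ok]
    nOut[ok] <- as.integer(rowSums(!is.na(mi) & abs(mi) > zThreshold))
  }
  pairHit <- nOut >= maxRefOutliers

  # (2) protein-level band
  refP <- mat[, refIds, drop = FALSE]
  medP <- rowMedianNA(refP)
  madP <- rowRawMADNA(refP, medP)
  half <- MAD_SD_CONST * proteinMADMult * madP
  outside <- sweep(refP, 1L, medP + half, ">") |
             sweep(refP, 1L, medP - half, "<")
  nOutP <- rowSums(outside, na.rm = TRUE)
  variableProt <- rownames(mat)[!is.na(nOutP) & nOutP >= maxRefOutliers]

  pp <- splitPairKey(stats$pairKey)
  protHit1 <- pp$protein1 %in% variableProt
  protHit2 <- pp$protein2 %in% variableProt

  status <- rep("kept", nrow(stats))
  reason <- rep(NA_character_, nrow(stats))
  hitP <- (protHit1 | protHit2) & !pairHit
  status[pairHit] <- "removed_variability_pair"
  reason[pairHit] <- sprintf("reference ratio outliers in %d samples",
                             nOut[pairHit])
  status[hitP] <- "removed_variability_protein"
  reason[hitP] <- ifelse(protHit1[hitP] & protHit2[hitP],
                         paste(pp$protein1[hitP], pp$protein2[hitP], sep = ","),
                         ifelse(protHit1[hitP], pp$protein1[hitP],
                                pp$protein2[hitP]))
  S4Vectors::DataFrame(pairKey = stats$pairKey, status = status,
                       reason = reason, row.names = stats$pairKey)
}

#' Annotation-based exclusion filter
#'
#' Removes every pair containing a protein on any supplied exclusion list
#' (e.g. GO:0005200 structural cytoskeleton constituents, whose apparent
#' shifts can reflect variable stroma content, or GO:0003735 ribosomal
#' proteins, which lack isoform-specific annotation). All triggering lists'
#' reasons are recorded.
#'
#' @param pairs DataFrame with `pairKey`, `protein1`, `protein2`.
#' @param exclusions A single exclusion list (as from
#'   [readExclusionList()]) or a list of them; `NULL`/empty keeps all pairs.
#' @return A [S4Vectors::DataFrame]: `pairKey`, `status` (`kept` or
#'   `removed_annotation`), `reason`.
#' @export
annotationFilter <- function(pairs, exclusions = NULL) {
  status <- rep("kept", nrow(pairs))
  reason <- rep(NA_character_, nrow(pairs))
  if (!is.null(exclusions) && length(exclusions)) {
    if (!is.null(exclusions$protein_ids)) exclusions <- list(exclusions)
    for (ex in exclusions) {
      hit <- pairs$protein1 %in% ex$protein_ids |
             pairs$protein2 %in% ex$protein_ids
      status[hit] <- "removed_annotation"
      reason[hit] <- ifelse(is.na(reason[hit]), ex$reason,
                            paste(reason[hit], ex$reason, sep = ";"))
    }
  }
  S4Vectors::DataFrame(pairKey = pairs$pairKey, status = status,
                       reason = reason, row.names = pairs$pairKey)
}

#' Single-protein contribution test
#'
#' For a significant pair, decides which of its proteins drives the signal:
#' a protein contributes iff, among the samples flagged as pair outliers,
#' its own single-protein `|Mi|` exceeds `singleZThreshold` in at least half
#' of them (count >= flagged/2, so 2 of 4 passes and 1 of 3 fails). The
#' lower threshold keeps pairs in which both proteins changed mildly but in
#' opposite directions. A protein with a degenerate (zero) reference MAD
#' cannot be standardized and is treated as non-contributing.
#'
#' @param outlierSamples Character vector of the pair's flagged test
#'   samples.
#' @param proteinMi Protein x test-sample modified z matrix from
#'   [proteinOutlierProfiles()].
#' @param proteins Character vector of the pair's two protein identifiers.
#' @param singleZThreshold Single-protein threshold (default 2).
#' @return Character vector (possibly empty) of contributing proteins.
#' @export
contributionTest <- function(outlierSamples, proteinMi, proteins,
                             singleZThreshold = 2) {
  if (!length(outlierSamples)) return(character(0))
  need <- length(outlierSamples) / 2
  ok <- vapply(proteins, function(p) {
    if (!p %in% rownames(proteinMi)) return(FALSE)
    mi <- proteinMi[p, outlierSamples]
    sum(!is.na(mi) & abs(mi) > singleZThreshold) >= need
  }, logical(1))
  proteins[ok]
}

#' Representative-pair redundancy resolution
#'
#' A strongly up- or downregulated hub protein would otherwise surface once
#' per interaction partner; this step represents each contributing protein
#' by its single highest-scoring significant pair. Significant pairs are
#' visited in decreasing score order (ties: smaller adjusted p, then
#' lexicographic pair key); a pair is kept iff none of its contributing
#' proteins is already represented by a kept pair, otherwise it is merged
#' into the first kept pair of such a protein. Pairs with no contributing
#' proteins cannot cause hub redundancy and are kept as-is (flagged in the
#' `contributors` column).
#'
#' @param sig DataFrame of significant pairs with `pairKey`, `score`,
#'   `adjP`.
#' @param contributors Named list (by `pairKey`) of contributing-protein
#'   vectors from [contributionTest()].
#' @return A [S4Vectors::DataFrame]: `pairKey`, `status` (`kept` or
#'   `merged_into_representative`), `representative` (`NA` for kept pairs),
#'   `contributors`.
#' @export
selectRepresentativePairs <- function(sig, contributors) {
  n <- nrow(sig)
  ord <- order(-sig$score, sig$adjP, sig$pairKey)
  status <- rep("kept", n)
  representative <- rep(NA_character_, n)
  repOf <- new.env(parent = emptyenv())  # protein -> kept pairKey
  for (i in ord) {
    key <- sig$pairKey[i]
    contr <- contributors[[key]] %||% character(0)
    taken <- contr[vapply(contr, function(p)
      !is.null(repOf[[p]]), logical(1))]
    if (length(taken)) {
      status[i] <- "merged_into_representative"
      representative[i] <- repOf[[taken[[1L]]]]
    } else {
      for (p in contr) repOf[[p]] <- key
    }
  }
  S4Vectors::DataFrame(
    pairKey = sig$pairKey, status = status, representative = representative,
    contributors = vapply(sig$pairKey, function(k)
      paste(contributors[[k]] %||% character(0), collapse = ","),
      character(1)),
    row.names = sig$pairKey)
}
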