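#' Complex over-representation among significant proteins
#'
#' Per complex, a 2x2 contingency table (member of the complex vs. not,
#' crossed with significant vs. not) over the background proteins, tested
#' with a two-sided Fisher's exact test and BH-adjusted across complexes.
#' Complexes with no measured member (no member in the background set) are
#' skipped.
#'
#' @param significantProteins Character vector of proteins flagged by the
#'   screen; must be a subset of `backgroundProteins`.
#' @param backgroundProteins Character vector of all analyzed proteins.
#' @param catalog Complex catalog `data.frame` (`complex_id`, `name`,
#'   `member_id`) as from [readComplexCatalog()].
#' @return A [S4Vectors::DataFrame], one row per tested complex:
#'   `complex_id`, `name`, `nMembersMeasured`, `nMembersSignificant`, `p`,
#'   `adjP`, sorted by p.
#' @export
complexOverrepresentation <- function(significantProteins,
                                      backgroundProteins, catalog) {
  if (!all(significantProteins %in% backgroundProteins))
    stop("significantProteins must be a subset of backgroundProteins")
  backgroundProteins <- unique(backgroundProteins)
  significantProteins <- unique(significantProteins)
  members <- split(catalog$member_id, catalog$complex_id)
  names4 <- vapply(split(catalog$name, catalog$complex_id), `[`,
                   character(1), 1L)
  nBg <- length(backgroundProteins)
  nSig <- length(significantProteins)
  rows <- lapply(names(members), function(cid) {
    mem <- intersect(unique(members[[cid]]), backgroundProteins)
    if (!length(mem)) return(NULL)
    a <- sum(mem %in% significantProteins)            # in complex, significant
    b <- length(mem) - a                              # in complex, not
    c0 <- nSig - a                                    # not in complex, significant
    d <- nBg - length(mem) - c0
    p <- stats::fisher.test(matrix(c(a, b, c0, d), 2L),
                            alternative = "two.sided")$p.value
    data.frame(complex_id = cid, name = names4[[cid]],
               nMembersMeasured = length(mem), nMembersSignificant = a,
               p = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no complex has a measured member")
  out <- S4Vectors::DataFrame(rows)
  out$adjP <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$complex_id), , drop = FALSE]
}

#' Median subunit expression profile per complex
#'
#' Represents each complex by the per-sample median log quantity of its
#' reliably measured subunits: a subunit is kept iff it is measured in more
#' than `majorityFraction` of all samples, the complex value exists only in
#' samples where *all* kept subunits are measured, and complexes with fewer
#' than 2 kept subunits are dropped.
#'
#' @param object A [PQRDataSet-class] (or a log-scale matrix).
#' @param catalog Complex catalog `data.frame`.
#' @param majorityFraction Measured-sample fraction a subunit must exceed
#'   to be kept (default 0.5, strict).
#' @return A list: `profile`, a complex x sample matrix of median subunit
#'   expression (`NA` where not evaluable), and `subunits`, a named list of
#'   the kept subunits per complex.
#' @export
complexMedianProfile <- function(object, catalog, majorityFraction = 0.5) {
  mat <- if (is(object, "PQRDataSet")) quantMatrix(object) else object
  nSamp <- ncol(mat)
  measuredFrac <- rowSums(!is.na(mat)) / nSamp
  members <- split(catalog$member_id, catalog$complex_id)
  kept <- lapply(members, function(mem) {
    mem <- intersect(unique(mem), rownames(mat))
    mem[measuredFrac[mem] > majorityFraction]
  })
  kept <- kept[vapply(kept, length, integer(1)) >= 2L]
  if (!length(kept))
    return(list(profile = matrix(numeric(0), 0L, nSamp,
                                 dimnames = list(NULL, colnames(mat))),
                subunits = list()))
  prof <- t(vapply(kept, function(sub) {
    sm <- mat[sub, , drop = FALSE]
    v <- apply(sm, 2L, stats::median)  # NA when any kept subunit missing
    v
  }, numeric(nSamp)))
  dimnames(prof) <- list(names(kept), colnames(mat))
  list(profile = prof, subunits = kept)
}

#' Whole-complex outlier scan
#'
#' Applies the modified z machinery to each complex's median-expression
#' trace: reference median and raw MAD of the trace, modified z in every
#' evaluable test sample, outliers at strict `|Mi| > zThreshold`. A complex
#' is retained iff its expression is an outlier in at least `minFraction`
#' of the evaluable test samples; the regulation direction is the sign of
#' the mean flagged Mi. The fraction over *all* test samples is also
#' reported, since a complex may not be evaluable everywhere.
#'
#' @param profile Complex x sample matrix from [complexMedianProfile()]
#'   (`$profile`).
#' @param refIds,testIds Sample identifiers.
#' @param zThreshold Outlier threshold (default 3.5).
#' @param minFraction Minimum flagged fraction, inclusive (default 0.10).
#' @param minRefObs Minimum evaluable reference samples (default 5).
#' @return A [S4Vectors::DataFrame], one row per complex: `complex_id`,
#'   `nRefObs`, `refMedian`, `refMAD`, `nEvaluableTest`, `nFlagged`,
#'   `flaggedFraction` (over evaluable test samples),
#'   `flaggedFractionAllTest`, `direction` (`up`/`down`/`NA`), `status`
#'   (`retained`, `dropped`, `untestable`).
#' @export
complexOutlierScan <- function(profile, refIds, testIds, zThreshold = 3.5,
                               minFraction = 0.10, minRefObs = 5) {
  ref <- profile[, refIds, drop = FALSE]
  tst <- profile[, testIds, drop = FALSE]
  med <- rowMedianNA(ref)
  mad <- rowRawMADNA(ref, med)
  nRef <- rowSums(!is.na(ref))
  testable <- nRef >= minRefObs & !is.na(mad) & mad > 0

  n <- nrow(profile)
  nEval <- as.integer(rowSums(!is.na(tst)))
  nFlag <- integer(n)
  direction <- rep(NA_character_, n)
  for (i in which(testable)) {
    mi <- MZ_CONST * (tst[i, ] - med[i]) / mad[i]
    fl <- !is.na(mi) & abs(mi) > zThreshold
    nFlag[i] <- sum(fl)
    if (nFlag[i]) direction[i] <- if (mean(mi[fl]) > 0) "up" else "down"
  }
  frac <- ifelse(testable & nEval > 0, nFlag / nEval, NA_real_)
  status <- rep("untestable", n)
  status[testable & !is.na(frac) & frac >= minFraction] <- "retained"
  status[testable & !is.na(frac) & frac < minFraction] <- "dropped"
  S4Vectors::DataFrame(
    complex_id = rownames(profile), nRefObs = unname(as.integer(nRef)),
    refMedian = unname(med), refMAD = unname(mad),
    nEvaluableTest = unname(nEval), nFlagged = unname(nFlag),
    flaggedFraction = unname(frac),
    flaggedFractionAllTest = unname(nFlag / length(testIds)),
    direction = unname(direction), status = unname(status),
    row.names = rownames(profile))
}
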