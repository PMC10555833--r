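#' Gamma fit by matching moments
#'
#' Closed-form moment estimators for the gamma distribution:
#' `shape = m^2 / v`, `rate = m / v`, with `m` and `v` the sample mean and
#' variance of the scores.
#'
#' @param scores Non-negative numeric vector with positive mean and
#'   variance.
#' @return Named numeric vector `c(shape = , rate = )`.
#' @examples
#' fitGammaMoments(c(1, 2, 3)) # m = 2, v = 1 -> shape 4, rate 2
#' @export
fitGammaMoments <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (any(scores < 0)) stop("background scores must be non-negative")
  m <- mean(scores)
  v <- stats::var(scores)
  if (!is.finite(v) || v <= 0)
    stop("cannot fit a gamma by matching moments: zero score variance")
  if (m <= 0)
    stop("cannot fit a gamma by matching moments: non-positive score mean")
  c(shape = m^2 / v, rate = m / v)
}

#' Randomized background score distribution
#'
#' Builds the null model for pair scores: `nPairs` random pairs are formed
#' from the analyzed proteins and, for each slot of a pair, a randomly
#' chosen analyzed protein donates its reference-sample measurements,
#' resampled with replacement across every sample position (reference and
#' test) of the pseudo-dataset; missing reference values are carried so each
#' donor's missingness rate is preserved. The full scoring path (reference
#' statistics, modified z, outlier calls, score) then runs on each random
#' pair. Because only reference values are used, the null captures
#' technical and biological reference variability while destroying real
#' pair structure. A gamma is fitted to the retained scores by matching
#' moments; if more than 95% of them are exactly zero the model falls back
#' to a rank-based empirical tail.
#'
#' @param object A [PQRDataSet-class] (or a log-scale matrix).
#' @param analyzedProteins Proteins appearing in testable pairs; the
#'   background is drawn from these.
#' @param nPairs Number of random pairs (>= 200).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param zThreshold Outlier threshold (default 3.5).
#' @param minRefObs Minimum reference observations per random pair
#'   (default 5).
#' @param refIds,testIds Sample identifiers; taken from `object` when it is
#'   a `PQRDataSet`.
#' @return A [PQRBackground-class].
#' @export
buildBackground <- function(object, analyzedProteins, nPairs, seed,
                            zThreshold = 3.5, minRefObs = 5,
                            refIds = NULL, testIds = NULL) {
  if (is(object, "PQRDataSet")) {
    mat <- quantMatrix(object)
    refIds <- referenceSamples(object)
    testIds <- testSamples(object)
  } else mat <- object
  nPairs <- as.integer(nPairs)
  if (nPairs < 200L)
    stop("nPairs must be at least 200 for a usable background")
  analyzedProteins <- intersect(analyzedProteins, rownames(mat))
  if (length(analyzedProteins) < 2L)
    stop("need at least 2 analyzed proteins for the background")
  seed <- as.integer(seed)

  nRef <- length(refIds)
  nAll <- nRef + length(testIds)
  refMat <- mat[analyzedProteins, refIds, drop = FALSE]

  set.seed(seed)
  protA <- sample.int(nrow(refMat), nPairs, replace = TRUE)
  protB <- sample.int(nrow(refMat), nPairs, replace = TRUE)
  while (any(same <- protA == protB))  # random pairs of distinct proteins
    protB[same] <- sample.int(nrow(refMat), sum(same), replace = TRUE)
  # each donor's reference values are permuted across the reference
  # positions (keeping the full empirical reference sample intact) and
  # drawn with replacement for the test positions; NAs are carried so the
  # donor's missingness rate is preserved
  drawSlot <- function(prot) {
    idxRef <- vapply(seq_len(nPairs), function(i) sample.int(nRef),
                     integer(nRef))              # nRef x nPairs permutations
    idxTest <- matrix(sample.int(nRef, nPairs * (nAll - nRef),
                                 replace = TRUE), nrow = nPairs)
    idx <- cbind(t(idxRef), idxTest)
    matrix(refMat[cbind(rep(prot, nAll), as.vector(idx))], nrow = nPairs)
  }
  pseudoA <- drawSlot(protA)
  pseudoB <- drawSlot(protB)
  ratios <- pseudoA - pseudoB
  colnames(ratios) <- c(refIds, testIds)
  rownames(ratios) <- sprintf("bg%06d::x", seq_len(nPairs))

  st <- referenceStats(ratios, refIds, minRefObs = minRefObs)
  co <- callOutliers(ratios, st, testIds, zThreshold = zThreshold)
  scores <- co$calls$score
  if (length(scores) < 50L)
    stop("only ", length(scores), " background scores retained; ",
         "increase nPairs")
  zeroFrac <- mean(scores == 0)
  if (zeroFrac > 0.95) {
    return(new("PQRBackground", scores = scores, shape = NA_real_,
               rate = NA_real_, nPairs = nPairs, seed = seed,
               empirical = TRUE, zeroFraction = zeroFrac))
  }
  fit <- fitGammaMoments(scores)
  new("PQRBackground", scores = scores, shape = unname(fit["shape"]),
      rate = unname(fit["rate"]), nPairs = nPairs, seed = seed,
      empirical = FALSE, zeroFraction = zeroFrac)
}

#' Score p-value under the background model
#'
#' Upper-tail probability `P(X >= score)` of the fitted gamma (or of the
#' empirical background with a pseudocount when the model uses the
#' rank-based fallback). Scores <= 0 map to p = 1.
#'
#' @param score Numeric vector of pair scores.
#' @param model A [PQRBackground-class].
#' @return Numeric vector of p-values in (0, 1].
#' @export
scorePValue <- function(score, model) {
  stopifnot(is(model, "PQRBackground"))
  p <- if (model@empirical) {
    bg <- model@scores
    vapply(score, function(s) (1 + sum(bg >= s)) / (1 + length(bg)),
           numeric(1))
  } else {
    stats::pgamma(score, shape = model@shape, rate = model@rate,
                  lower.tail = FALSE)
  }
  p[score <= 0] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-pair significance table
#'
#' Converts pair scores into gamma p-values under the background model,
#' BH-adjusts them, and annotates each pair with its score percentile, a
#' significance flag (`adjP < adjPThreshold`) and an advisory flag marking
#' the top 1% of scores among testable pairs (`ceiling(0.01 * n)` pairs,
#' ties broken by smaller p then lexicographic pair key).
#'
#' @param calls Per-pair calls from [callOutliers()] (`$calls`), or any
#'   DataFrame with `pairKey` and `score`.
#' @param model A [PQRBackground-class].
#' @param adjPThreshold Adjusted-p significance threshold (default 0.1).
#' @return The input DataFrame with columns `p`, `adjP`, `percentile`,
#'   `significant`, `top1pct` appended.
#' @export
significanceTable <- function(calls, model, adjPThreshold = 0.1) {
  out <- calls
  out$p <- scorePValue(out$score, model)
  out$adjP <- bhAdjust(out$p)
  n <- nrow(out)
  out$percentile <- if (n) 100 * rank(out$score, ties.method = "average") / n
                    else numeric(0)
  out$significant <- out$adjP < adjPThreshold
  nTop <- if (n) as.integer(ceiling(0.01 * n)) else 0L
  ord <- order(-out$score, out$p, out$pairKey)
  out$top1pct <- logical(n)
  if (nTop > 0L) out$top1pct[ord[seq_len(min(nTop, n))]] <- TRUE
  out
}
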