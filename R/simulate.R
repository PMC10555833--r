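#' Simulate a quantitative proteomics dataset with known ground truth
#'
#' Generates a log2-scale protein x sample matrix emulating the structure
#' the PQR screen assumes: per-protein log-normal baselines (normal on the
#' log scale), complex co-regulation through a shared per-sample latent
#' factor, independent measurement noise, and optional injected events with
#' recorded ground truth:
#' \describe{
#'   \item{shift pairs}{`delta` (log2) added to the first protein of a pair
#'     in a random subset (`fraction`) of test samples - the altered-PQR
#'     signal. With `split = TRUE` the shift is divided oppositely across
#'     both proteins (+delta/2 / -delta/2), the mild-but-opposite case.}
#'   \item{correlation-gain pairs}{a new shared latent factor (weight
#'     `weight`) added to both proteins only in the target group, creating
#'     a within-group correlation of `weight^2 / (weight^2 + noiseSD^2)`.}
#'   \item{hub proteins}{`delta` added to one protein in *all* test
#'     samples, the scenario redundancy resolution must collapse.}
#' }
#' Values are masked missing completely at random at `missingRate`. The
#' interaction pair list is all within-complex pairs plus any injected
#' pairs; everything is deterministic given `seed`.
#'
#' @param nProteins Total number of proteins (default 250).
#' @param nRef,nTest Reference / test sample counts (defaults 10 and 24,
#'   a typical cell-line panel split).
#' @param nComplexes Number of complexes (default 40).
#' @param complexSizeRange Integer range of complex sizes (default 3..6).
#' @param baselineMean,baselineSD Mean and SD of protein baselines in log2
#'   units (defaults 20 and 2).
#' @param noiseSD Independent measurement noise SD in log2 units (default
#'   0.25, chosen so null ratio `|Mi|` rarely exceeds 3.5).
#' @param coregSD Latent-factor weight shared by complex co-members
#'   (default 0.25, i.e. within-complex co-expression r of about 0.5;
#'   the shared factor cancels in within-complex ratios).
#' @param shiftPairs `data.frame(protein1, protein2, delta, fraction)` of
#'   PQR shift injections (protein names, or `NULL`).
#' @param splitShift Divide each shift oppositely across both proteins
#'   (default `FALSE`).
#' @param corGainPairs `data.frame(protein1, protein2, weight, group)` of
#'   correlation-gain injections (`group` is `"reference"` or `"test"`).
#' @param hubProteins `data.frame(protein, delta)` of hub up/down
#'   regulations.
#' @param missingRate Missing-completely-at-random rate (default 0.02).
#' @param seed Integer seed (mandatory).
#' @return A list: `dataset` ([PQRDataSet-class]), `truth` (`data.frame`
#'   of injected events: `type`, `target`, `samples`, `magnitude`),
#'   `catalog` (complex membership `data.frame`).
#' @examples
#' sim <- simulatePQRData(nProteins = 40, nRef = 6, nTest = 8,
#'                        nComplexes = 6, seed = 3)
#' sim$dataset
#' @export
simulatePQRData <- function(nProteins = 250, nRef = 10, nTest = 24,
                            nComplexes = 40, complexSizeRange = c(3, 6),
                            baselineMean = 20, baselineSD = 2,
                            noiseSD = 0.25, coregSD = 0.25,
                            shiftPairs = NULL, splitShift = FALSE,
                            corGainPairs = NULL, hubProteins = NULL,
                            missingRate = 0.02, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noiseSD > 0, missingRate >= 0, missingRate <= 1,
            nRef >= 2, nTest >= 1, nProteins >= 1)
  set.seed(as.integer(seed))

  proteins <- sprintf("P%04d", seq_len(nProteins))
  samples <- c(sprintf("REF%02d", seq_len(nRef)),
               sprintf("TST%02d", seq_len(nTest)))
  nSamp <- nRef + nTest
  refIds <- samples[seq_len(nRef)]
  testIds <- samples[nRef + seq_len(nTest)]

  # complex assignment: consecutive blocks of proteins
  sizeChoices <- seq(complexSizeRange[1L], complexSizeRange[2L])
  sizes <- if (nComplexes > 0)
    sizeChoices[sample.int(length(sizeChoices), nComplexes, replace = TRUE)]
  else integer(0)
  if (sum(sizes) > nProteins)
    stop("complexes require ", sum(sizes), " proteins but nProteins = ",
         nProteins)
  complexOf <- rep(NA_integer_, nProteins)
  if (nComplexes > 0)
    complexOf[seq_len(sum(sizes))] <- rep(seq_len(nComplexes), sizes)

  baseline <- stats::rnorm(nProteins, baselineMean, baselineSD)
  vals <- matrix(baseline, nProteins, nSamp) +
    matrix(stats::rnorm(nProteins * nSamp, 0, noiseSD), nProteins, nSamp)
  dimnames(vals) <- list(proteins, samples)
  if (nComplexes > 0 && coregSD > 0) {
    latent <- matrix(stats::rnorm(nComplexes * nSamp), nComplexes, nSamp)
    inCx <- !is.na(complexOf)
    vals[inCx, ] <- vals[inCx, ] + coregSD * latent[complexOf[inCx], ]
  }

  truth <- list()
  addTruth <- function(type, target, smp, magnitude)
    truth[[length(truth) + 1L]] <<- data.frame(
      type = type, target = target,
      samples = paste(smp, collapse = ","), magnitude = magnitude,
      stringsAsFactors = FALSE)

  injectedPairs <- NULL
  if (!is.null(shiftPairs) && nrow(shiftPairs)) {
    for (i in seq_len(nrow(shiftPairs))) {
      p1 <- shiftPairs$protein1[i]; p2 <- shiftPairs$protein2[i]
      delta <- shiftPairs$delta[i]
      frac <- shiftPairs$fraction[i]
      stopifnot(frac >= 0, frac <= 1)
      k <- max(1L, round(frac * nTest))
      smp <- sample(testIds, k)
      if (splitShift) {
        vals[p1, smp] <- vals[p1, smp] + delta / 2
        vals[p2, smp] <- vals[p2, smp] - delta / 2
      } else {
        vals[p1, smp] <- vals[p1, smp] + delta
      }
      addTruth("pqr_shift", pairKey(p1, p2), smp, delta)
      injectedPairs <- rbind(injectedPairs,
                             data.frame(protein1 = p1, protein2 = p2))
    }
  }
  if (!is.null(corGainPairs) && nrow(corGainPairs)) {
    for (i in seq_len(nrow(corGainPairs))) {
      p1 <- corGainPairs$protein1[i]; p2 <- corGainPairs$protein2[i]
      w <- corGainPairs$weight[i]
      grp <- corGainPairs$group[i]
      smp <- if (grp == "reference") refIds else testIds
      g <- stats::rnorm(length(smp))
      vals[p1, smp] <- vals[p1, smp] + w * g
      vals[p2, smp] <- vals[p2, smp] + w * g
      addTruth("correlation_gain", pairKey(p1, p2), smp, w)
      injectedPairs <- rbind(injectedPairs,
                             data.frame(protein1 = p1, protein2 = p2))
    }
  }
  if (!is.null(hubProteins) && nrow(hubProteins)) {
    for (i in seq_len(nrow(hubProteins))) {
      p <- hubProteins$protein[i]
      delta <- hubProteins$delta[i]
      vals[p, testIds] <- vals[p, testIds] + delta
      addTruth("hub_shift", p, testIds, delta)
    }
  }

  if (missingRate > 0) {
    mask <- stats::runif(length(vals)) < missingRate
    vals[mask] <- NA_real_
  }

  # pair list: all within-complex pairs plus injected pairs
  pairRows <- list()
  if (nComplexes > 0) {
    for (cx in seq_len(nComplexes)) {
      mem <- proteins[which(complexOf == cx)]
      if (length(mem) >= 2L) {
        cmb <- utils::combn(mem, 2L)
        pairRows[[length(pairRows) + 1L]] <- data.frame(
          protein1 = cmb[1L, ], protein2 = cmb[2L, ],
          source = sprintf("CPX%03d", cx), stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(injectedPairs)) {
    injectedPairs$source <- "injected"
    pairRows[[length(pairRows) + 1L]] <- injectedPairs
  }
  pairs <- unique(do.call(rbind, pairRows))

  design <- data.frame(sample_id = samples,
                       group = rep(c("reference", "test"), c(nRef, nTest)),
                       stringsAsFactors = FALSE)
  catalog <- if (nComplexes > 0) data.frame(
    complex_id = sprintf("CPX%03d", complexOf[!is.na(complexOf)]),
    name = sprintf("complex %d", complexOf[!is.na(complexOf)]),
    member_id = proteins[!is.na(complexOf)], stringsAsFactors = FALSE)
  else data.frame(complex_id = character(0), name = character(0),
                  member_id = character(0))

  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(0), target = character(0),
               samples = character(0), magnitude = numeric(0))

  if (is.null(pairs) || !nrow(pairs))
    stop("simulation produced no interaction pairs; increase nComplexes ",
         "or inject pairs")
  dataset <- PQRDataSet(vals, design, pairs)
  list(dataset = dataset, truth = truthDf, catalog = catalog)
}

#' Write a ground-truth table as TSV
#'
#' One row per injected event, joinable to result tables on the `target`
#' column (a pair key or protein identifier).
#'
#' @param truth Ground-truth `data.frame` from [simulatePQRData()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
groundTruthTable <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
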