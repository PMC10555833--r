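refIds <- sprintf("r%02d", 1:10)
testIds <- sprintf("t%02d", 1:6)

# build a matrix + ratios where pair behaviour is fully controlled
mkMat <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- c(refIds, testIds)
  m
}

test_that("pairs with outlying reference ratios are removed", {
  set.seed(1)
  quiet <- c(rnorm(10, 0, 0.05), rnorm(6, 0, 0.05))
  noisyRef <- quiet
  noisyRef[c(2, 5, 8)] <- c(4, -4, 5)       # 3 extreme reference ratios
  mat <- mkMat(list(A = quiet + 20, B = 20 - quiet,
                    C = noisyRef + 20, D = rep(20, 16)))
  pairs <- data.frame(protein1 = c("A", "C"), protein2 = c("B", "D"))
  ratios <- pairLogRatios(mat, pairs)
  st <- referenceStats(ratios, refIds)
  fr <- referenceVariabilityFilter(ratios, st, mat, refIds)
  expect_equal(fr["C::D", "status"], "removed_variability_pair")
  expect_equal(fr["A::B", "status"], "kept")
})

# deterministic mild jitter: evenly spaced, never outside a 2-sigma band
jit <- seq(-0.05, 0.04, by = 0.01)

test_that("pairs containing a variable protein are removed via the 1.4826 band", {
  vals <- c(5.0, 5.1, 4.9, 5.05, 4.95, 5.2, 4.8, 9.0, 9.1, 9.2)
  med <- median(vals)
  band <- 1.4826 * 2 * median(abs(vals - med))
  expect_equal(sum(vals > med + band | vals < med - band), 3L)

  # W co-varies with VAR so the pair *ratio* stays quiet: only the
  # protein-level rule can remove this pair
  mat <- mkMat(list(VAR = c(vals, rep(5, 6)),
                    W = c(vals + jit, rep(5, 6)),
                    A = 20 + c(jit, rep(0, 6)),
                    B = 20 - c(jit, rep(0, 6))))
  pairs <- data.frame(protein1 = c("VAR", "A"), protein2 = c("W", "B"))
  ratios <- pairLogRatios(mat, pairs)
  st <- referenceStats(ratios, refIds)
  fr <- referenceVariabilityFilter(ratios, st, mat, refIds)
  expect_equal(fr["VAR::W", "status"], "removed_variability_protein")
  expect_match(fr["VAR::W", "reason"], "VAR")
  expect_equal(fr["A::B", "status"], "kept")
})

test_that("a degenerate protein MAD collapses the band to the median", {
  vals <- c(rep(0, 7), 10, 10, 10)          # median 0, MAD 0
  mat <- mkMat(list(DEG = c(vals, rep(0, 6)),
                    W = c(vals + jit, rep(0, 6))))
  pairs <- data.frame(protein1 = "DEG", protein2 = "W")
  ratios <- pairLogRatios(mat, pairs)
  st <- referenceStats(ratios, refIds)
  fr <- referenceVariabilityFilter(ratios, st, mat, refIds)
  expect_equal(fr["DEG::W", "status"], "removed_variability_protein")
  expect_match(fr["DEG::W", "reason"], "DEG")
})

test_that("fractional mode scales the removal threshold with reference size", {
  mat <- mkMat(list(A = 20 + c(jit, rep(0, 6)),
                    B = 20 - c(jit, rep(0, 6))))
  ratios <- pairLogRatios(mat, data.frame(protein1 = "A", protein2 = "B"))
  st <- referenceStats(ratios, refIds)
  fr <- referenceVariabilityFilter(ratios, st, mat, refIds,
                                   maxRefOutliers = "auto")
  expect_equal(fr["A::B", "status"], "kept")  # ceil(0.3*10) = 3, none hit
})

test_that("annotation filter removes pairs with excluded proteins, logging reasons", {
  pairs <- S4Vectors::DataFrame(
    pairKey = c("ACTB::X", "Y::Z"), protein1 = c("ACTB", "Y"),
    protein2 = c("X", "Z"))
  cyto <- list(protein_ids = "ACTB", reason = "GO:0005200")
  ribo <- list(protein_ids = c("ACTB", "RPL3"), reason = "GO:0003735")
  af <- annotationFilter(pairs, list(cyto, ribo))
  expect_equal(af["ACTB::X", "status"], "removed_annotation")
  expect_equal(af["ACTB::X", "reason"], "GO:0005200;GO:0003735")
  expect_equal(af["Y::Z", "status"], "kept")
  none <- annotationFilter(pairs, NULL)
  expect_true(all(none$status == "kept"))
})

test_that("contribution test applies the at-least-half rule at threshold 2", {
  mi <- rbind(A = c(s1 = 3, s2 = 2.5, s3 = 0.1, s4 = 0.2),
              B = c(s1 = 0.5, s2 = 0.1, s3 = 0.4, s4 = 1.0),
              C = c(s1 = -2.5, s2 = -3, s3 = -2.2, s4 = -2.4))
  flagged <- c("s1", "s2", "s3", "s4")
  # A exceeds 2 in exactly 2 of 4 flagged samples -> contributes (>= half)
  expect_setequal(contributionTest(flagged, mi, c("A", "B")), "A")
  # both proteins, opposite signs, all samples -> both contribute
  expect_setequal(contributionTest(flagged, mi, c("A", "C")), c("A", "C"))
  # 1 of 3 fails the half rule
  expect_length(contributionTest(c("s2", "s3", "s4"), mi, "A"), 0)
  # neither exceeds 2 anywhere -> no contributors
  expect_length(contributionTest(flagged, mi, "B"), 0)
  # no flagged samples -> empty
  expect_length(contributionTest(character(0), mi, c("A", "B")), 0)
})

test_that("each contributing protein is represented by its best pair", {
  sig <- S4Vectors::DataFrame(
    pairKey = c("A::H", "B::H", "C::H", "X::Y"),
    score = c(12, 30, 9, 7),
    adjP = c(0.01, 0.001, 0.02, 0.03))
  contrib <- list("A::H" = "H", "B::H" = "H", "C::H" = "H",
                  "X::Y" = c("X", "Y"))
  rs <- selectRepresentativePairs(sig, contrib)
  expect_equal(rs["B::H", "status"], "kept")
  expect_equal(rs["A::H", "status"], "merged_into_representative")
  expect_equal(rs["A::H", "representative"], "B::H")
  expect_equal(rs["C::H", "representative"], "B::H")
  expect_equal(rs["X::Y", "status"], "kept")     # disjoint pair untouched
})

test_that("representative ties break by adjusted p then pair key", {
  sig <- S4Vectors::DataFrame(pairKey = c("H::Z", "A::H"),
                              score = c(10, 10), adjP = c(0.02, 0.01))
  rs <- selectRepresentativePairs(sig, list("H::Z" = "H", "A::H" = "H"))
  expect_equal(rs["A::H", "status"], "kept")     # smaller adjP wins
  sig2 <- S4Vectors::DataFrame(pairKey = c("H::Z", "A::H"),
                               score = c(10, 10), adjP = c(0.01, 0.01))
  rs2 <- selectRepresentativePairs(sig2, list("H::Z" = "H", "A::H" = "H"))
  expect_equal(rs2["A::H", "status"], "kept")    # lexicographic key wins
})

test_that("pairs with no contributors are kept and never absorb others", {
  sig <- S4Vectors::DataFrame(pairKey = c("A::B", "A::C"),
                              score = c(20, 10), adjP = c(0.01, 0.02))
  rs <- selectRepresentativePairs(sig, list("A::B" = character(0),
                                            "A::C" = character(0)))
  expect_true(all(rs$status == "kept"))
})

test_that("redundancy resolution collapses a hub to a single representative", {
  sim <- simulatePQRData(nProteins = 60, nRef = 10, nTest = 24,
                         nComplexes = 2, complexSizeRange = c(3, 3),
                         hubProteins = data.frame(protein = "P0030",
                                                  delta = 3),
                         missingRate = 0, seed = 60)
  # hub pair list: the shifted protein against 10 unrelated partners
  mat <- quantMatrix(sim$dataset)
  pairs <- data.frame(protein1 = "P0030",
                      protein2 = sprintf("P%04d", 31:40))
  design <- data.frame(sample_id = colnames(mat),
                       group = as.character(sampleGroups(sim$dataset)))
  ds <- PQRDataSet(mat, design, pairs)
  res <- runPQR(ds, seed = 2, nBackgroundPairs = 1000,
                variabilityFilter = FALSE)
  expect_true(all(res$significant))
  expect_equal(sum(res$status == "representative"), 1L)
  expect_equal(sum(res$status == "merged_into_representative"), 9L)
})

test_that("filters commute with protein relabeling", {
  set.seed(11)
  fx <- tinyFixture(nRef = 10, nTest = 6, nProteins = 10, seed = 12)
  fx$mat[1, 1:3] <- fx$mat[1, 1:3] + 6   # make protein 1 variable
  ratios <- pairLogRatios(fx$mat, fx$pairs)
  st <- referenceStats(ratios, fx$design$sample_id[1:10])
  fr1 <- referenceVariabilityFilter(ratios, st, fx$mat,
                                    fx$design$sample_id[1:10])
  ren <- fx
  rownames(ren$mat) <- paste0("Z", rownames(ren$mat))
  ren$pairs$protein1 <- paste0("Z", ren$pairs$protein1)
  ren$pairs$protein2 <- paste0("Z", ren$pairs$protein2)
  ratios2 <- pairLogRatios(ren$mat, ren$pairs)
  st2 <- referenceStats(ratios2, fx$design$sample_id[1:10])
  fr2 <- referenceVariabilityFilter(ratios2, st2, ren$mat,
                                    fx$design$sample_id[1:10])
  expect_identical(as.character(fr1$status), as.character(fr2$status))
})
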