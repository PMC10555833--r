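test_that("group correlations are pairwise-complete Pearson r", {
  mat <- rbind(X = c(1:10), Y = 2 * (1:10) + 1, Z = -(1:10),
               W = c(1, 2, 3, 100, rep(NA, 6)))
  colnames(mat) <- sprintf("s%02d", 1:10)
  ids <- colnames(mat)
  expect_equal(groupCorrelation(mat, "X", "Y", ids)$r, 1.0)
  expect_equal(groupCorrelation(mat, "X", "Z", ids)$r, -1.0)
  g <- groupCorrelation(mat, "X", "W", ids)
  expect_equal(g$n, 4L)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 100)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(g$r, brute, tolerance = 1e-12)
})

test_that("correlation p-values match the exact t-transform null", {
  expect_equal(correlationPValue(0, 10), 1.0)
  expect_equal(correlationPValue(1, 10), 0)
  expect_equal(correlationPValue(-1, 10), 0)
  # printed worked example: r = 0.76 with 18 samples -> p ~ 2.5e-4.
  # The exact value sits on the 1-significant-figure rounding boundary
  # because the r is itself printed rounded: over r in [0.755, 0.765] the
  # p-value spans [2.2e-4, 2.9e-4], and its lower part prints as 2e-4.
  p76 <- correlationPValue(0.76, 18)
  expect_gt(p76, correlationPValue(0.765, 18))
  expect_lt(p76, correlationPValue(0.755, 18))
  expect_equal(p76, 2.5e-4, tolerance = 0.05)
  expect_equal(signif(correlationPValue(0.7604, 18), 1), 2e-4)
  # oracle: cor.test on data constructed to have a given r
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    ct <- cor.test(x, y, method = "pearson")
    expect_equal(correlationPValue(unname(ct$estimate), n), ct$p.value,
                 tolerance = 1e-12)
  }
})

test_that("correlation p-values agree with a permutation null", {
  set.seed(15)
  n <- 20
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = sqrt(1 - 0.25))
  r <- cor(x, y)
  B <- 20000
  perm <- replicate(B, abs(cor(x, sample(y))) >= abs(r))
  pPerm <- (1 + sum(perm)) / (1 + B)
  pT <- correlationPValue(r, n)
  se <- sqrt(pT * (1 - pT) / B)
  expect_lt(abs(pPerm - pT), 4 * se + 2 / B)
})

test_that("shift classification follows the gain rule with strict thresholds", {
  # printed example: r -0.21 (ns) vs 0.76 (adj p 0.01), delta 0.97 -> gain in B
  expect_equal(classifyShift(-0.21, 0.76, 0.8, 0.01), "gain_in_B")
  # both groups significantly correlated -> no shift by definition
  expect_equal(classifyShift(0.65, 0.95, 0.01, 0.001), "no_shift")
  # gaining-group r at the boundary fails the strict > 0.6 rule
  expect_equal(classifyShift(0.0, 0.59, 0.9, 0.001), "no_shift")
  # delta must exceed 0.6 strictly
  expect_equal(classifyShift(0.05, 0.65, 0.9, 0.001), "no_shift")
  expect_equal(classifyShift(0.76, -0.21, 0.01, 0.8), "gain_in_A")
  expect_equal(classifyShift(NA, 0.9, NA, 0.001), "untestable")
})

test_that("corShift recovers injected correlation gains with few false calls", {
  gains <- data.frame(protein1 = sprintf("P%04d", 101:105),
                      protein2 = sprintf("P%04d", 106:110),
                      weight = 1.0, group = "test")
  sim <- simulatePQRData(nProteins = 110, nRef = 23, nTest = 18,
                         nComplexes = 20, complexSizeRange = c(5, 5),
                         coregSD = 0, corGainPairs = gains,
                         missingRate = 0, seed = 21)
  cs <- corShift(sim$dataset)
  gainKeys <- with(gains, paste(protein1, protein2, sep = "::"))
  called <- cs$pairKey[cs$classification == "gain_in_B"]
  expect_gte(length(intersect(called, gainKeys)), 4L)
  expect_lte(length(setdiff(called, gainKeys)), 1L)
  # the gains sort ahead of the null pairs, ordered by gaining-group p
  expect_true(all(which(cs$pairKey %in% called) <= length(called)))
})

test_that("swapping the groups swaps gain labels exactly", {
  gains <- data.frame(protein1 = "P0101", protein2 = "P0102",
                      weight = 0.6, group = "test")
  sim <- simulatePQRData(nProteins = 102, nRef = 20, nTest = 20,
                         nComplexes = 10, coregSD = 0,
                         corGainPairs = gains, missingRate = 0, seed = 31)
  ab <- corShift(sim$dataset, groups = c("reference", "test"))
  ba <- corShift(sim$dataset, groups = c("test", "reference"))
  ab <- ab[order(ab$pairKey), ]; ba <- ba[order(ba$pairKey), ]
  expect_identical(ab$classification == "gain_in_B",
                   ba$classification == "gain_in_A")
  expect_equal(ab$deltaR, -ba$deltaR)
})

test_that("identical groups produce no shifts", {
  sim <- simulatePQRData(nProteins = 40, nRef = 10, nTest = 10,
                         nComplexes = 8, missingRate = 0, seed = 41)
  cs <- corShift(sim$dataset, groups = c("test", "test"))
  expect_true(all(cs$classification %in% c("no_shift", "untestable")))
  expect_true(all(cs$deltaR[!is.na(cs$deltaR)] == 0))
})

test_that("classification is invariant to positive affine transforms", {
  sim <- simulatePQRData(nProteins = 40, nRef = 12, nTest = 12,
                         nComplexes = 8, missingRate = 0, seed = 51)
  ds <- sim$dataset
  cs1 <- corShift(ds)
  mat <- quantMatrix(ds)
  mat2 <- mat * 3.7 + rnorm(nrow(mat))  # per-protein intercepts, common slope
  ds2 <- PQRDataSet(mat2,
                    data.frame(sample_id = colnames(ds),
                               group = as.character(sampleGroups(ds))),
                    as.data.frame(interactionPairs(ds)[, c("protein1",
                                                           "protein2")]))
  cs2 <- corShift(ds2)
  cs1 <- cs1[order(cs1$pairKey), ]; cs2 <- cs2[order(cs2$pairKey), ]
  expect_equal(cs1$rA, cs2$rA, tolerance = 1e-12)
  expect_identical(as.character(cs1$classification),
                   as.character(cs2$classification))
})

test_that("a group smaller than minObs is an error", {
  sim <- simulatePQRData(nProteins = 20, nRef = 4, nTest = 10,
                         nComplexes = 4, missingRate = 0, seed = 61)
  expect_error(corShift(sim$dataset), "minObs")
})
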