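# Shared fixture builders; everything is generated in code at test time.

# Small deterministic matrix + design + pairs for IO and pipeline tests.
tinyFixture <- function(nRef = 6, nTest = 8, nProteins = 12, seed = 101) {
  set.seed(seed)
  proteins <- sprintf("PR%02d", seq_len(nProteins))
  samples <- c(sprintf("R%02d", seq_len(nRef)), sprintf("T%02d", seq_len(nTest)))
  mat <- matrix(rnorm(nProteins * (nRef + nTest), 20, 1),
                nProteins, nRef + nTest, dimnames = list(proteins, samples))
  design <- data.frame(sample_id = samples,
                       group = rep(c("reference", "test"), c(nRef, nTest)))
  pairs <- data.frame(protein1 = proteins[seq(1, nProteins - 1, by = 2)],
                      protein2 = proteins[seq(2, nProteins, by = 2)])
  list(mat = mat, design = design, pairs = pairs)
}

writeTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeMatrixTSV <- function(mat, path = tempfile(fileext = ".tsv")) {
  writeQuantMatrix(mat, path)
  path
}

# Independent brute-force modified z: explicit median and MAD loops,
# no vectorized shortcuts shared with the implementation.
bruteModifiedZ <- function(values, refValues) {
  refValues <- refValues[!is.na(refValues)]
  n <- length(refValues)
  srt <- sort(refValues)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else
    (srt[n / 2] + srt[n / 2 + 1]) / 2
  dev <- numeric(n)
  for (i in seq_len(n)) dev[i] <- abs(refValues[i] - med)
  srtd <- sort(dev)
  mad <- if (n %% 2 == 1) srtd[(n + 1) / 2] else
    (srtd[n / 2] + srtd[n / 2 + 1]) / 2
  0.6745 * (values - med) / mad
}

# Independent step-up Benjamini-Hochberg.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Fabricate a reference-stats DataFrame for direct callOutliers tests.
fakeStats <- function(keys, med, mad, testable = TRUE) {
  pp <- strsplit(keys, "::", fixed = TRUE)
  S4Vectors::DataFrame(
    pairKey = keys,
    protein1 = vapply(pp, `[`, character(1), 1L),
    protein2 = vapply(pp, `[`, character(1), 2L),
    nRefObs = 10L, refMedian = med, refMAD = mad,
    testable = rep(testable, length.out = length(keys)),
    status = "testable", row.names = keys)
}
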