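# Internal helpers shared across modules.

# Canonical key for an unordered protein pair; orientation is fixed
# alphabetically so ratio signs and output rows are deterministic.
pairKey <- function(p1, p2) {
  a <- pmin(p1, p2)
  b <- pmax(p1, p2)
  paste(a, b, sep = "::")
}

# Split keys back into the two proteins.
splitPairKey <- function(key) {
  parts <- strsplit(key, "::", fixed = TRUE)
  list(protein1 = vapply(parts, `[`, character(1), 1L),
       protein2 = vapply(parts, `[`, character(1), 2L))
}

# Row-wise median / raw MAD with NA handling. MAD here is the plain median
# of absolute deviations, NOT scaled by 1.4826: the 0.6745 constant in the
# modified z-score already provides the normal-consistency correction.
rowMedianNA <- function(x) {
  apply(x, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  })
}

rowRawMADNA <- function(x, centers) {
  dev <- abs(x - centers)
  rowMedianNA(dev)
}

rawMAD <- function(v, center = stats::median(v, na.rm = TRUE)) {
  stats::median(abs(v - center), na.rm = TRUE)
}

# Normal-consistency constant of the modified z-score (~qnorm(0.75)).
MZ_CONST <- 0.6745
# Reciprocal convention: scales a raw MAD to a standard-deviation estimate.
MAD_SD_CONST <- 1.4826

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lightweight run-log collector used by the pipeline and the CLI.
newRunLog <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  env
}

logLine <- function(log, ...) {
  if (is.null(log)) return(invisible(NULL))
  log$lines <- c(log$lines, paste0(...))
  invisible(NULL)
}
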