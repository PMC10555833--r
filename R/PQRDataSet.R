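#' Construct a PQRDataSet
#'
#' Bundles a log-scale protein abundance matrix, a sample design and a
#' stable-interaction pair list into a [PQRDataSet-class] object. Samples
#' present in the matrix but absent from the design are dropped with a
#' warning; design rows for unknown samples are ignored with a warning.
#' Pairs are deduplicated under unordered equality, self-pairs are dropped
#' with a warning, and pairs whose proteins are not both present in the
#' matrix are retained but flagged `measured = FALSE`.
#'
#' @param matrix Numeric matrix of log-scale abundances; rownames are protein
#'   identifiers, colnames sample identifiers. `NA` marks missing values.
#' @param design A `data.frame` with columns `sample_id` and `group`
#'   (`"reference"` or `"test"`), optionally `subtype`.
#' @param pairs A `data.frame` whose first two columns hold protein
#'   identifiers; an optional `source` column records provenance.
#'
#' @return A validated [PQRDataSet-class].
#' @examples
#' sim <- simulatePQRData(nProteins = 30, nRef = 5, nTest = 6,
#'                        nComplexes = 5, seed = 1)
#' sim$dataset
#' @export
PQRDataSet <- function(matrix, design, pairs) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  storage.mode(matrix) <- "double"
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate protein identifiers: ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]),
               collapse = ", "))
  design <- normalizeDesign(design)

  extra <- setdiff(design$sample_id, colnames(matrix))
  if (length(extra)) {
    warning("design lists ", length(extra),
            " sample(s) not present in the matrix; ignored: ",
            paste(utils::head(extra, 5L), collapse = ", "))
    design <- design[!design$sample_id %in% extra, , drop = FALSE]
  }
  undes <- setdiff(colnames(matrix), design$sample_id)
  if (length(undes)) {
    warning(length(undes),
            " matrix sample(s) absent from the design were dropped: ",
            paste(utils::head(undes, 5L), collapse = ", "))
    matrix <- matrix[, design$sample_id, drop = FALSE]
  } else {
    matrix <- matrix[, design$sample_id, drop = FALSE]
  }
  if (sum(design$group == "reference") < 2L)
    stop("at least 2 reference samples are required after joining the ",
         "design with the matrix")
  if (sum(design$group == "test") < 1L)
    stop("at least 1 test sample is required after joining the design ",
         "with the matrix")

  ip <- normalizePairs(pairs, rownames(matrix))

  cd <- S4Vectors::DataFrame(group = design$group, row.names = design$sample_id)
  if (!is.null(design$subtype)) cd$subtype <- design$subtype
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logAbundance = matrix), colData = cd)
  new("PQRDataSet", se, interactionPairs = ip)
}

# Coerce a user design table into the canonical (sample_id, group, subtype)
# form; group tokens other than reference/test are an error.
normalizeDesign <- function(design) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(design))) {
    if (ncol(design) >= 2L) {
      colnames(design)[1:2] <- c("sample_id", "group")
      if (ncol(design) >= 3L && !"subtype" %in% colnames(design))
        colnames(design)[3L] <- "subtype"
    } else stop("design needs columns sample_id and group")
  }
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(design$group), c("reference", "test"))
  if (length(bad))
    stop("unknown group token(s): ", paste(bad, collapse = ", "),
         " (allowed tokens: reference, test)")
  if (!sum(design$group == "reference"))
    stop("design defines zero reference samples")
  if (!is.null(design$subtype)) design$subtype <- as.character(design$subtype)
  design
}

# Deduplicate a raw two-column pair table under unordered equality and fix
# the alphabetical orientation.
normalizePairs <- function(pairs, proteinIds) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("pair list needs at least two protein columns")
  p1 <- as.character(pairs[[1L]])
  p2 <- as.character(pairs[[2L]])
  src <- if ("source" %in% colnames(pairs)) as.character(pairs$source)
         else if (ncol(pairs) >= 3L) as.character(pairs[[3L]])
         else rep(NA_character_, length(p1))
  keep <- !(is.na(p1) | is.na(p2) | p1 == "" | p2 == "")
  p1 <- p1[keep]; p2 <- p2[keep]; src <- src[keep]
  self <- p1 == p2
  if (any(self)) {
    warning("dropped ", sum(self), " self-pair(s): ",
            paste(utils::head(unique(p1[self]), 5L), collapse = ", "))
    p1 <- p1[!self]; p2 <- p2[!self]; src <- src[!self]
  }
  if (!length(p1)) stop("pair list contains no usable pairs")
  a <- pmin(p1, p2); b <- pmax(p1, p2)
  key <- paste(a, b, sep = "::")
  first <- !duplicated(key)
  # aggregate provenance of duplicates
  srcAgg <- vapply(split(src, key), function(s) {
    s <- unique(s[!is.na(s)])
    if (length(s)) paste(s, collapse = ";") else NA_character_
  }, character(1))
  ip <- S4Vectors::DataFrame(
    protein1 = a[first], protein2 = b[first], pairKey = key[first],
    source = unname(srcAgg[key[first]]),
    measured = a[first] %in% proteinIds & b[first] %in% proteinIds)
  ip <- ip[order(ip$pairKey), , drop = FALSE]
  rownames(ip) <- ip$pairKey
  ip
}
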