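#' Read a protein-by-sample quantitative matrix
#'
#' Parses a delimited text file whose first column holds protein identifiers
#' and whose header row holds sample identifiers. Empty cells, `NA` and
#' `NaN` are treated as missing. When `alreadyLog = FALSE` the raw
#' intensities are log-transformed with `logBase` and non-positive raw
#' values become missing.
#'
#' @param path Path to the file.
#' @param delimiter Field separator (default tab).
#' @param alreadyLog Are the stored values already log-scale? Default `TRUE`.
#' @param logBase Base used when transforming raw values (default 2).
#' @return A numeric matrix (proteins x samples).
#' @examples
#' f <- tempfile()
#' writeLines(c("protein\ts1\ts2", "A\t1\t2", "B\t3\t4"), f)
#' readQuantMatrix(f)
#' @export
readQuantMatrix <- function(path, delimiter = "\t", alreadyLog = TRUE,
                            logBase = 2) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 3L)
    stop("malformed matrix header in ", path,
         ": need a protein-ID column and at least 2 sample columns")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate protein identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  missingTok <- vals == "" | toupper(vals) %in% c("NA", "NAN")
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !missingTok, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s: '%s'",
                 ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]], path,
                 vals[bad[1L, , drop = FALSE]]))
  num[missingTok] <- NA_real_
  num[!is.finite(num)] <- NA_real_
  dimnames(num) <- list(ids, colnames(vals))
  if (!alreadyLog) {
    num[!is.na(num) & num <= 0] <- NA_real_
    num <- log(num, base = logBase)
  }
  num
}

#' Read a sample design table
#'
#' Two-column table (`sample_id`, `group`) with an optional third `subtype`
#' column. Group tokens must be `reference` or `test`. Rows naming samples
#' absent from `sampleIds` are dropped with a warning.
#'
#' @param path Path to the file.
#' @param sampleIds Optional character vector of known sample identifiers
#'   (e.g. `colnames` of the matrix) used to warn about unknown samples.
#' @param delimiter Field separator (default tab).
#' @return A `data.frame` with columns `sample_id`, `group` and optionally
#'   `subtype`.
#' @export
readDesign <- function(path, sampleIds = NULL, delimiter = "\t") {
  if (!file.exists(path)) stop("design file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  design <- normalizeDesign(raw)
  if (!is.null(sampleIds)) {
    extra <- setdiff(design$sample_id, sampleIds)
    if (length(extra)) {
      warning("design lists ", length(extra),
              " unknown sample(s); ignored: ",
              paste(utils::head(extra, 5L), collapse = ", "))
      design <- design[!design$sample_id %in% extra, , drop = FALSE]
    }
    if (!sum(design$group == "reference"))
      stop("design defines zero reference samples after joining with the matrix")
  }
  design
}

#' Read a stable-interaction pair list
#'
#' At least two columns of protein identifiers; an optional `source` column.
#' Pairs are deduplicated under unordered equality, self-pairs dropped with
#' a warning, and pairs with unmeasured proteins flagged.
#'
#' @param path Path to the file.
#' @param proteinIds Character vector of measured protein identifiers.
#' @param delimiter Field separator (default tab).
#' @return A [S4Vectors::DataFrame] with columns `protein1`, `protein2`,
#'   `pairKey`, `source`, `measured`.
#' @export
readPairs <- function(path, proteinIds = character(0), delimiter = "\t") {
  if (!file.exists(path)) stop("pair file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character", comment.char = ""),
    error = function(e) stop("empty or unreadable pair file: ", path))
  if (!nrow(raw)) stop("pair file contains no pairs: ", path)
  normalizePairs(raw, proteinIds)
}

#' Read a flat protein exclusion list
#'
#' One identifier per line (a header line equal to `protein_id` is
#' tolerated). The `reason` (e.g. `"GO:0005200"` for structural cytoskeleton
#' constituents or `"GO:0003735"` for ribosomal proteins) is recorded with
#' every exclusion the list triggers.
#'
#' @param path Path to the file.
#' @param reason Short label describing why these proteins are excluded;
#'   defaults to the file name.
#' @return A list with elements `protein_ids` (character) and `reason`.
#' @export
readExclusionList <- function(path, reason = basename(path)) {
  if (!file.exists(path)) stop("exclusion file not found: ", path)
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[ids != "" & tolower(ids) != "protein_id"]
  if (!length(ids)) stop("exclusion list is empty: ", path)
  list(protein_ids = unique(ids), reason = reason)
}

#' Read a complex-membership catalog
#'
#' Long-format table with columns `complex_id`, `name`, `member_id` (one row
#' per subunit). Complexes with fewer than 2 members are dropped with a
#' warning.
#'
#' @param path Path to the file.
#' @param delimiter Field separator (default tab).
#' @return A `data.frame` with columns `complex_id`, `name`, `member_id`.
#' @export
readComplexCatalog <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("complex catalog not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  need <- c("complex_id", "member_id")
  if (!all(need %in% colnames(raw))) {
    if (ncol(raw) >= 3L) colnames(raw)[1:3] <- c("complex_id", "name", "member_id")
    else stop("complex catalog needs columns complex_id, name, member_id")
  }
  if (!"name" %in% colnames(raw)) raw$name <- raw$complex_id
  raw <- unique(raw[, c("complex_id", "name", "member_id")])
  sizes <- table(raw$complex_id)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("dropped ", length(small), " complex(es) with < 2 members")
    raw <- raw[!raw$complex_id %in% small, , drop = FALSE]
  }
  raw
}

#' Write a result table as TSV
#'
#' Values are written at full precision; list columns are collapsed with
#' commas so the file round-trips through standard spreadsheet tools.
#'
#' @param x A `data.frame` or [S4Vectors::DataFrame].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeResultTable <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]]))
      x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ","),
                       character(1))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a quantitative matrix as TSV
#'
#' Inverse of [readQuantMatrix()] for log-scale matrices; full precision,
#' `NA` for missing values.
#'
#' @param mat Numeric matrix with protein rownames and sample colnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeQuantMatrix <- function(mat, path) {
  df <- data.frame(protein_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1L][is.na(mat)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
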