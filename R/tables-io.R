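## Reading, validating, normalising and filtering abundance tables and
## sample metadata.

sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a taxon abundance table from delimited text
#'
#' Expects one header row of ids and a numeric body; the first column
#' holds the ids of whichever dimension is in rows. Tab or comma
#' delimiters are sniffed from the header unless declared.
#'
#' @param path file path.
#' @param orientation \code{"taxa"} (default; taxa in rows, the
#'   canonical on-disk layout) or \code{"samples"} (samples in rows; the
#'   table is transposed on read).
#' @param sep field delimiter; \code{NULL} to sniff.
#' @param isRelative \code{NA} to auto-detect (all column sums within
#'   \code{1e-6} of 1), or an explicit override.
#' @return An \code{\link{AbundanceTable}} with taxa in rows.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("taxon\ts1\ts2", "t1\t5\t0", "t2\t5\t10"), tf)
#' readAbundanceTable(tf)
#' @export
readAbundanceTable <- function(path, orientation = c("taxa", "samples"),
                               sep = NULL, isRelative = NA) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    mnStop("mnFormatError", sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- sniffSep(path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, row.names = NULL,
               check.names = FALSE, stringsAsFactors = FALSE,
               comment.char = ""),
    error = function(e) mnStop("mnFormatError",
                               sprintf("cannot parse '%s': %s", path,
                                       conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) < 2L)
    mnStop("mnFormatError", "empty abundance table")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    mnStop("mnFormatError", sprintf("duplicated row ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  body <- df[, -1L, drop = FALSE]
  if (anyDuplicated(names(body)))
    mnStop("mnFormatError", "duplicated column ids in header")
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      mnStop("mnFormatError",
             sprintf("non-numeric cell at row '%s', column '%s'",
                     ids[bad], names(body)[j]))
    }
    if (anyNA(col))
      mnStop("mnFormatError",
             sprintf("missing value at row '%s', column '%s'",
                     ids[which(is.na(col))[1L]], names(body)[j]))
    if (any(col < 0))
      mnStop("mnFormatError",
             sprintf("negative abundance at row '%s', column '%s'",
                     ids[which(col < 0)[1L]], names(body)[j]))
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples") m <- t(m)
  AbundanceTable(m, isRelative = isRelative)
}

#' Write an AbundanceTable as TSV (taxa in rows)
#'
#' @param table an \code{AbundanceTable}.
#' @param path output path.
#' @param idColumn name for the leading id column.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceTable <- function(table, path, idColumn = "taxon_id") {
  stopifnot(is(table, "AbundanceTable"))
  df <- data.frame(taxonIds(table), abundances(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from delimited text
#'
#' Requires \code{sample_id} and \code{group} columns; any additional
#' numeric columns are carried along as covariates.
#'
#' @param path file path.
#' @param sep delimiter; \code{NULL} to sniff.
#' @return A \code{data.frame} with one row per sample, \code{group} as
#'   a factor, and covariate columns (if any) numeric.
#' @export
readSampleMetadata <- function(path, sep = NULL) {
  if (!file.exists(path))
    mnStop("mnFormatError", sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- sniffSep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("sample_id", "group") %in% names(df)))
    mnStop("mnFormatError",
           "metadata must contain 'sample_id' and 'group' columns")
  if (anyDuplicated(df$sample_id))
    mnStop("mnFormatError", sprintf("duplicated sample_id: %s",
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  if (any(is.na(df$group) | df$group == ""))
    mnStop("mnFormatError", "missing group value in metadata")
  df$group <- factor(df$group)
  rownames(df) <- NULL
  df
}

#' Align metadata rows to a table's samples
#'
#' Checks that every sample in the table has exactly one metadata row
#' and returns the metadata reordered to match the table's sample
#' order.
#'
#' @param metadata data.frame from \code{\link{readSampleMetadata}}.
#' @param table an \code{AbundanceTable}.
#' @return The reordered metadata.
#' @export
alignMetadata <- function(metadata, table) {
  ids <- sampleIds(table)
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing))
    mnStop("mnFormatError", sprintf("samples without metadata: %s",
                                    paste(missing, collapse = ", ")))
  out <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  droplevels(out)
}

## Numeric covariate columns of a metadata frame (everything except the
## required id/group columns that parses as numeric).
metadataCovariates <- function(metadata) {
  extra <- setdiff(names(metadata), c("sample_id", "group"))
  keep <- extra[vapply(metadata[extra], is.numeric, logical(1))]
  if (!length(keep)) return(NULL)
  m <- as.matrix(metadata[keep])
  rownames(m) <- metadata$sample_id
  m
}

#' Convert a table to relative abundances
#'
#' Divides each sample column by its sum. Idempotent on tables already
#' flagged relative.
#'
#' @param table an \code{AbundanceTable}.
#' @return An \code{AbundanceTable} with \code{isRelative = TRUE}.
#' @examples
#' m <- matrix(c(1, 3, 2, 2), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' abundances(toRelativeAbundance(AbundanceTable(m)))
#' @export
toRelativeAbundance <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  if (isRelative(table)) return(table)
  v <- abundances(table)
  cs <- colSums(v)
  if (any(cs <= 0))
    mnStop("mnDegenerateSampleError",
           sprintf("all-zero sample column: %s",
                   paste(colnames(v)[cs <= 0], collapse = ", ")))
  AbundanceTable(sweep(v, 2, cs, "/"), isRelative = TRUE,
                 taxonomy = taxonomy(table))
}

#' Filter low-abundance taxa
#'
#' Drops every taxon whose mean relative abundance across samples is
#' strictly below \code{minMeanRel} (default 1e-4, i.e. 0.01\%), as
#' well as taxa with zero abundance in all samples. A taxon at exactly
#' the threshold is kept. Survivor abundances are returned on the
#' original scale, un-renormalised, unless \code{renormalize = TRUE}.
#'
#' @param table an \code{AbundanceTable} (counts or relative).
#' @param minMeanRel mean relative-abundance threshold (fraction).
#' @param renormalize re-close surviving columns to 1 after filtering.
#' @return A list with \code{table} (the filtered
#'   \code{AbundanceTable}) and \code{dropped} (character vector of
#'   removed taxon ids).
#' @examples
#' m <- matrix(rep(c(0.5, 0.4995, 5e-05), 3), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
#' filterTaxa(AbundanceTable(m))$dropped
#' @export
filterTaxa <- function(table, minMeanRel = 1e-4, renormalize = FALSE) {
  stopifnot(is(table, "AbundanceTable"))
  if (!isScalarNumber(minMeanRel) || minMeanRel < 0)
    mnStop("mnParameterError", "'minMeanRel' must be a nonnegative number")
  rel <- toRelativeAbundance(table)
  meanRel <- rowMeans(abundances(rel))
  allZero <- rowSums(abundances(table)) == 0
  keep <- !allZero & meanRel >= minMeanRel
  if (!any(keep))
    mnStop("mnDegenerateResultError",
           "filtering removed every taxon; lower 'minMeanRel'")
  dropped <- taxonIds(table)[!keep]
  v <- abundances(table)[keep, , drop = FALSE]
  tax <- taxonomy(table)
  tax <- tax[names(tax) %in% rownames(v)]
  ## after dropping taxa the surviving columns of a relative table no
  ## longer close to 1, so the flag is only TRUE when re-closing
  out <- AbundanceTable(v, isRelative = renormalize, taxonomy = tax)
  list(table = out, dropped = dropped)
}
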