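#' Validate an expression matrix
#'
#' Internal contract shared by all operations: a numeric feature-by-sample
#' matrix with unique, non-empty dimnames and no missing values.
#'
#' @param x numeric matrix, features in rows, samples in columns.
#' @return `x`, invisibly, after validation.
#' @noRd
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (features x samples)")
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("empty matrix: no features or no samples")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must carry feature ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x))
    stop("missing value(s) in expression matrix; imputation is not supported")
  invisible(x)
}

#' Check that labels are consistent with a matrix
#' @noRd
validate_labels <- function(x, labels) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("labels must be a named vector with unique sample ids")
  missing_ids <- setdiff(names(labels), colnames(x))
  if (length(missing_ids))
    stop("labeled sample(s) absent from matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  invisible(labels)
}

#' Read a delimited expression table
#'
#' Reads a tab-separated expression table with a header row and a leading
#' identifier column. Lines starting with `!` (GEO series-matrix metadata)
#' are skipped, so a series-matrix file can be read directly.
#'
#' @param path path to a TSV file.
#' @param orientation `"features_in_rows"` (default; identifier column holds
#'   feature ids, remaining columns are samples) or `"samples_in_rows"` (the
#'   transpose).
#' @return a numeric matrix, features in rows and samples in columns, with
#'   feature ids as rownames and sample ids as colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
#' write_expression_table(m, tf)
#' identical(read_expression_table(tf), m + 0)
#' @seealso [write_expression_table()], [read_labels()]
#' @export
read_expression_table <- function(path,
                                  orientation = c("features_in_rows",
                                                  "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("malformed table: need a header row and at least one data row")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  hdr <- gsub("^\"|\"$", "", hdr)
  if (length(hdr) < 2L)
    stop("malformed header: expected an identifier column plus data columns")
  tab <- utils::read.delim(text = lines[-1L], header = FALSE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), quote = "\"")
  if (ncol(tab) != length(hdr))
    stop("malformed table: header and data rows differ in field count")
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  colnames(vals) <- hdr[-1L]   # after as.matrix: `[.data.frame` mangles dups
  if (!is.numeric(vals))
    stop("non-numeric cell(s) in expression table")
  storage.mode(vals) <- "double"
  if (anyNA(ids) || anyNA(vals))
    stop("missing value(s) in expression table")
  rownames(vals) <- ids
  if (orientation == "samples_in_rows") vals <- t(vals)
  validate_expression(vals)
  vals
}

#' Write an expression table
#'
#' Writes a feature-by-sample matrix as TSV with a `feature_id` identifier
#' column. Values are rendered with 17 significant digits so that a
#' write/read round trip reproduces the doubles bit for bit.
#'
#' @param x numeric matrix (features x samples) with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  validate_expression(x)
  chr <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  out <- cbind(feature_id = rownames(x), chr)
  colnames(out) <- c("feature_id", colnames(x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sample label table
#'
#' Two-column tab-separated table, `sample_id` then `phenotype`, no header
#' required (a header row `sample_id<TAB>phenotype` is tolerated).
#'
#' @param path path to the label file.
#' @return named character vector mapping sample id to phenotype.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(utils::read.delim(path, header = FALSE, sep = "\t",
                                    stringsAsFactors = FALSE),
                  error = function(e) stop("empty label file: ", path))
  if (nrow(tab) == 0L) stop("empty label file: ", path)
  if (ncol(tab) < 2L) stop("label table needs two columns: sample_id, phenotype")
  if (identical(tolower(as.character(tab[1L, 1:2])),
                c("sample_id", "phenotype")))
    tab <- tab[-1L, , drop = FALSE]
  if (nrow(tab) == 0L) stop("label file has a header but no rows: ", path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(tab[[2L]]), ids)
}

#' Write a sample label table
#' @param labels named character vector (sample id -> phenotype).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels),
                                phenotype = unname(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
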