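#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric genes-by-samples matrix that carries
#' optional per-sample `batch` and `cohort` labels. Gene and sample IDs live
#' in the dimnames and must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must have
#'   unique rownames (gene IDs) and colnames (sample IDs).
#' @param batch optional per-sample batch labels (length = ncol).
#' @param cohort optional per-sample cohort labels (length = ncol).
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, batch = NULL, cohort = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have gene rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have sample colnames")
  if (nrow(values) == 0 && is.null(rownames(values))) rownames(values) <- character(0)
  if (ncol(values) == 0 && is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (!is.null(batch)) {
    if (length(batch) != ncol(values))
      stop("`batch` length must equal the number of samples")
    batch <- stats::setNames(as.character(batch), colnames(values))
  }
  if (!is.null(cohort)) {
    if (length(cohort) != ncol(values))
      stop("`cohort` length must equal the number of samples")
    cohort <- stats::setNames(as.character(cohort), colnames(values))
  }
  structure(values, batch = batch, cohort = cohort, class = c("expr_matrix", "matrix"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples\n", nrow(x), ncol(x)))
  b <- attr(x, "batch")
  if (!is.null(b)) cat("  batches:", paste(unique(b), collapse = ", "), "\n")
  invisible(x)
}

as_expr_matrix <- function(x) {
  if (inherits(x, "expr_matrix")) return(x)
  expression_matrix(as.matrix(x))
}

# Rebuild the wrapper after subsetting/altering the underlying matrix,
# carrying batch/cohort for the samples that remain.
expr_like <- function(values, template) {
  b <- attr(template, "batch")
  co <- attr(template, "cohort")
  expression_matrix(values,
    batch  = if (!is.null(b)) unname(b[colnames(values)]) else NULL,
    cohort = if (!is.null(co)) unname(co[colnames(values)]) else NULL)
}

#' Read an expression matrix from disk
#'
#' Supports dense TSV/CSV (genes in rows, first column = gene ID, header =
#' sample IDs) and MatrixMarket MTX with `<stem>.rows.txt` / `<stem>.cols.txt`
#' ID sidecars.
#'
#' @param path file path; format is inferred from the extension unless given.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
      stop("cannot infer format from extension of ", path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rid <- readLines(paste0(stem, ".rows.txt"))
    cid <- readLines(paste0(stem, ".cols.txt"))
    if (length(rid) != nrow(m) || length(cid) != ncol(m))
      stop("MTX ID sidecar length does not match matrix dimensions")
    dimnames(m) <- list(rid, cid)
    return(expression_matrix(m))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene IDs in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m)
}

#' Write an expression matrix to disk
#'
#' @param expr an [expression_matrix()] or plain matrix.
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"mtx"` (MTX writes `.rows.txt` /
#'   `.cols.txt` ID sidecars next to the matrix).
#' @param digits significant digits for the dense text formats.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("tsv", "csv", "mtx"),
                             digits = 10) {
  expr <- as_expr_matrix(expr)
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass_expr(expr), sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(expr), paste0(stem, ".rows.txt"))
    writeLines(colnames(expr), paste0(stem, ".cols.txt"))
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(expr),
                   signif(unclass_expr(expr), digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

unclass_expr <- function(x) {
  attr(x, "batch") <- NULL
  attr(x, "cohort") <- NULL
  attr(x, "class") <- NULL
  x
}
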