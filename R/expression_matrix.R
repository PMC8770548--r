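#' Construct an expression matrix
#'
#' Lightweight container for a gene-by-sample expression matrix together with
#' its scale. Linear scales (`"FPKM"`, `"TPM"`) must be non-negative; `"LOG2"`
#' holds log2(x + pseudocount) values and may be negative after batch
#' adjustment.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers and must be unique.
#' @param scale One of `"FPKM"`, `"TPM"`, `"LOG2"`.
#' @return An object of class `expr_matrix` with elements `values` and
#'   `scale`.
#' @export
expression_matrix <- function(values, scale = c("FPKM", "TPM", "LOG2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_arg("`values` must be a numeric matrix")
  }
  if (anyNA(values)) stop_arg("expression matrix contains NA values")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_arg("expression matrix needs gene (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(values))) stop_arg("duplicated gene identifiers")
  if (anyDuplicated(colnames(values))) stop_arg("duplicated sample identifiers")
  if (scale != "LOG2" && any(values < 0)) {
    stop_arg(scale, "-scale expression must be non-negative")
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "expr_matrix: %d genes x %d samples (%s scale)\n",
    nrow(x$values), ncol(x$values), x$scale
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

as_expr_values <- function(x, scale = NULL) {
  if (inherits(x, "expr_matrix")) {
    if (!is.null(scale) && !(x$scale %in% scale)) {
      stop_arg(
        "expected expression on ", paste(scale, collapse = "/"),
        " scale, got ", x$scale
      )
    }
    x$values
  } else if (is.matrix(x)) {
    x
  } else {
    stop_arg("expected an expr_matrix or a numeric matrix")
  }
}

#' Read an expression matrix from TSV
#'
#' Genes in rows (first column = gene id), samples as remaining columns.
#'
#' @param path File path.
#' @param scale Scale of the stored values.
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(path, scale = c("FPKM", "TPM", "LOG2")) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  expression_matrix(m, match.arg(scale))
}

#' Write an expression matrix to TSV
#'
#' @param expr An `expr_matrix` or matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  m <- as_expr_values(expr)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
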