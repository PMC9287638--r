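#' Gene-by-cell expression matrix container
#'
#' Light container holding a non-negative genes x cells matrix together with a
#' layer tag recording whether the values are raw counts or normalized
#' expression. Genes are rows (symbols as row names), cells are columns
#' (barcodes as column names). Values may be a base matrix or any
#' \pkg{Matrix} sparse matrix; sparse input is kept sparse throughout the
#' pipeline so large matrices are never densified.
#'
#' @param values numeric matrix or \code{Matrix::Matrix}, genes x cells, with
#'   unique non-empty row and column names and no negative or missing entries.
#' @param layer one of \code{"counts"} or \code{"normalized"}.
#' @return an object of class \code{expr_matrix}: a list with elements
#'   \code{values} and \code{layer}.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("G1", "G2"), c("c1", "c2")))
#' em <- expression_matrix(m)
#' dim(em)
#' @export
expression_matrix <- function(values, layer = c("counts", "normalized")) {
  layer <- match.arg(layer)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (inherits(values, "Matrix")) {
    values <- as_dgc(values)
  } else if (!is.matrix(values) || !is.numeric(values)) {
    validation_error("'values' must be a numeric matrix or a Matrix object")
  }
  gn <- rownames(values)
  cn <- colnames(values)
  if (is.null(gn) || anyNA(gn) || any(gn == ""))
    validation_error("gene (row) names are required and must be non-empty")
  if (is.null(cn) && ncol(values) > 0)
    validation_error("cell (column) names are required")
  if (anyDuplicated(gn))
    validation_error("duplicate gene symbol: %s", gn[duplicated(gn)][1L])
  if (!is.null(cn) && anyDuplicated(cn))
    validation_error("duplicate cell barcode: %s", cn[duplicated(cn)][1L])
  vals <- if (inherits(values, "CsparseMatrix")) values@x else values
  if (anyNA(vals)) validation_error("expression matrix contains NA/NaN entries")
  if (length(vals) && min(vals) < 0)
    validation_error("expression matrix contains negative entries")
  structure(list(values = values, layer = layer), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer '%s'%s\n",
              nrow(x$values), ncol(x$values), x$layer,
              if (inherits(x$values, "Matrix")) " (sparse)" else ""))
  invisible(x)
}

# Row-subset keeping class and layer.
subset_genes <- function(em, idx) {
  expression_matrix(em$values[idx, , drop = FALSE], layer = em$layer)
}

# Validate + unwrap: accept expr_matrix, base matrix or Matrix.
as_expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) return(x$values)
  if (is.matrix(x) || inherits(x, "Matrix")) return(x)
  validation_error("expected an expr_matrix or a matrix")
}
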