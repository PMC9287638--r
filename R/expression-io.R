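#' Read a MatrixMarket triplet matrix with gene/barcode sidecars
#'
#' 10x-style trio: a MatrixMarket coordinate file (genes as rows) plus one
#' sidecar line per gene and per barcode. Multi-column sidecars (e.g. 10x
#' \code{genes.tsv} with id and symbol) use the second column as the symbol.
#'
#' @param matrix_path path to the \code{.mtx} coordinate file.
#' @param genes_path path to the gene sidecar (one line per row of the matrix).
#' @param barcodes_path path to the barcode sidecar (one line per column).
#' @return an \code{\link{expression_matrix}} with layer \code{"counts"}.
#' @export
read_mtx_triplet <- function(matrix_path, genes_path, barcodes_path) {
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) format_error("cannot parse '%s': %s",
                                                 matrix_path, conditionMessage(e)))
  m <- as_dgc(m)
  read_sidecar <- function(path, col = 1L) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*$", lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    vapply(fields, function(f) f[[min(col, length(f))]], "")
  }
  genes <- read_sidecar(genes_path, col = 2L)
  barcodes <- read_sidecar(barcodes_path, col = 1L)
  if (length(genes) != nrow(m))
    format_error("gene sidecar has %d entries but matrix declares %d rows",
                 length(genes), nrow(m))
  if (length(barcodes) != ncol(m))
    format_error("barcode sidecar has %d entries but matrix declares %d columns",
                 length(barcodes), ncol(m))
  dimnames(m) <- list(genes, barcodes)
  expression_matrix(m, layer = "counts")
}

#' Read a dense expression table
#'
#' CSV/TSV with gene symbols in the first column and a header row of cell
#' barcodes. The delimiter is sniffed from the file extension (\code{.csv} is
#' comma, anything else tab) unless given. Tables stored cells-as-rows must
#' be flagged explicitly with \code{cells_as_rows = TRUE}; orientation is
#' never guessed.
#'
#' @param path input file.
#' @param sep field delimiter; \code{NULL} to sniff from the extension.
#' @param cells_as_rows transpose after reading (default FALSE).
#' @param layer layer tag of the stored values (default \code{"counts"}).
#' @return an \code{\link{expression_matrix}}.
#' @export
read_dense_table <- function(path, sep = NULL, cells_as_rows = FALSE,
                             layer = "counts") {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) format_error("cannot parse '%s': %s",
                                     path, conditionMessage(e)))
  if (ncol(tab) < 1L) format_error("'%s' has no columns", path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    validation_error("duplicate gene symbol in '%s': %s",
                     path, ids[duplicated(ids)][1L])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (ncol(vals) == 0L)
    warning(sprintf("'%s' contains %d gene(s) but zero cells", path, nrow(vals)))
  if (cells_as_rows) {
    vals <- t(vals)
  }
  expression_matrix(vals, layer = layer)
}

#' Write an expression matrix as MatrixMarket triplet plus sidecars
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param dir output directory (created if missing); writes
#'   \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv}.
#' @return the directory path, invisibly.
#' @export
write_mtx_triplet <- function(em, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- as_dgc(as_expr_values(em))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write / read per-cell activity scores
#'
#' Tab-separated table with columns \code{cell_id}, \code{activity_raw},
#' \code{activity_scaled}, in the input cell order; numbers are written with
#' 17 significant digits so the round trip is exact.
#'
#' @param scores an \code{\link{activity}} result (class
#'   \code{activity_scores}) or a data.frame with those three columns.
#' @param path output file.
#' @return \code{write_scores}: \code{path}, invisibly. \code{read_scores}: a
#'   data.frame with columns \code{cell_id}, \code{activity_raw},
#'   \code{activity_scaled}.
#' @export
write_scores <- function(scores, path) {
  df <- as.data.frame(scores)
  need <- c("cell_id", "activity_raw", "activity_scaled")
  if (!all(need %in% names(df)))
    validation_error("scores must have columns %s", paste(need, collapse = ", "))
  out <- data.frame(cell_id = df$cell_id,
                    activity_raw = sprintf("%.17g", df$activity_raw),
                    activity_scaled = sprintf("%.17g", df$activity_scaled))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "numeric"))
  need <- c("cell_id", "activity_raw", "activity_scaled")
  if (!all(need %in% names(tab)))
    format_error("'%s' lacks required score columns", path)
  tab
}
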