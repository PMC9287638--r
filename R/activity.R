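#' Match network edges to matrix genes
#'
#' Resolves each edge endpoint to a row of the expression matrix by
#' case-insensitive symbol equality. Edges with either endpoint missing from
#' the matrix are dropped (equivalent to treating absent genes as
#' zero-expressed); coverage is always reported so network attrition is
#' visible.
#'
#' @param x an \code{\link{expression_matrix}} or a genes x cells matrix with
#'   symbol row names.
#' @param edges a \code{\link{ppi_edges}} object (or data.frame with columns
#'   \code{from}, \code{to}).
#' @return list with integer index vectors \code{i}, \code{j} (rows of the
#'   matrix, one entry per retained edge), \code{n_edges_used},
#'   \code{gene_coverage} (network genes found / network genes),
#'   \code{edge_coverage} (edges retained / edges).
#' @export
match_genes <- function(x, edges) {
  vals <- as_expr_values(x)
  genes <- toupper(rownames(vals))
  if (is.null(genes)) validation_error("matrix has no gene names")
  if (nrow(edges) == 0L) validation_error("edge list is empty")
  ii <- match(toupper(edges$from), genes)
  jj <- match(toupper(edges$to), genes)
  keep <- !is.na(ii) & !is.na(jj)
  if (!any(keep))
    validation_error("network and matrix share no interacting genes")
  universe <- unique(c(toupper(edges$from), toupper(edges$to)))
  list(i = ii[keep], j = jj[keep],
       n_edges_used = sum(keep),
       gene_coverage = mean(universe %in% genes),
       edge_coverage = mean(keep))
}

#' Raw differentiation activity per cell
#'
#' For each cell \eqn{k}, sums the mass-action weights of the network edges:
#' \eqn{P_k = \sum_{\{i,j\}} x_{ik} x_{jk}} over matched unordered edges
#' (\code{edge_once}, the default), or the literal double sum over a
#' symmetric adjacency matrix, which counts every undirected edge twice
#' (\code{symmetric_double}, exactly twice the edge-once value). Self-loops,
#' if kept upstream, contribute \eqn{x_{ik}^2} once under either convention.
#' The sum streams over the edge list against the (sparse) matrix; the
#' weighted edge matrix is never materialized per cell.
#'
#' @param x an \code{\link{expression_matrix}} (any non-negative layer) or a
#'   genes x cells matrix.
#' @param edges a \code{\link{ppi_edges}} object.
#' @param convention \code{"edge_once"} or \code{"symmetric_double"}.
#' @return named numeric vector of raw activities, one per cell, with
#'   attributes \code{n_edges_used}, \code{gene_coverage},
#'   \code{edge_coverage}.
#' @export
compute_activity <- function(x, edges,
                             convention = c("edge_once", "symmetric_double")) {
  convention <- match.arg(convention)
  vals <- as_expr_values(x)
  v <- if (inherits(vals, "CsparseMatrix")) vals@x else vals
  if (anyNA(v)) validation_error("expression matrix contains NA/NaN")
  if (length(v) && min(v) < 0)
    validation_error("expression matrix contains negative entries")
  m <- match_genes(vals, edges)
  self <- m$i == m$j
  p_pair <- Matrix::colSums(vals[m$i[!self], , drop = FALSE] *
                            vals[m$j[!self], , drop = FALSE])
  p_self <- if (any(self))
    Matrix::colSums(vals[m$i[self], , drop = FALSE]^2) else 0
  raw <- switch(convention,
                edge_once = p_pair + p_self,
                symmetric_double = 2 * p_pair + p_self)
  raw <- as.numeric(raw)
  names(raw) <- colnames(vals)
  attr(raw, "n_edges_used") <- m$n_edges_used
  attr(raw, "gene_coverage") <- m$gene_coverage
  attr(raw, "edge_coverage") <- m$edge_coverage
  raw
}

#' Min-max scale raw activities to [0, 1]
#'
#' \eqn{P^{scaled}_k = (P_k - \min P)/(\max P - \min P)}, the minimum and
#' maximum taken over all cells in the data set. A constant raw vector has no
#' range; by convention it scales to all zeros, with a warning.
#'
#' @param raw numeric vector of raw activities.
#' @return numeric vector in \[0, 1\], same names.
#' @export
scale_activity <- function(raw) {
  if (length(raw) == 0L) validation_error("cannot scale an empty score vector")
  if (anyNA(raw) || any(!is.finite(raw)))
    validation_error("raw activities must be finite")
  rng <- range(raw)
  if (rng[1L] == rng[2L]) {
    warning("raw activity is constant across cells; scaled scores set to 0")
    return(stats::setNames(numeric(length(raw)), names(raw)))
  }
  (raw - rng[1L]) / (rng[2L] - rng[1L])
}

#' Differentiation activity of the PPI network per cell
#'
#' The package's core scorer. Given a non-negative expression matrix and the
#' undirected differentiation PPI network, each edge \eqn{\{i,j\}} is
#' weighted by the mass-action product of its endpoints' expression,
#' \eqn{W_{ij} = A_{ij} x_i x_j}, and the per-cell activity is the sum of
#' all edge weights, subsequently min-max scaled across cells to \[0, 1\].
#' Matrices containing zeros are accepted.
#'
#' @inheritParams compute_activity
#' @return object of class \code{activity_scores}: list with
#'   \code{cell_ids}, \code{raw}, \code{scaled}, \code{n_edges_used},
#'   \code{gene_coverage}, \code{edge_coverage}, \code{convention}.
#' @examples
#' fx <- toy_fixture()
#' act <- activity(fx$matrix, fx$edges)
#' act$raw
#' @export
activity <- function(x, edges,
                     convention = c("edge_once", "symmetric_double")) {
  convention <- match.arg(convention)
  raw <- compute_activity(x, edges, convention = convention)
  scaled <- scale_activity(as.numeric(stats::setNames(raw, NULL)))
  res <- list(cell_ids = names(raw) %||% as.character(seq_along(raw)),
              raw = as.numeric(raw),
              scaled = as.numeric(scaled),
              n_edges_used = attr(raw, "n_edges_used"),
              gene_coverage = attr(raw, "gene_coverage"),
              edge_coverage = attr(raw, "edge_coverage"),
              convention = convention,
              call = match.call())
  class(res) <- "activity_scores"
  res
}

#' Fast activity approximation on highly variable features
#'
#' Selects the top \code{n_hvf} genes by vst standardized variance on the
#' raw counts, normalizes the full matrix, restricts the normalized matrix
#' to the selected genes, and scores that reduced matrix against the same
#' (unreduced) edge list. Normalization is computed on the full matrix
#' before subsetting, never recomputed from reduced totals.
#'
#' @param counts counts-layer \code{\link{expression_matrix}}.
#' @param edges a \code{\link{ppi_edges}} object.
#' @param n_hvf number of highly variable features (default 2000, clamped to
#'   the gene count).
#' @param normalization \code{"lognorm"} (library-size log1p) or
#'   \code{"offset"} (zero-free offset log2 variant).
#' @param scale_factor,offset normalization parameters, see
#'   \code{\link{lognormalize}} and \code{\link{offset_lognormalize}}.
#' @param loess_span,clip vst parameters, see \code{\link{select_hvf}}.
#' @inheritParams compute_activity
#' @return an \code{activity_scores} object; element \code{hvf} holds the
#'   \code{\link{select_hvf}} result.
#' @export
activity_hvf <- function(counts, edges, n_hvf = 2000L,
                         normalization = c("lognorm", "offset"),
                         convention = c("edge_once", "symmetric_double"),
                         scale_factor = 1e4, offset = 1.1,
                         loess_span = 0.3, clip = NULL) {
  normalization <- match.arg(normalization)
  convention <- match.arg(convention)
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$layer != "counts")
    validation_error("activity_hvf selects features on a counts-layer matrix")
  hvf <- select_hvf(counts, n = n_hvf, loess_span = loess_span, clip = clip)
  norm <- switch(normalization,
                 lognorm = lognormalize(counts, scale_factor = scale_factor),
                 offset = offset_lognormalize(counts, offset = offset,
                                              scale_factor = scale_factor))
  reduced <- subset_genes(norm, match(hvf$selected, rownames(norm$values)))
  res <- activity(reduced, edges, convention = convention)
  res$hvf <- hvf
  res$call <- match.call()
  res
}

#' @export
print.activity_scores <- function(x, ...) {
  cat(sprintf("Differentiation activity over %d cells (%s convention)\n",
              length(x$raw), x$convention))
  cat(sprintf("  edges used: %d | gene coverage: %.1f%% | edge coverage: %.1f%%\n",
              x$n_edges_used, 100 * x$gene_coverage, 100 * x$edge_coverage))
  cat(sprintf("  raw activity: min %.4g, median %.4g, max %.4g\n",
              min(x$raw), stats::median(x$raw), max(x$raw)))
  if (!is.null(x$hvf))
    cat(sprintf("  HVF approximation on top %d features\n", x$hvf$n_selected))
  invisible(x)
}

#' @export
summary.activity_scores <- function(object, ...) {
  out <- list(n_cells = length(object$raw),
              convention = object$convention,
              n_edges_used = object$n_edges_used,
              gene_coverage = object$gene_coverage,
              edge_coverage = object$edge_coverage,
              raw = summary(object$raw),
              scaled = summary(object$scaled))
  class(out) <- "summary.activity_scores"
  out
}

#' @export
print.summary.activity_scores <- function(x, ...) {
  cat(sprintf("Differentiation activity: %d cells, %d edges (%s)\n",
              x$n_cells, x$n_edges_used, x$convention))
  cat(sprintf("Network coverage: %.1f%% of genes, %.1f%% of edges\n",
              100 * x$gene_coverage, 100 * x$edge_coverage))
  cat("Raw activity:\n"); print(x$raw)
  cat("Scaled activity:\n"); print(x$scaled)
  invisible(x)
}

#' @export
as.data.frame.activity_scores <- function(x, ...) {
  data.frame(cell_id = x$cell_ids,
             activity_raw = x$raw,
             activity_scaled = x$scaled,
             stringsAsFactors = FALSE)
}

#' @export
plot.activity_scores <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::hist(x$scaled, breaks = "FD", col = "grey80",
                 main = "Scaled activity", xlab = "activity (scaled)", ...)
  graphics::plot(sort(x$raw), seq_along(x$raw) / length(x$raw), type = "s",
                 xlab = "raw activity", ylab = "ECDF",
                 main = "Raw activity ECDF", ...)
  invisible(x)
}
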