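#' End-to-end scoring pipeline
#'
#' Read an expression matrix and an edge list, filter cells then genes,
#' normalize, score every cell, and optionally write the score table and a
#' JSON run report. Deterministic given inputs and configuration; every
#' parameter that affects the output appears in the report.
#'
#' @param matrix either an \code{\link{expression_matrix}}, a path to a
#'   dense CSV/TSV table, or a directory / named list containing
#'   \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv}.
#' @param edges a \code{\link{ppi_edges}} object or path to an edge-list TSV.
#' @param filter a \code{\link{filter_config}}; \code{NULL} skips QC
#'   filtering entirely.
#' @param normalization \code{"lognorm"}, \code{"offset"}, or \code{"none"}
#'   (input already normalized).
#' @param n_hvf optional: score on the top-n highly variable features
#'   instead of all genes.
#' @param convention edge-sum convention, see \code{\link{compute_activity}}.
#' @param scale_factor,offset normalization parameters.
#' @param out_scores optional path for the score TSV.
#' @param out_report optional path for the JSON report.
#' @return list with \code{scores} (an \code{activity_scores} object) and
#'   \code{report} (named list).
#' @export
run_pipeline <- function(matrix, edges, filter = filter_config(),
                         normalization = c("lognorm", "offset", "none"),
                         n_hvf = NULL,
                         convention = c("edge_once", "symmetric_double"),
                         scale_factor = 1e4, offset = 1.1,
                         out_scores = NULL, out_report = NULL) {
  normalization <- match.arg(normalization)
  convention <- match.arg(convention)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("[stage %s] %s", name, conditionMessage(e)),
                          class = class(e)))
    })
  }
  report <- list(tool = "diffact", version = as.character(utils::packageVersion("diffact")),
                 parameters = list(normalization = normalization,
                                   convention = convention,
                                   scale_factor = scale_factor,
                                   offset = offset,
                                   n_hvf = n_hvf,
                                   filter = if (is.null(filter)) NULL
                                            else unclass(filter)))

  em <- stage("read_matrix", {
    if (inherits(matrix, "expr_matrix")) matrix
    else if (is.list(matrix))
      read_mtx_triplet(matrix$matrix, matrix$genes, matrix$barcodes)
    else if (dir.exists(matrix))
      read_mtx_triplet(file.path(matrix, "matrix.mtx"),
                       file.path(matrix, "genes.tsv"),
                       file.path(matrix, "barcodes.tsv"))
    else read_dense_table(matrix)
  })
  el <- stage("read_edges", {
    if (inherits(edges, "ppi_edges")) edges else read_edge_list(edges)
  })
  report$input <- list(n_genes = nrow(em), n_cells = ncol(em),
                       n_edges = nrow(el))

  if (!is.null(filter)) {
    em <- stage("filter_cells", filter_cells(em, filter))
    report$filter_cells <- attr(em, "report")
    em <- stage("filter_genes", filter_genes(em, filter))
    report$filter_genes <- attr(em, "report")
  }

  scores <- if (!is.null(n_hvf)) {
    stage("activity_hvf",
          activity_hvf(em, el, n_hvf = n_hvf,
                       normalization = if (normalization == "none") "lognorm"
                                       else normalization,
                       convention = convention,
                       scale_factor = scale_factor, offset = offset))
  } else {
    norm <- stage("normalize", switch(normalization,
      lognorm = lognormalize(em, scale_factor = scale_factor),
      offset = offset_lognormalize(em, offset = offset,
                                   scale_factor = scale_factor),
      none = {
        if (em$layer == "counts") em$layer <- "normalized"
        em
      }))
    stage("activity", activity(norm, el, convention = convention))
  }
  report$scores <- list(n_cells = length(scores$raw),
                        n_edges_used = scores$n_edges_used,
                        gene_coverage = scores$gene_coverage,
                        edge_coverage = scores$edge_coverage)

  if (!is.null(out_scores)) stage("write_scores", write_scores(scores, out_scores))
  if (!is.null(out_report))
    stage("write_report",
          jsonlite::write_json(report, out_report, auto_unbox = TRUE,
                               digits = NA, null = "null", pretty = TRUE))
  list(scores = scores, report = report)
}
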