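#' Quality-control filter configuration
#'
#' Defaults follow common droplet scRNA-seq practice: cells are kept when
#' their detected-feature count lies in \[200, 3000\] (lower bound removes
#' debris/empty droplets, upper bound doublets), their total counts do not
#' exceed 12000, and their mitochondrial fraction is at most 5\%; genes are
#' kept when detected in at least 3 cells.
#'
#' @param min_features_per_cell lower bound on detected features (default 200).
#' @param max_features_per_cell upper bound on detected features (default 3000).
#' @param max_counts_per_cell upper bound on per-cell total counts
#'   (default 12000).
#' @param max_mito_fraction upper bound on the mitochondrial count fraction
#'   (default 0.05).
#' @param min_cells_per_gene minimum number of cells a gene must be detected
#'   in (default 3, inclusive).
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes
#'   (default \code{"MT-"}).
#' @return a list of class \code{filter_config}.
#' @export
filter_config <- function(min_features_per_cell = 200L,
                          max_features_per_cell = 3000L,
                          max_counts_per_cell = 12000L,
                          max_mito_fraction = 0.05,
                          min_cells_per_gene = 3L,
                          mito_prefix = "MT-") {
  if (min_features_per_cell >= max_features_per_cell)
    validation_error("min_features_per_cell must be below max_features_per_cell")
  if (min_features_per_cell < 0 || max_counts_per_cell < 0 ||
      min_cells_per_gene < 0)
    validation_error("filter bounds must be non-negative")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    validation_error("max_mito_fraction must lie in [0, 1]")
  structure(list(min_features_per_cell = as.integer(min_features_per_cell),
                 max_features_per_cell = as.integer(max_features_per_cell),
                 max_counts_per_cell = as.numeric(max_counts_per_cell),
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 mito_prefix = mito_prefix),
            class = "filter_config")
}

#' Filter cells on detected features, total counts and mitochondrial content
#'
#' A cell is retained when all hold: detected features within
#' \[min, max\], total counts at or below the maximum, and mitochondrial
#' fraction at or below the maximum. The attached report counts removals per
#' criterion (a cell failing several counts towards each).
#'
#' @param em counts-layer \code{\link{expression_matrix}}.
#' @param config a \code{\link{filter_config}}.
#' @return filtered \code{expression_matrix} with attribute \code{report}.
#' @export
filter_cells <- function(em, config = filter_config()) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$layer != "counts")
    validation_error("filter_cells expects a counts-layer matrix")
  x <- em$values
  nfeat <- Matrix::colSums(x > 0)
  total <- Matrix::colSums(x)
  mito_rows <- startsWith(toupper(rownames(x)), toupper(config$mito_prefix))
  mito <- if (any(mito_rows)) Matrix::colSums(x[mito_rows, , drop = FALSE])
          else numeric(ncol(x))
  mito_frac <- ifelse(total > 0, mito / total, 0)

  low  <- nfeat < config$min_features_per_cell
  high <- nfeat > config$max_features_per_cell
  cnt  <- total > config$max_counts_per_cell
  mit  <- mito_frac > config$max_mito_fraction
  keep <- !(low | high | cnt | mit)
  if (!any(keep))
    validation_error("all %d cells removed by quality filters", ncol(x))
  report <- list(n_cells_in = ncol(x),
                 n_cells_out = sum(keep),
                 removed_low_features = sum(low),
                 removed_high_features = sum(high),
                 removed_high_counts = sum(cnt),
                 removed_high_mito = sum(mit))
  out <- expression_matrix(x[, keep, drop = FALSE], layer = "counts")
  attr(out, "report") <- report
  out
}

#' Filter genes by detection across cells
#'
#' Retains genes detected (count > 0) in at least
#' \code{min_cells_per_gene} cells; the boundary is inclusive.
#'
#' @inheritParams filter_cells
#' @return filtered \code{expression_matrix} with attribute \code{report}.
#' @export
filter_genes <- function(em, config = filter_config()) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$layer != "counts")
    validation_error("filter_genes expects a counts-layer matrix")
  ncells <- Matrix::rowSums(em$values > 0)
  keep <- ncells >= config$min_cells_per_gene
  out <- subset_genes(em, which(keep))
  attr(out, "report") <- list(n_genes_in = nrow(em$values),
                              n_genes_out = sum(keep),
                              removed_low_detection = sum(!keep))
  out
}

# Divide each column of a sparse/dense matrix by a per-column scalar.
scale_columns <- function(x, divisor) {
  if (inherits(x, "CsparseMatrix")) {
    x@x <- x@x / rep.int(divisor, diff(x@p))
    x
  } else {
    sweep(x, 2L, divisor, "/")
  }
}

#' Library-size log-normalization
#'
#' Standard scRNA-seq normalization: each count is divided by its cell's
#' total, multiplied by a scale factor and natural-log transformed with a
#' pseudocount of one, \eqn{x' = \ln(1 + c \cdot s / T)}. Zero counts map to
#' zero, so sparsity is preserved.
#'
#' @param em counts-layer \code{\link{expression_matrix}}.
#' @param scale_factor multiplier applied after library-size division
#'   (default 10000).
#' @return normalized-layer \code{expression_matrix}.
#' @export
lognormalize <- function(em, scale_factor = 1e4) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$layer != "counts")
    validation_error("lognormalize expects a counts-layer matrix")
  if (scale_factor <= 0) validation_error("scale_factor must be positive")
  total <- Matrix::colSums(em$values)
  if (any(total == 0))
    validation_error("%d cell(s) have zero total counts; filter cells first",
                     sum(total == 0))
  x <- scale_columns(em$values, total / scale_factor)
  if (inherits(x, "CsparseMatrix")) x@x <- log1p(x@x) else x <- log1p(x)
  expression_matrix(x, layer = "normalized")
}

#' Offset log-normalization (zero-free output)
#'
#' Variant producing a strictly positive matrix: counts are library-size
#' scaled as in \code{\link{lognormalize}}, then an offset greater than one
#' is added before taking base-2 logs, \eqn{x' = \log_2(o + c \cdot s / T)}.
#' A zero count maps to \eqn{\log_2 o > 0}, so downstream methods that
#' reject zeros can consume the result. The activity score itself does not
#' need this: it accepts matrices with zeros.
#'
#' @inheritParams lognormalize
#' @param offset value added before the log; must exceed 1 when zeros are
#'   present (default 1.1).
#' @return normalized-layer \code{expression_matrix} (dense, strictly
#'   positive).
#' @export
offset_lognormalize <- function(em, offset = 1.1, scale_factor = 1e4) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$layer != "counts")
    validation_error("offset_lognormalize expects a counts-layer matrix")
  if (scale_factor <= 0) validation_error("scale_factor must be positive")
  x <- em$values
  has_zero <- if (inherits(x, "CsparseMatrix"))
    length(x@x) < prod(dim(x)) || any(x@x == 0) else any(x == 0)
  if (offset <= 1 && has_zero)
    validation_error(
      "offset must exceed 1 when zero counts are present (log2(%g) <= 0)",
      offset)
  total <- Matrix::colSums(x)
  if (any(total == 0))
    validation_error("%d cell(s) have zero total counts; filter cells first",
                     sum(total == 0))
  dense <- as.matrix(scale_columns(x, total / scale_factor))
  expression_matrix(log2(offset + dense), layer = "normalized")
}

#' Highly variable feature selection (vst)
#'
#' Variance-stabilizing ranking of genes by cell-to-cell variability:
#' \enumerate{
#'   \item per-gene mean \eqn{\mu_i} and variance \eqn{\sigma^2_i} of the raw
#'     counts;
#'   \item local (loess) regression of \eqn{\log_{10}\sigma^2} on
#'     \eqn{\log_{10}\mu} over genes with positive variance, giving an
#'     expected standard deviation \eqn{\hat\sigma_i};
#'   \item counts standardized as
#'     \eqn{z_{ik} = \min((x_{ik}-\mu_i)/\hat\sigma_i,\; \mathrm{clip})};
#'   \item genes ranked by the variance of \eqn{z} (computed about
#'     \eqn{\mu_i}, denominator \eqn{N-1}).
#' }
#' Genes with zero raw variance get standardized variance 0.
#'
#' @param em counts-layer \code{\link{expression_matrix}} with at least two
#'   cells.
#' @param n number of features to select (default 2000; clamped to the gene
#'   count with a warning).
#' @param loess_span span of the mean-variance loess fit (default 0.3).
#' @param clip upper clip for standardized values; default
#'   \eqn{\sqrt{N_\mathrm{cells}}}.
#' @return object of class \code{hvf_selection}: list with
#'   \code{ranked_genes} (all genes, decreasing standardized variance),
#'   \code{selected} (top \code{n}), \code{standardized_variance} (named, in
#'   input gene order), \code{n_selected}.
#' @export
select_hvf <- function(em, n = 2000L, loess_span = 0.3, clip = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$layer != "counts")
    validation_error("select_hvf expects a counts-layer matrix")
  x <- em$values
  ngene <- nrow(x); ncell <- ncol(x)
  if (ncell < 2L) validation_error("select_hvf needs at least 2 cells")
  if (n < 1L) validation_error("n must be at least 1")
  if (n > ngene) {
    warning(sprintf("n = %d exceeds the %d available genes; clamping", n, ngene))
    n <- ngene
  }
  if (is.null(clip)) clip <- sqrt(ncell)

  mu <- Matrix::rowMeans(x)
  ex2 <- Matrix::rowMeans(x^2)
  v <- (ex2 - mu^2) * ncell / (ncell - 1)
  v <- pmax(v, 0)
  pos <- v > 0
  if (sum(pos) < 3L)
    validation_error("fewer than 3 genes with positive variance; local regression underdetermined")
  fit <- stats::loess(log10(v[pos]) ~ log10(mu[pos]), span = loess_span,
                      degree = 2)
  sd_exp <- rep(NA_real_, ngene)
  sd_exp[pos] <- sqrt(10^stats::fitted(fit))

  std_var <- numeric(ngene)
  xs <- as_dgc(x)
  xt <- methods::as(Matrix::t(xs), "CsparseMatrix")   # cells x genes
  gidx <- rep(seq_len(ngene), diff(xt@p))
  ok <- pos[gidx]
  z <- pmin((xt@x[ok] - mu[gidx][ok]) / sd_exp[gidx][ok], clip)
  ssq <- numeric(ngene)
  if (length(z)) {
    agg <- rowsum(z^2, gidx[ok])
    ssq[as.integer(rownames(agg))] <- agg[, 1L]
  }
  nnz <- diff(xt@p)
  z0 <- pmin(-mu / sd_exp, clip)   # contribution of implicit zeros
  std_var[pos] <- (((ncell - nnz) * z0^2)[pos] + ssq[pos]) / (ncell - 1)

  names(std_var) <- rownames(x)
  ord <- order(-std_var)           # stable: ties keep input gene order
  ranked <- rownames(x)[ord]
  structure(list(ranked_genes = ranked,
                 selected = ranked[seq_len(n)],
                 standardized_variance = std_var,
                 n_selected = as.integer(n)),
            class = "hvf_selection")
}

#' @export
print.hvf_selection <- function(x, ...) {
  cat(sprintf("<hvf_selection> top %d of %d genes; leading features: %s\n",
              x$n_selected, length(x$ranked_genes),
              paste(utils::head(x$selected, 5L), collapse = ", ")))
  invisible(x)
}
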