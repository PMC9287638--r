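#' Simulate an Erdos-Renyi PPI network
#'
#' Undirected G(n, p) graph over the first \code{n_network_genes} synthetic
#' symbols (\code{G0001}, \code{G0002}, ...), no self-loops, deduplicated,
#' deterministic per seed.
#'
#' @param n_network_genes number of network genes.
#' @param edge_density probability of each of the \eqn{\binom{n}{2}} pairs.
#' @param seed RNG seed (the generator is a pure function of its arguments).
#' @param genes optional symbol vector to use instead of \code{G000k} names.
#' @return a \code{\link{ppi_edges}} object.
#' @export
simulate_network <- function(n_network_genes, edge_density = 0.1, seed = 1L,
                             genes = NULL) {
  if (n_network_genes < 2L) validation_error("need at least 2 network genes")
  if (edge_density <= 0 || edge_density > 1)
    validation_error("edge_density must lie in (0, 1]")
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(n_network_genes))
  pairs <- utils::combn(genes, 2L)
  draw <- withr::with_seed(seed, stats::runif(ncol(pairs)) < edge_density)
  if (!any(draw))
    validation_error("no edges drawn at density %g; increase edge_density",
                     edge_density)
  ppi_edges(pairs[1L, draw], pairs[2L, draw])
}

#' Simulate a potency-labelled count matrix
#'
#' Negative-binomial baseline counts with per-gene means drawn from a
#' log-normal around \code{nb_mean} (emulating scRNA-seq overdispersion and
#' mean heterogeneity). Each cell \eqn{k} receives a potency label
#' \eqn{p_k}: uniform on \[0, 1\] (\code{"uniform"}) or a balanced binary
#' split (\code{"two_population"}). The expected counts of the first
#' \code{n_network_genes} genes are multiplied by
#' \eqn{1 + \mathrm{effect} \cdot p_k} before drawing — the minimal
#' mechanism by which more pluripotent cells express the differentiation
#' network more broadly.
#'
#' @param n_genes total genes (network genes are the first
#'   \code{n_network_genes}).
#' @param n_network_genes genes participating in the network.
#' @param n_cells number of cells.
#' @param nb_mean median of the per-gene baseline mean distribution
#'   (default 2).
#' @param nb_dispersion negative-binomial size parameter (default 5; smaller
#'   is more overdispersed).
#' @param potency_model \code{"uniform"} or \code{"two_population"}.
#' @param potency_effect multiplicative effect strength (0 = null model).
#' @param seed RNG seed.
#' @return list with \code{matrix} (counts-layer
#'   \code{\link{expression_matrix}}), \code{potency} (numeric labels, one
#'   per cell) and \code{network_genes} (symbols of the boosted genes).
#' @export
simulate_counts <- function(n_genes = 500L, n_network_genes = 100L,
                            n_cells = 300L, nb_mean = 2, nb_dispersion = 5,
                            potency_model = c("uniform", "two_population"),
                            potency_effect = 0, seed = 1L) {
  potency_model <- match.arg(potency_model)
  if (n_network_genes > n_genes)
    validation_error("n_network_genes cannot exceed n_genes")
  if (nb_mean <= 0 || nb_dispersion <= 0)
    validation_error("nb_mean and nb_dispersion must be positive")
  if (potency_effect < 0) validation_error("potency_effect must be >= 0")
  genes <- sprintf("G%04d", seq_len(n_genes))
  cells <- sprintf("C%04d", seq_len(n_cells))
  out <- withr::with_seed(seed, {
    base_mu <- stats::rlnorm(n_genes, meanlog = log(nb_mean), sdlog = 1)
    p <- switch(potency_model,
                uniform = stats::runif(n_cells),
                two_population = sample(rep(c(0, 1), length.out = n_cells)))
    boost <- matrix(1, n_genes, n_cells)
    boost[seq_len(n_network_genes), ] <-
      rep(1 + potency_effect * p, each = n_network_genes)
    mu <- base_mu * boost
    counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                    size = nb_dispersion),
                     n_genes, n_cells, dimnames = list(genes, cells))
    list(counts = counts, p = p)
  })
  list(matrix = expression_matrix(Matrix::Matrix(out$counts, sparse = TRUE),
                                  layer = "counts"),
       potency = stats::setNames(out$p, cells),
       network_genes = genes[seq_len(n_network_genes)])
}

#' Canonical hand-checked regression fixture
#'
#' Frozen 5-gene by 4-cell count matrix and 3-edge network with
#' hand-computed raw and scaled activities. The first cell has expression
#' \code{(1, 2, 3, 0, 0)} over edges \{g1,g2\}, \{g2,g3\}, \{g4,g5\}, giving
#' \eqn{1\cdot2 + 2\cdot3 + 0\cdot0 = 8}.
#'
#' @return list with \code{matrix}, \code{edges}, \code{expected_raw},
#'   \code{expected_scaled}.
#' @export
toy_fixture <- function() {
  m <- matrix(c(1, 2, 3, 0, 0,
                0, 0, 0, 0, 0,
                1, 1, 1, 1, 1,
                2, 0, 1, 3, 2),
              nrow = 5, ncol = 4,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  edges <- ppi_edges(c("g1", "g2", "g4"), c("g2", "g3", "g5"))
  # raw: c1 = 1*2 + 2*3 + 0 = 8 ; c2 = 0 ; c3 = 1+1+1 = 3 ; c4 = 0+0+6 = 6
  raw <- c(c1 = 8, c2 = 0, c3 = 3, c4 = 6)
  scaled <- c(c1 = 1, c2 = 0, c3 = 3 / 8, c4 = 6 / 8)
  list(matrix = expression_matrix(m, layer = "counts"),
       edges = edges, expected_raw = raw, expected_scaled = scaled)
}
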