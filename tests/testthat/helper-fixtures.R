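# Shared fixtures and independent oracles for the test suite.

# Dense quadratic-form oracle: builds the full symmetric adjacency matrix and
# evaluates P_k = x_k' A x_k per cell (literal double sum). Under the
# edge-once convention each off-diagonal edge counts once and self-loops
# once. Independent of the streaming implementation.
dense_activity_oracle <- function(X, edges, convention = "edge_once") {
  genes <- toupper(rownames(X))
  A <- matrix(0, nrow(X), nrow(X))
  for (r in seq_len(nrow(edges))) {
    i <- match(toupper(edges$from[r]), genes)
    j <- match(toupper(edges$to[r]), genes)
    if (is.na(i) || is.na(j)) next
    A[i, j] <- 1
    A[j, i] <- 1
  }
  X <- as.matrix(X)
  quad <- apply(X, 2, function(xk) as.numeric(t(xk) %*% A %*% xk))
  diag_part <- apply(X, 2, function(xk) sum(diag(A) * xk^2))
  if (convention == "edge_once") (quad - diag_part) / 2 + diag_part
  else quad  # symmetric double sum; diagonal already counted once
}

# Random scoring instance: non-negative matrix with zeros plus a random
# undirected network over a superset of the matrix genes.
random_instance <- function(seed, max_genes = 50, max_cells = 20,
                            density = 0.5) {
  set.seed(seed)
  ng <- sample(3:max_genes, 1)
  nc <- sample(2:max_cells, 1)
  genes <- sprintf("R%03d", seq_len(ng))
  X <- matrix(stats::runif(ng * nc), ng, nc,
              dimnames = list(genes, sprintf("c%03d", seq_len(nc))))
  X[stats::runif(length(X)) < 0.4] <- 0   # realistic sparsity
  pairs <- utils::combn(genes, 2)
  keep <- stats::runif(ncol(pairs)) < density
  if (!any(keep)) keep[1] <- TRUE
  list(X = X, edges = ppi_edges(pairs[1, keep], pairs[2, keep]))
}

# Crafted QC fixture: each bad cell violates exactly one default threshold.
# 3200 genes so the 3000-feature upper bound is exercisable; gene MT-1 is
# mitochondrial. Genes gKEEP3/gDROP2 probe the 3-cells-per-gene boundary
# among retained cells.
qc_fixture <- function() {
  ng <- 3200
  genes <- c("MT-1", "gKEEP3", "gDROP2", sprintf("g%04d", seq_len(ng - 3)))
  cells <- c("ok1", "ok2", "ok3", "low_feat", "high_feat", "high_counts",
             "high_mito")
  X <- matrix(0, ng, length(cells), dimnames = list(genes, cells))
  body <- 4:ng  # generic genes
  X[body[1:250], "ok1"] <- 2                        # ~250 feats, ~500 counts
  X[body[251:500], "ok2"] <- 2
  X[body[501:750], "ok3"] <- 2
  X[body[1:150], "low_feat"] <- 1                   # 150 feats < 200
  X[body[1:3100], "high_feat"] <- 1                 # 3100 feats > 3000
  X[body[1:300], "high_counts"] <- 50               # 15000 counts > 12000
  X[body[1:249], "high_mito"] <- 1
  X["MT-1", "high_mito"] <- 100                     # mito fraction 100/349
  X["gKEEP3", c("ok1", "ok2", "ok3")] <- 1          # detected in 3 kept cells
  X["gDROP2", c("ok1", "ok2")] <- 1                 # detected in only 2
  expression_matrix(X, layer = "counts")
}

write_toy_dataset <- function(dir) {
  fx <- toy_fixture()
  write_mtx_triplet(fx$matrix, dir)
  write_edge_list(fx$edges, file.path(dir, "edges.tsv"))
  fx
}

extdata <- function(name) system.file("extdata", name, package = "diffact")
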