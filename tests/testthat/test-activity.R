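test_that("gene matching reports coverage and drops unmatched edges", {
  m <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("c1", "c2")))
  edges <- ppi_edges(c("A", "B"), c("B", "C"))
  mm <- match_genes(m, edges)
  expect_equal(mm$n_edges_used, 1L)
  expect_equal(mm$gene_coverage, 2 / 3)
  expect_equal(mm$edge_coverage, 1 / 2)

  # matrix genes superset of network genes -> everything retained
  m2 <- matrix(1, 3, 1, dimnames = list(c("A", "B", "C"), "c1"))
  expect_equal(match_genes(m2, edges)$edge_coverage, 1)

  # disjoint symbol spaces -> hard error
  m3 <- matrix(1, 2, 1, dimnames = list(c("X", "Y"), "c1"))
  expect_error(match_genes(m3, edges), "share no interacting genes",
               class = "diffact_validation_error")
})

test_that("edge-sum activity matches the hand example and rejects bad input", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  edges <- ppi_edges(c("g1", "g2"), c("g2", "g3"))
  expect_equal(as.numeric(compute_activity(m, edges)), 8)
  expect_equal(as.numeric(compute_activity(m, edges,
                                           convention = "symmetric_double")),
               16)

  zero <- matrix(0, 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  expect_equal(as.numeric(compute_activity(zero, edges)), 0)

  neg <- matrix(c(-1, 2, 3), 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  expect_error(compute_activity(neg, edges), "negative",
               class = "diffact_validation_error")
  nan <- matrix(c(NaN, 2, 3), 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  expect_error(compute_activity(nan, edges), class = "diffact_validation_error")
})

test_that("streaming sums agree with the dense oracle, including self-loops", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    for (conv in c("edge_once", "symmetric_double")) {
      got <- as.numeric(compute_activity(inst$X, inst$edges, convention = conv))
      want <- dense_activity_oracle(inst$X, inst$edges, convention = conv)
      expect_equal(got, unname(want), tolerance = 1e-10)
    }
  }
  # self-loops contribute x^2 once under either convention
  m <- matrix(c(2, 3), 2, 1, dimnames = list(c("A", "B"), "c1"))
  looped <- ppi_edges(c("A", "A"), c("A", "B"), keep_self_loops = TRUE)
  expect_equal(as.numeric(compute_activity(m, looped)), 4 + 6)
  expect_equal(as.numeric(compute_activity(m, looped,
                                           convention = "symmetric_double")),
               4 + 12)
})

test_that("min-max scaling honours its contract including degenerate input", {
  expect_equal(scale_activity(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- scale_activity(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  expect_warning(single <- scale_activity(3), "constant")
  expect_equal(single, 0)
  expect_error(scale_activity(numeric()), class = "diffact_validation_error")
  expect_error(scale_activity(c(1, Inf)), class = "diffact_validation_error")
})

test_that("activity is homogeneous, additive over edge-disjoint networks and monotone", {
  for (seed in 1:15) {
    inst <- random_instance(seed, max_genes = 30)
    raw <- as.numeric(compute_activity(inst$X, inst$edges))

    # scaling one cell by c scales its raw score by c^2
    set.seed(seed + 1000)
    k <- sample(ncol(inst$X), 1); cc <- stats::runif(1, 0.5, 3)
    X2 <- inst$X; X2[, k] <- cc * X2[, k]
    raw2 <- as.numeric(compute_activity(X2, inst$edges))
    expect_equal(raw2[k], cc^2 * raw[k], tolerance = 1e-10)
    expect_equal(raw2[-k], raw[-k], tolerance = 1e-12)

    # union of edge-disjoint networks adds raw activities
    split_at <- max(1, nrow(inst$edges) %/% 2)
    e1 <- ppi_edges(inst$edges$from[1:split_at], inst$edges$to[1:split_at])
    if (split_at < nrow(inst$edges)) {
      rest <- (split_at + 1):nrow(inst$edges)
      e2 <- ppi_edges(inst$edges$from[rest], inst$edges$to[rest])
      both <- as.numeric(compute_activity(inst$X, e1)) +
        as.numeric(compute_activity(inst$X, e2))
      expect_equal(both, raw, tolerance = 1e-12)
    }

    # raising one network gene's expression never lowers the score
    g <- inst$edges$from[1]
    X3 <- inst$X; X3[toupper(rownames(X3)) == g, k] <-
      X3[toupper(rownames(X3)) == g, k] + 1
    raw3 <- as.numeric(compute_activity(X3, inst$edges))
    expect_gte(raw3[k], raw[k])
  }
})

test_that("scaled scores are invariant to the double-count convention", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    a <- activity(inst$X, inst$edges, convention = "edge_once")
    b <- activity(inst$X, inst$edges, convention = "symmetric_double")
    expect_equal(b$raw, 2 * a$raw, tolerance = 1e-12)
    expect_equal(a$scaled, b$scaled, tolerance = 1e-12)
  }
})

test_that("the activity_scores object carries its contract invariants", {
  fx <- toy_fixture()
  a <- activity(fx$matrix, fx$edges)
  expect_s3_class(a, "activity_scores")
  expect_length(a$raw, length(a$cell_ids))
  expect_length(a$scaled, length(a$cell_ids))
  expect_true(all(a$raw >= 0))
  expect_equal(range(a$scaled), c(0, 1))
  expect_equal(a$n_edges_used, 3L)
  expect_equal(a$gene_coverage, 1)
  df <- as.data.frame(a)
  expect_named(df, c("cell_id", "activity_raw", "activity_scaled"))
  expect_output(print(a), "4 cells")
  expect_output(print(summary(a)), "coverage")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(a))
})

test_that("HVF approximation reduces to the full score when all genes are kept", {
  sim <- simulate_counts(n_genes = 120, n_network_genes = 40, n_cells = 80,
                         potency_effect = 2, seed = 13)
  net <- simulate_network(40, edge_density = 0.15, seed = 13)
  full <- activity(lognormalize(sim$matrix), net)
  hv <- activity_hvf(sim$matrix, net, n_hvf = 120)
  expect_equal(hv$scaled, full$scaled, tolerance = 1e-12)
  expect_equal(hv$raw, full$raw, tolerance = 1e-12)

  # an HVF set disjoint from the network is a hard matching error
  set.seed(99)
  off <- matrix(rpois(200, 4), 20, 10,
                dimnames = list(sprintf("OFF%02d", 1:20),
                                sprintf("c%02d", 1:10)))
  expect_error(activity_hvf(expression_matrix(off), net, n_hvf = 10),
               "share no interacting genes",
               class = "diffact_validation_error")
})
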