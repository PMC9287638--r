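test_that("GO annotation parsing filters by term, descendants and taxon", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "SYMBOL\tGO TERM\tTAXON ID",
    "TP53\tGO:0030154\t9606",
    "Tp53\tGO:0030154\t9606",
    "ACTB\tGO:0030154\t10090",
    "GATA3\tGO:0048468\t9606"), path)
  cat_desc <- parse_go_annotations(path, "GO:0030154", taxon = "9606",
                                   descendants = "GO:0048468")
  expect_setequal(cat_desc$identifiers, c("TP53", "GATA3"))

  # no descendants: identity filter on the exact term
  cat_exact <- parse_go_annotations(path, "GO:0030154", taxon = "9606")
  expect_setequal(cat_exact$identifiers, "TP53")

  # membership is case-insensitive after normalization
  expect_true(all(catalog_contains(cat_desc, c("tp53", "Gata3"))))
  expect_false(catalog_contains(cat_desc, "ACTB"))

  # wrong taxon everywhere -> empty-catalog error, distinct from parse failure
  expect_error(parse_go_annotations(path, "GO:0030154", taxon = "7227"),
               class = "diffact_empty_catalog")

  # missing column -> format error naming the column kind
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("SYMBOL\tGO TERM", "TP53\tGO:0030154"), bad)
  expect_error(parse_go_annotations(bad, "GO:0030154"),
               "taxon", class = "diffact_format_error")
})

test_that("SIF parsing preserves rows, skips comments/blanks, flags short rows", {
  path <- tempfile(fileext = ".sif")
  writeLines(c("A\tinteracts-with\tB", "# comment", "",
               "C\tcontrols-state-change-of\tD\textra\tcols"), path)
  rec <- parse_sif(path)
  expect_equal(rec$participant_a, c("A", "C"))
  expect_equal(rec$participant_b, c("B", "D"))

  empty <- tempfile(); writeLines(character(), empty)
  expect_equal(nrow(parse_sif(empty)), 0L)

  short <- tempfile(); writeLines("A\tinteracts-with", short)
  expect_error(parse_sif(short), "line 1", class = "diffact_format_error")
})

test_that("catalog filtering drops chemicals, non-catalog pairs, self-loops and duplicates with full accounting", {
  rec <- data.frame(
    participant_a = c("A", "B", "A", "A", "A"),
    interaction_type = "i",
    participant_b = c("B", "A", "CHEBI:15377", "A", "C"))
  cat_ab <- protein_catalog(c("A", "B"))
  edges <- suppressMessages(filter_to_catalog(rec, cat_ab))
  rep <- attr(edges, "report")
  expect_equal(nrow(edges), 1L)
  expect_equal(sort(unlist(edges[1, c("from", "to")], use.names = FALSE)),
               c("A", "B"))
  expect_equal(rep$chemical_dropped, 1L)
  expect_equal(rep$out_of_catalog_dropped, 1L)   # (A, C)
  expect_equal(rep$self_loop_dropped, 1L)
  expect_equal(rep$duplicate_collapsed, 1L)      # reversed (B, A)
  # conservation: rows in = edges out + all per-reason drops
  expect_equal(rep$input_rows,
               rep$final_edges + rep$chemical_dropped +
                 rep$out_of_catalog_dropped + rep$self_loop_dropped +
                 rep$duplicate_collapsed)

  # catalog covering everything, no chemicals/dups -> pass-through
  rec2 <- data.frame(participant_a = c("A", "B"), interaction_type = "i",
                     participant_b = c("B", "C"))
  edges2 <- suppressMessages(filter_to_catalog(rec2, protein_catalog(c("A", "B", "C"))))
  expect_equal(nrow(edges2), 2L)

  # all chemical -> empty edge list, warned not errored
  rec3 <- data.frame(participant_a = "CHEBI:1", interaction_type = "i",
                     participant_b = "A")
  expect_warning(suppressMessages(filter_to_catalog(rec3, cat_ab)), "empty")
})

test_that("filtering is idempotent, symmetric in participant order, and monotone in the catalog", {
  set.seed(42)
  syms <- LETTERS[1:8]
  rec <- data.frame(participant_a = sample(syms, 60, TRUE),
                    interaction_type = "i",
                    participant_b = sample(syms, 60, TRUE))
  cat_small <- protein_catalog(LETTERS[1:5])
  cat_big <- protein_catalog(LETTERS[1:8])

  e1 <- suppressMessages(suppressWarnings(filter_to_catalog(rec, cat_small)))
  # re-feed the output as records: identical edge set
  refed <- data.frame(participant_a = e1$from, interaction_type = "i",
                      participant_b = e1$to)
  e2 <- suppressMessages(filter_to_catalog(refed, cat_small))
  expect_equal(as.data.frame(e1)[c("from", "to")],
               as.data.frame(e2)[c("from", "to")])

  # permuting participant columns yields the same unordered edge set
  swapped <- data.frame(participant_a = rec$participant_b,
                        interaction_type = "i",
                        participant_b = rec$participant_a)
  e3 <- suppressMessages(suppressWarnings(filter_to_catalog(swapped, cat_small)))
  expect_equal(as.data.frame(e1)[order(e1$from, e1$to), c("from", "to")],
               as.data.frame(e3)[order(e3$from, e3$to), c("from", "to")],
               ignore_attr = TRUE)

  # enlarging the catalog never loses edges
  e4 <- suppressMessages(suppressWarnings(filter_to_catalog(rec, cat_big)))
  expect_gte(nrow(e4), nrow(e1))
  expect_true(all(paste(e1$from, e1$to) %in% paste(e4$from, e4$to)))
})

test_that("edge lists round-trip through disk and collapse reversed duplicates", {
  e <- ppi_edges(c("A", "B"), c("B", "C"))
  path <- tempfile(fileext = ".tsv")
  write_edge_list(e, path)
  back <- read_edge_list(path)
  expect_equal(as.data.frame(back), as.data.frame(e), ignore_attr = TRUE)

  dup <- tempfile(); writeLines(c("A\tB", "B\tA"), dup)
  expect_warning(got <- read_edge_list(dup), "duplicate")
  expect_equal(nrow(got), 1L)

  hdr_only <- tempfile(); writeLines("from\tto", hdr_only)
  expect_equal(nrow(read_edge_list(hdr_only)), 0L)

  bad <- tempfile(); writeLines(c("A\tB", "Conly"), bad)
  expect_error(read_edge_list(bad), "line 2", class = "diffact_format_error")
})

test_that("end-to-end network build on the packaged example matches the hand trace", {
  out <- tempfile(fileext = ".tsv")
  edges <- suppressMessages(
    build_network(extdata("example_annotations.tsv"),
                  extdata("example_interactions.sif"),
                  go_term = "GO:0030154", taxon = "9606",
                  descendants = "GO:0048468", out = out))
  rep <- attr(edges, "report")
  # 11 data rows: 2 chemical, 2 out-of-catalog (EGFR, ACTB), 1 self,
  # 2 duplicates, 4 edges
  expect_equal(rep$input_rows, 11L)
  expect_equal(rep$chemical_dropped, 2L)
  expect_equal(rep$out_of_catalog_dropped, 2L)
  expect_equal(rep$self_loop_dropped, 1L)
  expect_equal(rep$duplicate_collapsed, 2L)
  expect_equal(nrow(edges), 4L)
  expect_equal(as.data.frame(read_edge_list(out)),
               as.data.frame(read_edge_list(extdata("example_edges.tsv"))),
               ignore_attr = TRUE)
})
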