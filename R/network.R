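#' Protein catalog for a GO biological-process term
#'
#' Set of gene symbols (uppercase-normalized) annotated to a GO term; the
#' node universe from which the differentiation PPI network is built.
#'
#' @param identifiers character vector of gene symbols.
#' @param source_term GO accession the catalog was built for.
#' @param taxon NCBI taxon id the annotations were restricted to.
#' @return object of class \code{protein_catalog}.
#' @export
protein_catalog <- function(identifiers, source_term = NA_character_,
                            taxon = NA_character_) {
  ids <- unique(toupper(as.character(identifiers)))
  ids <- ids[!is.na(ids) & ids != ""]
  if (length(ids) == 0L)
    validation_error("protein catalog is empty", class = "diffact_empty_catalog")
  structure(list(identifiers = ids,
                 source_term = source_term,
                 taxon = as.character(taxon)),
            class = "protein_catalog")
}

#' @export
print.protein_catalog <- function(x, ...) {
  cat(sprintf("<protein_catalog> %d symbols (term %s, taxon %s)\n",
              length(x$identifiers), x$source_term, x$taxon))
  invisible(x)
}

#' Case-insensitive catalog membership
#'
#' @param catalog a \code{\link{protein_catalog}}.
#' @param symbols character vector of gene symbols.
#' @return logical vector.
#' @export
catalog_contains <- function(catalog, symbols) {
  toupper(symbols) %in% catalog$identifiers
}

#' Parse a GO annotation export into a protein catalog
#'
#' Reads a tab-separated annotation export (QuickGO-style: one annotation per
#' row with at least a symbol column, a GO-ID column and a taxon column,
#' located by name) and keeps the unique symbols whose rows match the
#' requested taxon and whose GO ID is the target term or any of the supplied
#' descendant terms. Ontology traversal is deliberately out of scope: the
#' descendant-term closure must be supplied by the caller (or the export
#' pre-filtered), which keeps the builder fully offline.
#'
#' @param path path to the tab-separated annotation export (header required).
#' @param go_term GO accession of the target term, e.g. \code{"GO:0030154"}.
#' @param taxon NCBI taxon id to keep (default 9606, human).
#' @param descendants character vector of descendant GO accessions folded
#'   into the target term (default none).
#' @return a \code{\link{protein_catalog}}.
#' @export
parse_go_annotations <- function(path, go_term, taxon = "9606",
                                 descendants = character()) {
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", check.names = FALSE),
    error = function(e) format_error("cannot parse annotation table: %s",
                                     conditionMessage(e)))
  lowered <- tolower(names(tab))
  find_col <- function(pattern, what) {
    hit <- grep(pattern, lowered)
    if (length(hit) == 0L)
      format_error("annotation export lacks a %s column", what)
    hit[1L]
  }
  sym_col <- find_col("symbol", "symbol")
  go_col  <- find_col("go[ ._-]?(term|id)", "GO-ID")
  tax_col <- find_col("taxon", "taxon")

  terms <- c(go_term, descendants)
  keep <- tab[[tax_col]] == as.character(taxon) & tab[[go_col]] %in% terms
  syms <- unique(toupper(tab[[sym_col]][keep]))
  syms <- syms[!is.na(syms) & syms != ""]
  if (length(syms) == 0L)
    validation_error(
      "no annotation rows match term %s (plus %d descendants) and taxon %s",
      go_term, length(descendants), taxon, class = "diffact_empty_catalog")
  protein_catalog(syms, source_term = go_term, taxon = taxon)
}

#' Parse a SIF interaction file
#'
#' Simple interaction format: tab-separated rows
#' \code{participant_a <TAB> interaction_type <TAB> participant_b}, extra
#' columns ignored (extended-SIF dialects). Blank lines and lines starting
#' with \code{#} are skipped. The interaction type is never interpreted: the
#' network is undirected and unweighted.
#'
#' @param path path to the SIF file.
#' @return data.frame with columns \code{participant_a},
#'   \code{interaction_type}, \code{participant_b}, row order preserved.
#' @export
parse_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(participant_a = character(), interaction_type = character(),
                      participant_b = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    format_error("SIF line %d has %d column(s); at least 3 required",
                 lineno[bad], nf[bad])
  }
  data.frame(participant_a   = vapply(fields, `[[`, "", 1L),
             interaction_type = vapply(fields, `[[`, "", 2L),
             participant_b   = vapply(fields, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Undirected PPI edge list
#'
#' Stores unique unordered gene-symbol pairs. Pairs are canonicalized
#' (lexicographically smaller symbol first, uppercase) so that (a,b) and
#' (b,a) collapse to one edge; self-loops are dropped unless
#' \code{keep_self_loops}.
#'
#' @param from,to character vectors of equal length, edge endpoints.
#' @param keep_self_loops keep pairs with identical endpoints (default FALSE).
#' @param warn_duplicates emit a warning when duplicate pairs are collapsed.
#' @return object of class \code{ppi_edges}: data.frame with columns
#'   \code{from}, \code{to}; attribute \code{gene_universe}.
#' @export
ppi_edges <- function(from, to, keep_self_loops = FALSE, warn_duplicates = FALSE) {
  from <- toupper(as.character(from)); to <- toupper(as.character(to))
  if (length(from) != length(to))
    validation_error("'from' and 'to' must have equal length")
  if (length(from) && any(from == "" | to == "" | is.na(from) | is.na(to)))
    validation_error("edge endpoints must be non-empty")
  a <- pmin(from, to); b <- pmax(from, to)
  self <- a == b
  if (!keep_self_loops) { a <- a[!self]; b <- b[!self] }
  dup <- duplicated(paste(a, b, sep = "\r"))
  if (any(dup) && warn_duplicates)
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
  a <- a[!dup]; b <- b[!dup]
  out <- data.frame(from = a, to = b, stringsAsFactors = FALSE)
  structure(out, gene_universe = sort(unique(c(a, b))),
            class = c("ppi_edges", "data.frame"))
}

#' @export
print.ppi_edges <- function(x, ...) {
  cat(sprintf("<ppi_edges> %d undirected edges over %d genes\n",
              nrow(x), length(attr(x, "gene_universe"))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Filter interaction records to catalog proteins
#'
#' Applies the network-assembly rules: a record survives iff neither
#' participant carries a chemical-compound prefix and both participants are
#' members of the protein catalog. Survivors are deduplicated as unordered
#' pairs and self-pairs dropped (by default). Each input row is attributed to
#' exactly one fate, checked in the order chemical, out-of-catalog,
#' self-loop, duplicate, retained, so the counts always sum to the input row
#' count.
#'
#' @param records data.frame from \code{\link{parse_sif}}.
#' @param catalog a \code{\link{protein_catalog}}.
#' @param chemical_prefixes identifier prefixes marking small molecules
#'   (default \code{"CHEBI:"}).
#' @param keep_self_loops retain records whose two participants coincide.
#' @return a \code{\link{ppi_edges}} object with attribute \code{report}: a
#'   list of per-reason drop counts.
#' @export
filter_to_catalog <- function(records, catalog,
                              chemical_prefixes = "CHEBI:",
                              keep_self_loops = FALSE) {
  stopifnot(inherits(catalog, "protein_catalog"))
  a <- toupper(records$participant_a)
  b <- toupper(records$participant_b)
  n <- length(a)
  has_prefix <- function(x) {
    hit <- rep(FALSE, length(x))
    for (p in toupper(chemical_prefixes)) hit <- hit | startsWith(x, p)
    hit
  }
  chem <- has_prefix(a) | has_prefix(b)
  in_cat <- (a %in% catalog$identifiers) & (b %in% catalog$identifiers)
  out_cat <- !chem & !in_cat
  self <- !chem & !out_cat & a == b
  drop_self <- self & !keep_self_loops
  cand <- !chem & !out_cat & !drop_self
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- cand & duplicated(replace(key, !cand, NA_character_), incomparables = NA)
  final <- cand & !dup
  edges <- ppi_edges(lo[final], hi[final], keep_self_loops = keep_self_loops)
  report <- list(input_rows = n,
                 chemical_dropped = sum(chem),
                 out_of_catalog_dropped = sum(out_cat),
                 self_loop_dropped = sum(drop_self),
                 duplicate_collapsed = sum(dup),
                 final_edges = sum(final),
                 final_nodes = length(attr(edges, "gene_universe")))
  message(sprintf(
    "network build: %d rows -> %d edges (%d chemical, %d out-of-catalog, %d self-loop, %d duplicate dropped)",
    n, report$final_edges, report$chemical_dropped,
    report$out_of_catalog_dropped, report$self_loop_dropped,
    report$duplicate_collapsed))
  if (report$final_edges == 0L)
    warning("no interactions survived filtering; edge list is empty")
  attr(edges, "report") <- report
  edges
}

#' Write / read a two-column edge list
#'
#' Tab-separated, one unordered pair per line, with a \code{from<TAB>to}
#' header. Reading tolerates a missing header and collapses duplicate or
#' reversed pairs with a warning, so \code{read_edge_list(write_edge_list(E))}
#' is the identity on edge sets.
#'
#' @param edges a \code{\link{ppi_edges}} object.
#' @param path output (or input) file path.
#' @return \code{read_edge_list} returns a \code{\link{ppi_edges}} object;
#'   \code{write_edge_list} returns \code{path} invisibly.
#' @export
write_edge_list <- function(edges, path) {
  df <- as.data.frame(edges)[, c("from", "to")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param keep_self_loops retain self-pairs when reading.
#' @export
read_edge_list <- function(path, keep_self_loops = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  header_names <- c("from", "to", "gene_a", "gene_b", "participant_a",
                    "participant_b", "source", "target", "node1", "node2")
  if (length(lines)) {
    first <- tolower(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
    if (length(first) >= 2L && all(first[1:2] %in% header_names)) {
      lines <- lines[-1L]; lineno <- lineno[-1L]
    }
  }
  if (length(lines) == 0L)
    return(ppi_edges(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    format_error("edge list line %d has %d column(s); 2 required",
                 lineno[bad], nf[bad])
  }
  ppi_edges(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L),
            keep_self_loops = keep_self_loops, warn_duplicates = TRUE)
}

#' Build the differentiation PPI network
#'
#' End-to-end network construction: parse the GO annotation export into a
#' protein catalog, parse the SIF interaction dump, and keep the unique
#' undirected protein-protein pairs whose two participants both belong to the
#' catalog, excluding chemical compounds.
#'
#' @inheritParams parse_go_annotations
#' @inheritParams filter_to_catalog
#' @param annotations path to the GO annotation export.
#' @param interactions path to the SIF interaction file.
#' @param out optional path: write the resulting edge list there.
#' @return a \code{\link{ppi_edges}} object with build \code{report} attribute.
#' @export
build_network <- function(annotations, interactions, go_term = "GO:0030154",
                          taxon = "9606", descendants = character(),
                          chemical_prefixes = "CHEBI:",
                          keep_self_loops = FALSE, out = NULL) {
  catalog <- parse_go_annotations(annotations, go_term = go_term,
                                  taxon = taxon, descendants = descendants)
  records <- parse_sif(interactions)
  edges <- filter_to_catalog(records, catalog,
                             chemical_prefixes = chemical_prefixes,
                             keep_self_loops = keep_self_loops)
  attr(edges, "report")$catalog_size <- length(catalog$identifiers)
  if (!is.null(out)) write_edge_list(edges, out)
  edges
}
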