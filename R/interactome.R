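# Protein-protein interactome: loading, cleaning, LCC extraction and the
# symmetrically normalized adjacency every downstream network stage consumes.

# Header tokens we recognise when auto-detecting a header row in an edge list.
.ppi_header_tokens <- c(
  "gene", "gene_a", "gene_b", "genea", "geneb", "protein", "protein1",
  "protein2", "protein_a", "protein_b", "source", "target", "from", "to",
  "node1", "node2", "symbol", "symbol_a", "symbol_b", "interactor_a",
  "interactor_b"
)

new_interactome <- function(edges) {
  # edges: tibble(from, to) with from < to, unique, no self-loops
  nodes <- sort(unique(c(edges$from, edges$to)))
  graph <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  structure(
    list(graph = graph, nodes = nodes, edges = edges),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  comps <- igraph::components(x$graph)
  cat(sprintf(
    "<interactome> %d nodes, %d edges, %d connected component(s)\n",
    length(x$nodes), nrow(x$edges), comps$no
  ))
  invisible(x)
}

#' Load a protein-protein interaction network from an edge-list TSV
#'
#' Reads a two-or-more-column tab-separated edge list of gene symbols and
#' returns a cleaned, undirected interactome: symbols are upper-cased and
#' whitespace-stripped, self-loops are dropped, duplicate and reversed pairs
#' are collapsed, and nodes are held in lexicographic order so that all
#' derived matrices are reproducible across runs. A header row is detected
#' when its first two fields match common column names (`gene_a`, `protein1`,
#' `source`, ...); any extra columns (e.g. edge weights or evidence codes)
#' are ignored, as the network is treated as unweighted.
#'
#' @param path Path to the edge-list TSV.
#' @return An object of class `interactome` wrapping an [igraph] graph, the
#'   sorted node vector and a tibble of canonical (`from < to`) edges.
#' @seealso [extract_lcc()], [symmetric_normalize()], [as_edge_tibble()]
#' @export
load_ppi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty PPI edge-list file: %s", path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed edge-list row(s) with fewer than 2 fields at line(s): %s",
      paste(head(bad, 10), collapse = ", ")
    ))
  }

  first <- tolower(trimws(fields[[1]][1:2]))
  has_header <- any(first %in% .ppi_header_tokens)
  if (has_header) fields <- fields[-1]
  if (length(fields) == 0) abort("edge-list file contains only a header row")

  a <- normalize_symbols(vapply(fields, `[`, character(1), 1L))
  b <- normalize_symbols(vapply(fields, `[`, character(1), 2L))

  edges <- tibble(from = pmin(a, b), to = pmax(a, b)) |>
    filter(.data$from != .data$to) |>
    distinct()
  if (nrow(edges) == 0) {
    abort("no edges remain after removing self-loops and duplicates")
  }
  new_interactome(edges)
}

#' Build an interactome directly from an edge table
#'
#' Programmatic counterpart of [load_ppi()]: takes a data frame with two
#' gene-symbol columns and applies the same cleaning rules.
#'
#' @param edges Data frame whose first two columns are gene symbols.
#' @return An `interactome`.
#' @export
as_interactome <- function(edges) {
  stopifnot(ncol(edges) >= 2)
  a <- normalize_symbols(edges[[1]])
  b <- normalize_symbols(edges[[2]])
  tb <- tibble(from = pmin(a, b), to = pmax(a, b)) |>
    filter(.data$from != .data$to) |>
    distinct()
  if (nrow(tb) == 0) abort("no edges remain after cleaning")
  new_interactome(tb)
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest connected component of the
#' interactome, the connected core on which shortest-path distances are
#' defined. Size ties are broken in favour of the component containing the
#' lexicographically smallest node, so the result is deterministic.
#'
#' @param g An `interactome`.
#' @return An `interactome` restricted to the LCC.
#' @export
extract_lcc <- function(g) {
  stopifnot(inherits(g, "interactome"))
  comps <- igraph::components(g$graph)
  sizes <- comps$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    # each candidate's smallest member; nodes are stored sorted, so the first
    # node falling in a candidate component decides the tie
    reps <- vapply(
      biggest,
      function(k) min(g$nodes[comps$membership == k]),
      character(1)
    )
    biggest <- biggest[which.min(reps)]
  }
  keep <- g$nodes[comps$membership == biggest]
  edges <- g$edges |> filter(.data$from %in% keep & .data$to %in% keep)
  new_interactome(edges)
}

#' Binary adjacency matrix of an interactome
#'
#' @param g An `interactome`.
#' @return A symmetric sparse 0/1 matrix indexed by the lexicographic node
#'   order.
#' @export
adjacency <- function(g) {
  stopifnot(inherits(g, "interactome"))
  A <- igraph::as_adjacency_matrix(g$graph, sparse = TRUE)
  A[A > 1] <- 1
  A
}

#' Symmetrically normalized adjacency matrix
#'
#' Computes \eqn{\hat A = D^{-1/2} A D^{-1/2}} where \eqn{A} is the binary
#' adjacency matrix and \eqn{D} the diagonal degree matrix, i.e.
#' \eqn{\hat A_{uv} = 1/\sqrt{\deg(u)\deg(v)}} for every edge \eqn{(u,v)} and
#' 0 elsewhere. This is the propagation operator of the module-learning model.
#'
#' @param g An `interactome` in which every node has degree at least one
#'   (run [extract_lcc()] first).
#' @return A symmetric sparse real matrix with the same indexing as the
#'   adjacency.
#' @export
symmetric_normalize <- function(g) {
  A <- adjacency(g)
  d <- Matrix::rowSums(A)
  if (any(d == 0)) {
    abort(paste0(
      "zero-degree node(s) present: ",
      paste(head(rownames(A)[d == 0], 5), collapse = ", "),
      "; extract the largest connected component first (extract_lcc())"
    ))
  }
  Dinv <- Diagonal(x = 1 / sqrt(d))
  Ahat <- Dinv %*% A %*% Dinv
  dimnames(Ahat) <- dimnames(A)
  Ahat
}

#' Edge table of an interactome
#'
#' @param g An `interactome`.
#' @return A tibble with columns `from` and `to` (canonical `from < to`).
#' @export
as_edge_tibble <- function(g) {
  stopifnot(inherits(g, "interactome"))
  as_tibble(g$edges)
}

#' Node degrees
#'
#' @param g An `interactome`.
#' @return Named integer vector of node degrees in lexicographic node order.
#' @export
node_degrees <- function(g) {
  stopifnot(inherits(g, "interactome"))
  igraph::degree(g$graph)
}

#' Write an interactome back to an edge-list TSV
#'
#' @param g An `interactome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(g, path) {
  readr::write_tsv(as_edge_tibble(g), path, col_names = TRUE)
  invisible(path)
}
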