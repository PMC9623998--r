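#' Build a simple undirected graph from an edge table
#'
#' The graph is the sole input of all subgraph extractors: a simple
#' undirected [igraph][igraph::igraph-package] graph with character vertex
#' names. Vertex names define the deterministic (lexicographic, C-locale)
#' order used for every tie-break in the solvers. Duplicate edges are
#' collapsed; self-loops are rejected.
#'
#' @param edges two-column matrix or data frame of endpoint identifiers
#'   (coerced to character), one row per edge; may have zero rows
#' @param vertices optional character vector of vertex identifiers, to
#'   declare isolated vertices; endpoints are always included
#' @return an igraph object
#' @examples
#' g <- ds_graph(rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))
#' graph_density(g)
#' @export
ds_graph <- function(edges = NULL, vertices = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2)
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (is.vector(edges)) edges <- matrix(edges, ncol = 2, byrow = TRUE)
    if (ncol(edges) != 2L) abort_input("edges must have two columns")
    em <- matrix(trimws(as.character(edges)), ncol = 2)
  }
  if (anyNA(em) || any(em == "")) abort_input("edge endpoints must be non-missing identifiers")
  if (any(em[, 1] == em[, 2])) abort_input("self-loops are not allowed")
  vs <- vsort(unique(c(as.vector(em), as.character(vertices))))
  g <- igraph::make_empty_graph(n = length(vs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vs)
  if (nrow(em) > 0L) {
    g <- igraph::add_edges(g, t(em))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  g
}

# deterministic C-locale sort used for all vertex ordering / tie-breaking
vsort <- function(x) sort(as.character(x), method = "radix")

assert_graph <- function(g) {
  if (!igraph::is_igraph(g)) abort_input("expected an igraph object")
  if (igraph::is_directed(g)) abort_input("graph must be undirected")
  if (is.null(igraph::V(g)$name)) abort_input("graph vertices must be named")
  invisible(g)
}

#' Vertex names in deterministic order
#' @param g an igraph graph
#' @return character vector of vertex names, lexicographically sorted
#' @export
graph_vertices <- function(g) {
  assert_graph(g)
  vsort(igraph::V(g)$name)
}

# edge matrix with each row sorted and rows in lexicographic order
edge_table <- function(g) {
  em <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(em) == 0L) return(em)
  swap <- em[, 1] > em[, 2]
  em[swap, ] <- em[swap, 2:1]
  em[order(em[, 1], em[, 2], method = "radix"), , drop = FALSE]
}

#' Exact density of a graph
#'
#' @param g an igraph graph with at least one vertex
#' @return a [rho] object, |E|/|V|
#' @export
graph_density <- function(g) {
  assert_graph(g)
  if (igraph::vcount(g) < 1L) abort_input("density is undefined for an empty vertex set")
  rho(igraph::ecount(g), igraph::vcount(g))
}

#' Vertex-induced subgraph
#'
#' @param g an igraph graph
#' @param s character vector of vertex names, a subset of the vertices of g
#' @return the induced subgraph on `s` (an igraph object)
#' @export
induced <- function(g, s) {
  assert_graph(g)
  s <- unique(as.character(s))
  missing <- setdiff(s, igraph::V(g)$name)
  if (length(missing) > 0L) {
    abort_input("vertices not in graph: %s", paste(missing, collapse = ", "))
  }
  igraph::induced_subgraph(g, s)
}

# number of graph edges internal to the vertex subset s
induced_edge_count <- function(g, s) {
  igraph::ecount(induced(g, s))
}

#' Exhaustive densest-subgraph oracle
#'
#' Enumerates every non-empty vertex subset (2^|V| - 1 of them) and returns
#' the exact maximum induced density together with *all* subsets attaining
#' it. Intended as an independent correctness oracle for the LP/ILP
#' extractors on small graphs; refuses graphs above the enumeration cap.
#'
#' @param g an igraph graph with 1 <= |V| <= `max_vertices`
#' @param max_vertices enumeration cap (default 15)
#' @return list with `density` (a [rho]) and `sets` (list of sorted
#'   character vectors, every densest vertex subset)
#' @export
brute_force_densest <- function(g, max_vertices = 15L) {
  assert_graph(g)
  n <- igraph::vcount(g)
  if (n < 1L) abort_input("graph has no vertices")
  if (n > max_vertices) {
    abort_input("brute-force oracle refuses graphs with more than %d vertices", max_vertices)
  }
  vs <- graph_vertices(g)
  em <- edge_table(g)
  emask <- if (nrow(em) > 0L) {
    bitwOr(bitwShiftL(1L, match(em[, 1], vs) - 1L),
           bitwShiftL(1L, match(em[, 2], vs) - 1L))
  } else integer(0)
  subsets <- seq_len(2^n - 1)
  sizes <- vapply(subsets, function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L), numeric(1))
  ecnt <- vapply(subsets, function(s) sum(bitwAnd(s, emask) == emask), numeric(1))
  # exact fraction maximisation by cross-multiplication
  best <- 1L
  for (i in subsets) {
    if (ecnt[i] * sizes[best] > ecnt[best] * sizes[i]) best <- i
  }
  is_max <- ecnt * sizes[best] == ecnt[best] * sizes
  sets <- lapply(subsets[is_max], function(s) {
    vs[bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L]
  })
  list(density = rho(ecnt[best], sizes[best]), sets = sets)
}

#' Inclusion-minimal members of a list of vertex sets
#'
#' Helper over the oracle output: the subsets none of whose proper subsets
#' also appears in the list.
#' @param sets list of character vectors
#' @return sublist of inclusion-minimal sets, in lexicographic order
#' @export
minimal_sets <- function(sets) {
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      j != i && length(sets[[j]]) < length(sets[[i]]) && all(sets[[j]] %in% sets[[i]])
    }, logical(1)))
  }, logical(1))
  out <- lapply(sets[keep], vsort)
  out[order(vapply(out, function(s) paste(s, collapse = "\r"), character(1)), method = "radix")]
}

#' Read a graph from an edge-list file
#'
#' Format: one edge per line, two whitespace-separated vertex identifiers.
#' Lines beginning with `#` are comments, except `#vertex <id>` lines which
#' declare isolated vertices.
#'
#' @param path file path
#' @return an igraph graph
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort_input("edge-list file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  vhead <- grepl("^#vertex\\s+", lines)
  extra <- sub("^#vertex\\s+", "", lines[vhead])
  body <- lines[!vhead & !grepl("^#", lines)]
  edges <- if (length(body) > 0L) {
    parts <- strsplit(body, "\\s+")
    bad <- lengths(parts) != 2L
    if (any(bad)) abort_input("malformed edge line: '%s'", body[which(bad)[1]])
    do.call(rbind, parts)
  } else NULL
  ds_graph(edges, vertices = extra)
}

#' Write a graph to an edge-list file
#'
#' @param g an igraph graph
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(g, path) {
  assert_graph(g)
  em <- edge_table(g)
  iso <- setdiff(graph_vertices(g), unique(as.vector(em)))
  lines <- c(
    if (length(iso)) paste("#vertex", iso),
    if (nrow(em)) paste(em[, 1], em[, 2])
  )
  writeLines(lines, path)
  invisible(path)
}
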