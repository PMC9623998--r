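# Densest-subgraph extraction family.
#
# All four methods share one LP core (the classic densest-subgraph LP
# relaxation): an edge variable x_e and a vertex variable y_v, maximising
# sum(x) subject to x_e <= y at both endpoints and sum(y) <= 1. The optimum
# equals the maximum density D, and thresholding y at 1/|V| recovers a
# densest subgraph. The maximal variant adds a binary selector z_v with
# y_v >= z_v / |V|; the minimal variant descends by LP inside shrinking
# vertex sets.
#
# Every extracted vertex set is re-counted in exact rational arithmetic and
# asserted against the expected density before it is returned: LP numerics
# can never change what the package reports.

# epsilon for the y >= 1/|V| membership threshold
MEMBER_EPS <- 1e-6
# slack subtracted from D in >= constraints, far below the 1/|V|^2 density
# granularity for any graph this package targets
DENSITY_SLACK <- 1e-9

# shared constraint block: x_e <= y_i, x_e <= y_j, sum(y) <= 1
lp_core <- function(g) {
  vs <- graph_vertices(g)
  em <- edge_table(g)
  ne <- nrow(em); nv <- length(vs)
  if (ne < 1L) abort_input("graph has no edges: densest-subgraph extraction is undefined")
  nvar <- ne + nv
  A <- matrix(0, 2 * ne + 1, nvar)
  ei <- match(em[, 1], vs); ej <- match(em[, 2], vs)
  rows1 <- seq_len(ne) * 2L - 1L
  rows2 <- seq_len(ne) * 2L
  A[cbind(rows1, seq_len(ne))] <- 1
  A[cbind(rows1, ne + ei)] <- -1
  A[cbind(rows2, seq_len(ne))] <- 1
  A[cbind(rows2, ne + ej)] <- -1
  A[2 * ne + 1, ne + seq_len(nv)] <- 1
  list(A = A, dir = rep("<=", 2 * ne + 1), b = c(rep(0, 2 * ne), 1),
       vs = vs, em = em, ne = ne, nv = nv)
}

#' Solve the densest-subgraph LP relaxation
#'
#' Maximises the total edge mass `sum(x)` subject to `x_e <= y_i`,
#' `x_e <= y_j` for each edge `(i, j)`, `sum(y) <= 1`, and nonnegativity.
#' The optimal objective equals the maximum subgraph density of the graph
#' (within solver tolerance).
#'
#' @param g an igraph graph with at least one edge
#' @return object of class `basic_lp`: `edge_values` (named by
#'   "u|v"), `vertex_values` (named by vertex), `objective`
#' @examples
#' g <- ds_graph(t(combn(as.character(1:4), 2)))  # K4
#' solve_basic_lp(g)$objective                    # 1.5
#' @export
solve_basic_lp <- function(g) {
  assert_graph(g)
  core <- lp_core(g)
  obj <- c(rep(1, core$ne), rep(0, core$nv))
  sol <- lp_solve(obj, core$A, core$dir, core$b)
  if (sol$status != "optimal") {
    abort_solver("BasicLP did not solve to optimality (status %s): solver misconfiguration", sol$status)
  }
  structure(list(
    edge_values = stats::setNames(sol$solution[seq_len(core$ne)],
                                  paste(core$em[, 1], core$em[, 2], sep = "|")),
    vertex_values = stats::setNames(sol$solution[core$ne + seq_len(core$nv)], core$vs),
    objective = sol$objective,
    n_vertices = core$nv
  ), class = "basic_lp")
}

#' Extract a densest subgraph from an optimal LP solution
#'
#' Selects the vertices with `y_i >= 1/|V| - eps` and verifies by exact
#' recount that the induced density matches the LP objective. Any optimal
#' solution's threshold set induces a densest subgraph, so the recount is a
#' hard assertion, not a heuristic.
#'
#' @param sol a `basic_lp` solution for `g`
#' @param g the graph `sol` was solved on
#' @param eps membership tolerance (default 1e-6)
#' @return a [subgraph_result] with method tag `"ds"`
#' @export
extract_densest <- function(sol, g, eps = MEMBER_EPS) {
  assert_graph(g)
  if (!inherits(sol, "basic_lp")) abort_input("sol must come from solve_basic_lp()")
  nv <- igraph::vcount(g)
  if (sol$n_vertices != nv || !setequal(names(sol$vertex_values), igraph::V(g)$name)) {
    abort_input("LP solution does not match this graph")
  }
  s <- names(sol$vertex_values)[sol$vertex_values >= 1 / nv - eps]
  res <- subgraph_result(g, s, method = "ds")
  if (abs(rho_value(res$density) - sol$objective) > 1e-6 * max(1, sol$objective)) {
    abort_solver(
      "extracted subgraph density %s disagrees with LP objective %.8f",
      format(res$density), sol$objective)
  }
  res
}

#' A densest subgraph (DS method)
#'
#' One LP solve plus threshold extraction. Which densest subgraph is
#' returned depends on the solver path (deterministic for this package,
#' but not canonical); use [find_all_minimal_densest] or
#' [find_maximal_densest_ilp] for canonical outputs.
#'
#' @param g an igraph graph with at least one edge
#' @return a [subgraph_result] with method tag `"ds"`
#' @export
find_densest <- function(g) {
  extract_densest(solve_basic_lp(g), g)
}

# exact maximum density via one LP + verified extraction
max_density <- function(g) find_densest(g)$density

#' One minimal densest subgraph
#'
#' A densest subgraph none of whose proper induced subgraphs is also
#' densest, found by greedy LP descent: starting from an extracted
#' densest subgraph S, look for a densest subgraph of the same density
#' inside S minus one vertex and shrink to it; when no single-vertex
#' removal preserves the maximum density D, no proper subset of S can be
#' densest (any such subset would survive inside some S minus v), so S
#' is inclusion-minimal. Candidate removals are scanned
#' largest-identifier-first, a deterministic order that steers ties
#' between disjoint equal candidates to the lexicographically least one.
#' The descent uses at most |S| shrink rounds of at most |S| LP solves.
#'
#' @param g an igraph graph with at least one edge
#' @return a [subgraph_result] with method tag `"min-ds"`
#' @export
find_one_minimal_densest <- function(g) {
  assert_graph(g)
  first <- find_densest(g)
  D <- first$density
  s <- first$vertices
  repeat {
    if (length(s) <= 2L) break
    removed <- FALSE
    for (v in rev(s)) {
      rest <- setdiff(s, v)
      # cheap exact check first: is S minus v itself still densest?
      ec <- induced_edge_count(g, rest)
      if (rho_cmp(rho(ec, length(rest)), D) == 0) {
        s <- rest
        removed <- TRUE
        break
      }
      if (ec == 0L) next
      cand <- find_densest(induced(g, rest))
      if (rho_cmp(cand$density, D) == 0) {
        s <- cand$vertices
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  res <- subgraph_result(g, s, method = "min-ds")
  if (rho_cmp(res$density, D) != 0) {
    abort_solver("minimal densest candidate has density %s, expected %s",
                 format(res$density), format(D))
  }
  res
}

#' All minimal densest subgraphs (Min-DS method)
#'
#' Iterative peeling: find a minimal densest subgraph of the current graph,
#' stop as soon as its density drops below the maximum density D of the
#' original graph, otherwise record it and delete its vertices. Distinct
#' minimal densest subgraphs cannot intersect (their intersection would be
#' a smaller densest subgraph), so peeling enumerates exactly all of them,
#' pairwise vertex-disjoint.
#'
#' @inheritParams find_one_minimal_densest
#' @return a `subgraph_list` of [subgraph_result]s, method tag `"min-ds"`
#' @export
find_all_minimal_densest <- function(g) {
  assert_graph(g)
  D <- max_density(g)
  cur <- g
  out <- list()
  while (igraph::ecount(cur) > 0L) {
    r <- find_one_minimal_densest(cur)
    if (rho_cmp(r$density, D) < 0) break
    out[[length(out) + 1L]] <- r
    cur <- igraph::delete_vertices(cur, r$vertices)
  }
  subgraph_list(out, method = "min-ds", D = D)
}

#' The maximal densest subgraph via ILP (Max-DS method)
#'
#' Solves: maximise `sum(z)` subject to the LP core, `sum(x) >= D`, and
#' `y_v >= z_v / |V|`. The selected vertices induce the unique maximal
#' densest subgraph — the union of all densest subgraphs.
#'
#' @param g an igraph graph with at least one edge
#' @param D the exact maximum density of `g` (a [rho]); computed via the
#'   LP if omitted
#' @return a [subgraph_result] with method tag `"max-ds"`
#' @export
find_maximal_densest_ilp <- function(g, D = NULL) {
  assert_graph(g)
  if (is.null(D)) D <- max_density(g)
  if (!inherits(D, "rho")) abort_input("D must be a rho density")
  core <- lp_core(g)
  ne <- core$ne; nv <- core$nv
  nvar <- ne + 2 * nv
  A <- cbind(core$A, matrix(0, nrow(core$A), nvar - ncol(core$A)))
  dens_row <- c(rep(1, ne), rep(0, 2 * nv))
  link_lo <- matrix(0, nv, nvar)
  link_lo[cbind(seq_len(nv), ne + seq_len(nv))] <- 1
  link_lo[cbind(seq_len(nv), ne + nv + seq_len(nv))] <- -1 / nv
  A <- rbind(A, dens_row, link_lo)
  dir <- c(core$dir, ">=", rep(">=", nv))
  b <- c(core$b, rho_value(D) - DENSITY_SLACK, rep(0, nv))
  obj <- c(rep(0, ne + nv), rep(1, nv))
  res <- milp_solve(obj, A, dir, b, bin_idx = ne + nv + seq_len(nv), maximize = TRUE)
  if (res$status != "optimal") {
    abort_solver("MaxILP infeasible although D is the maximum density: solver misconfiguration")
  }
  s <- core$vs[res$solution[ne + nv + seq_len(nv)] > 0.5]
  out <- subgraph_result(g, s, method = "max-ds")
  if (rho_cmp(out$density, D) != 0) {
    abort_solver("maximal densest candidate has density %s, expected %s",
                 format(out$density), format(D))
  }
  out
}

#' One growth step of the LP-based maximal-densest search
#'
#' Solves the densest-subgraph LP with three extra constraints: the total
#' edge mass must reach the maximum density D, every vertex already in `R`
#' must be selected (`y_i >= 1/|V|`), and at least one vertex outside `R`
#' must be selected (`sum(y) over V - R >= 1/|V|`). Returns the threshold
#' vertex set of the optimum, or an empty character vector when the LP is
#' infeasible (no densest subgraph strictly extends `R`).
#'
#' @param g an igraph graph with at least one edge
#' @param D the exact maximum density of `g` (a [rho])
#' @param R character vector, a proper subset of the vertices
#' @return character vector of selected vertices (possibly empty)
#' @export
solve_max_lp <- function(g, D, R) {
  assert_graph(g)
  if (!inherits(D, "rho")) abort_input("D must be a rho density")
  core <- lp_core(g)
  nv <- core$nv; ne <- core$ne
  R <- unique(as.character(R))
  if (!all(R %in% core$vs)) abort_input("R contains vertices not in the graph")
  if (length(R) >= nv) abort_input("R must be a proper subset of the vertices")
  dens_row <- c(rep(1, ne), rep(0, nv))
  in_r <- match(R, core$vs)
  r_rows <- matrix(0, length(in_r), ne + nv)
  r_rows[cbind(seq_along(in_r), ne + in_r)] <- 1
  outside_row <- c(rep(0, ne), as.numeric(!(core$vs %in% R)))
  A <- rbind(core$A, dens_row, r_rows, outside_row)
  dir <- c(core$dir, ">=", rep(">=", length(in_r)), ">=")
  b <- c(core$b, rho_value(D) - DENSITY_SLACK, rep(1 / nv, length(in_r)), 1 / nv)
  obj <- c(rep(1, ne), rep(0, nv))
  sol <- lp_solve(obj, A, dir, b)
  if (sol$status != "optimal") return(character(0))
  if (sol$objective < rho_value(D) - 1e-6) return(character(0))
  y <- sol$solution[ne + seq_len(nv)]
  thresh <- vsort(core$vs[y >= 1 / nv - MEMBER_EPS])
  extends <- function(s) length(setdiff(s, R)) > 0L
  if (extends(thresh)) return(thresh)
  # Degenerate optima can spread the mandatory outside mass over several
  # vertices that all sit below the 1/|V| threshold. The support of any
  # optimal solution still induces a densest subgraph, contains R, and
  # contains an outside vertex, so fall back to it (recount-verified).
  supp <- vsort(core$vs[y > 1e-7])
  if (extends(supp) &&
      rho_cmp(rho(induced_edge_count(g, supp), length(supp)), D) == 0) {
    return(supp)
  }
  thresh
}

#' The maximal densest subgraph by iterated LP growth
#'
#' Starts from any densest subgraph and repeatedly asks the LP for a
#' densest subgraph that strictly extends the current vertex set, until no
#' extension exists. Terminates within |V| LP calls and must agree with
#' [find_maximal_densest_ilp] on every input (the maximal densest subgraph
#' is unique).
#'
#' @param g an igraph graph with at least one edge
#' @return a [subgraph_result] with method tag `"max-ds"`
#' @export
find_maximal_densest_iterative <- function(g) {
  assert_graph(g)
  first <- find_densest(g)
  D <- first$density
  R <- first$vertices
  iters <- 0L
  while (length(R) < igraph::vcount(g)) {
    s <- solve_max_lp(g, D, R)
    if (length(s) == 0L || setequal(s, R)) break
    R <- vsort(union(R, s))
    iters <- iters + 1L
    if (iters > igraph::vcount(g)) {
      abort_solver("maximal-densest iteration exceeded |V| LP calls")
    }
  }
  out <- subgraph_result(g, R, method = "max-ds")
  if (rho_cmp(out$density, D) != 0) {
    abort_solver("iterative maximal densest has density %s, expected %s",
                 format(out$density), format(D))
  }
  out
}

#' Minimal sub-densest subgraphs (Min-SDS method)
#'
#' Like Min-DS, but peeling continues while the current minimal densest
#' subgraph keeps density at least `theta * D`, where D is the maximum
#' density of the *original* graph and `theta` in (0, 1) is the density
#' tolerance. The boundary is inclusive: a subgraph with density exactly
#' `theta * D` is selected (the stop condition is a strict `<`), and the
#' comparison is exact — rational density against `theta` held at its
#' printed decimal value.
#'
#' @param g an igraph graph with at least one edge
#' @param theta density tolerance, strictly between 0 and 1
#'   (default 0.85, the value at which the F2-score of hot-spot
#'   recovery peaks on alanine-scanning benchmarks)
#' @return a `subgraph_list` of pairwise-disjoint [subgraph_result]s,
#'   method tag `"min-sds"`, each with density >= theta * D
#' @examples
#' # K4 and a triangle, disjoint: D = 3/2
#' g <- ds_graph(rbind(
#'   t(combn(paste0("a", 1:4), 2)),
#'   t(combn(paste0("b", 1:3), 2))))
#' length(min_sds(g, theta = 0.6))  # 2: the triangle (density 1) passes 0.9
#' @export
min_sds <- function(g, theta = 0.85) {
  assert_graph(g)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta >= 1) {
    abort_input("theta must lie strictly between 0 and 1")
  }
  D <- max_density(g)
  cur <- g
  out <- list()
  while (igraph::ecount(cur) > 0L) {
    r <- find_one_minimal_densest(cur)
    if (rho_cmp_scaled(r$density, theta, D) < 0) break
    r$method <- "min-sds"
    out[[length(out) + 1L]] <- r
    cur <- igraph::delete_vertices(cur, r$vertices)
  }
  subgraph_list(out, method = "min-sds", D = D, theta = theta)
}
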