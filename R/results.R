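#' Subgraph extraction result
#'
#' A vertex subset of a graph together with its induced edge count and
#' exact density. Subgraphs are always vertex-induced: the edge count is
#' recomputed from the parent graph, never taken from a solver.
#'
#' @param g the parent igraph graph
#' @param s character vector of vertex names (subset of the graph)
#' @param method one of `"ds"`, `"min-ds"`, `"max-ds"`, `"min-sds"`
#' @return object of class `subgraph_result` with fields `vertices`
#'   (sorted), `edge_count`, `density` (a [rho]), `method`
#' @export
subgraph_result <- function(g, s, method = c("ds", "min-ds", "max-ds", "min-sds")) {
  method <- match.arg(method)
  s <- vsort(unique(as.character(s)))
  if (length(s) == 0L) abort_solver("empty vertex set extracted")
  ec <- induced_edge_count(g, s)
  structure(list(
    vertices = s,
    edge_count = ec,
    density = rho(ec, length(s)),
    method = method
  ), class = "subgraph_result")
}

#' @export
print.subgraph_result <- function(x, ...) {
  cat(sprintf("<%s> %d vertices, %d edges, density %s\n  {%s}\n",
              x$method, length(x$vertices), x$edge_count,
              format(x$density), paste(x$vertices, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.subgraph_result <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x))
}

#' @importFrom tibble as_tibble
#' @method as_tibble subgraph_result
#' @export
as_tibble.subgraph_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_vertices = length(x$vertices),
    edge_count = x$edge_count,
    density_num = x$density$num,
    density_den = x$density$den,
    density = rho_value(x$density),
    vertices = list(x$vertices)
  )
}

# ordered collection of subgraph results from one extraction run
subgraph_list <- function(results, method, D, theta = NULL) {
  structure(results, class = "subgraph_list",
            method = method, max_density = D, theta = theta)
}

#' @export
print.subgraph_list <- function(x, ...) {
  th <- attr(x, "theta")
  cat(sprintf("%s extraction: %d subgraph(s), graph maximum density %s%s\n",
              attr(x, "method"), length(x), format(attr(x, "max_density")),
              if (!is.null(th)) sprintf(", theta = %g", th) else ""))
  for (r in x) print(r)
  invisible(x)
}

#' @method as_tibble subgraph_list
#' @export
as_tibble.subgraph_list <- function(x, ...) {
  if (length(x) == 0L) {
    return(tibble::tibble(method = character(), n_vertices = integer(),
                          edge_count = integer(), density_num = numeric(),
                          density_den = numeric(), density = numeric(),
                          vertices = list()))
  }
  do.call(rbind, lapply(x, as_tibble.subgraph_result))
}

#' Union of predicted vertices across subgraph results
#'
#' The residue-level prediction of a method is the union of the vertex
#' sets it returns.
#'
#' @param x a `subgraph_result` or `subgraph_list`
#' @return sorted character vector of vertex names
#' @export
predicted_vertices <- function(x) {
  if (inherits(x, "subgraph_result")) return(x$vertices)
  if (inherits(x, "subgraph_list")) return(vsort(unique(unlist(lapply(x, `[[`, "vertices")))))
  abort_input("expected a subgraph_result or subgraph_list")
}

#' Run one extraction method by name
#'
#' Dispatcher used by the command-line front end; always returns a
#' `subgraph_list` (singleton for `ds` / `max-ds`).
#'
#' @param g an igraph graph with at least one edge
#' @param method `"ds"`, `"min-ds"`, `"max-ds"` or `"min-sds"`
#' @param theta Min-SDS density tolerance (used only for `min-sds`)
#' @return a `subgraph_list`
#' @export
run_method <- function(g, method = c("min-sds", "ds", "min-ds", "max-ds"),
                       theta = 0.85) {
  method <- match.arg(method)
  switch(method,
    "ds" = {
      r <- find_densest(g)
      subgraph_list(list(r), method = "ds", D = r$density)
    },
    "min-ds" = find_all_minimal_densest(g),
    "max-ds" = {
      r <- find_maximal_densest_ilp(g)
      subgraph_list(list(r), method = "max-ds", D = r$density)
    },
    "min-sds" = min_sds(g, theta = theta)
  )
}

#' Serialize an extraction run to a structured report
#'
#' @param x a `subgraph_list`
#' @return a list (JSON-ready): report version, method, theta (if any),
#'   maximum density as exact fraction and float, and one record per
#'   subgraph with vertices, edge count and density
#' @export
report_list <- function(x) {
  if (!inherits(x, "subgraph_list")) abort_input("expected a subgraph_list")
  D <- attr(x, "max_density")
  out <- list(
    report_version = 1L,
    method = attr(x, "method"),
    max_density = list(num = D$num, den = D$den, value = rho_value(D)),
    n_subgraphs = length(x),
    subgraphs = lapply(x, function(r) list(
      vertices = r$vertices,
      edge_count = r$edge_count,
      density = list(num = r$density$num, den = r$density$den,
                     value = rho_value(r$density))
    ))
  )
  th <- attr(x, "theta")
  if (!is.null(th)) out$theta <- th
  out
}

#' Write an extraction report as JSON
#'
#' @param x a `subgraph_list`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(report_list(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
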