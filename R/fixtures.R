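# Deterministic synthetic inputs: random and planted-dense graphs for the
# solvers, and toy multi-chain PDB files whose inter-chain contact pattern
# is prescribed exactly, so the whole pipeline is testable offline.

#' Seeded Erdos-Renyi random graph
#'
#' @param n number of vertices (>= 1); names are zero-padded (`v01`, ...)
#'   so lexicographic order equals numeric order
#' @param p edge probability in \[0, 1\]
#' @param seed integer seed; the same seed always yields the same graph
#' @return an igraph graph (isolated vertices retained)
#' @export
random_graph <- function(n, p, seed) {
  if (!is.numeric(n) || n < 1 || n != floor(n)) abort_input("n must be a positive integer")
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) abort_input("p must lie in [0, 1]")
  vs <- sprintf("v%0*d", max(2L, nchar(as.character(n))), seq_len(n))
  withr_seed(seed, {
    if (n < 2L) return(ds_graph(NULL, vertices = vs))
    em <- t(utils::combn(vs, 2L))
    em <- em[stats::runif(nrow(em)) < p, , drop = FALSE]
    ds_graph(em, vertices = vs)
  })
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Random graph with planted dense blocks
#'
#' Disjoint near-clique blocks planted on top of a sparse background:
#' block-internal edges appear with probability `block_density`, all other
#' pairs with probability `p_background`. The planted blocks are the
#' ground truth for recovery tests of the extractors.
#'
#' @param n_background number of background-only vertices
#' @param p_background background edge probability (should be well below
#'   the planted density)
#' @param blocks integer vector of block sizes
#' @param block_density within-block edge probability (default 1: cliques)
#' @param seed integer seed
#' @return list with `graph` (igraph) and `blocks` (list of vertex-name
#'   vectors, the ground truth)
#' @export
planted_graph <- function(n_background, p_background, blocks,
                          block_density = 1, seed = 1L) {
  if (any(blocks < 2)) abort_input("planted blocks need at least 2 vertices")
  if (block_density <= p_background) {
    abort_input("planted block density must exceed the background probability")
  }
  width <- max(2L, nchar(as.character(n_background + sum(blocks))))
  bg <- sprintf("bg%0*d", width, seq_len(n_background))
  bl <- lapply(seq_along(blocks), function(i) {
    sprintf("pl%d.%0*d", i, width, seq_len(blocks[i]))
  })
  all_vs <- c(bg, unlist(bl))
  block_of <- stats::setNames(rep(c(0L, seq_along(blocks)), c(length(bg), blocks)), all_vs)
  withr_seed(seed, {
    em <- t(utils::combn(all_vs, 2L))
    same_block <- block_of[em[, 1]] == block_of[em[, 2]] & block_of[em[, 1]] > 0L
    pr <- ifelse(same_block, block_density, p_background)
    em <- em[stats::runif(nrow(em)) < pr, , drop = FALSE]
    list(graph = ds_graph(em, vertices = all_vs), blocks = bl)
  })
}

#' Specification of a toy multi-chain complex
#'
#' Describes a synthetic structure of single-carbon residues: which chains
#' exist, how many residues each has, and exactly which inter-chain
#' residue pairs must be in contact. Residue references are
#' `"<chain>:<resno>"`.
#'
#' @param chains named integer vector: chain id -> residue count
#' @param contacts list of length-2 character vectors of residue
#'   references; every pair must span two different chains
#' @param spacing distance in Angstrom separating non-contacting groups
#'   (must exceed the contact threshold; default 50)
#' @return a `toy_complex_spec` object
#' @export
toy_complex_spec <- function(chains, contacts = list(), spacing = 50) {
  if (is.null(names(chains)) || any(!nzchar(names(chains)))) {
    abort_input("chains must be a named vector: chain id -> residue count")
  }
  refs <- unlist(lapply(names(chains), function(ch) paste0(ch, ":", seq_len(chains[[ch]]))))
  for (p in contacts) {
    if (length(p) != 2L || !all(p %in% refs)) {
      abort_input("contact pair (%s) references unknown residues", paste(p, collapse = ", "))
    }
    if (sub(":.*$", "", p[1]) == sub(":.*$", "", p[2])) {
      abort_input("contact pair (%s) is intra-chain; contacts must span chains",
                  paste(p, collapse = ", "))
    }
  }
  if (spacing <= 2 * bondi_radii[["C"]] + WATER_DIAMETER + 1) {
    abort_input("spacing must comfortably exceed the carbon contact threshold")
  }
  structure(list(chains = chains, contacts = lapply(contacts, as.character),
                 spacing = spacing), class = "toy_complex_spec")
}

# contact threshold between two lone carbon atoms: 1.70 + 1.70 + 2.75
CARBON_CONTACT <- 2 * 1.70 + 2.75

#' Write a toy complex as a PDB file
#'
#' Emits single-carbon "residues" (one CA atom each, residue name GLY)
#' positioned so that exactly the prescribed inter-chain pairs satisfy the
#' contact rule d <= r + r + 2.75 A (threshold 6.15 A between carbons).
#' Contact components are laid out independently: cliques as compact point
#' clusters of diameter < 5.8 A, general patterns by embedding the
#' graph-distance matrix in 3D; components and isolated residues sit on a
#' coarse grid `spacing` apart. The realised geometry is verified against
#' the requested contact set before writing, and an unsatisfiable request
#' is an error. The spec is echoed into REMARK lines.
#'
#' @param spec a [toy_complex_spec]
#' @param path output PDB path
#' @return `path`, invisibly
#' @export
write_toy_structure <- function(spec, path) {
  if (!inherits(spec, "toy_complex_spec")) abort_input("spec must be a toy_complex_spec")
  refs <- unlist(lapply(names(spec$chains), function(ch) {
    paste0(ch, ":", seq_len(spec$chains[[ch]]))
  }))
  n <- length(refs)
  adj <- matrix(FALSE, n, n, dimnames = list(refs, refs))
  for (p in spec$contacts) {
    adj[p[1], p[2]] <- TRUE; adj[p[2], p[1]] <- TRUE
  }
  cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(cg)$membership
  pos <- matrix(NA_real_, n, 3, dimnames = list(refs, NULL))
  grid_n <- ceiling(max(comp)^(1 / 3))
  for (ci in seq_len(max(comp))) {
    members <- refs[comp == ci]
    k <- length(members)
    local <- if (k == 1L) {
      matrix(0, 1, 3)
    } else if (all(adj[members, members][upper.tri(diag(k))])) {
      clique_coords(k)
    } else {
      sp <- igraph::distances(igraph::induced_subgraph(cg, members))
      embed_component(5.0 * sp)
    }
    off <- ((ci - 1) %% grid_n) * spec$spacing
    off2 <- (((ci - 1) %/% grid_n) %% grid_n) * spec$spacing
    off3 <- ((ci - 1) %/% grid_n^2) * spec$spacing
    pos[members, ] <- sweep(local, 2, c(off, off2, off3), "+")
  }
  verify_toy_geometry(refs, pos, adj)

  ord <- order(sub(":.*$", "", refs), as.integer(sub("^.*:", "", refs)), method = "radix")
  lines <- c(
    "REMARK   1 SYNTHETIC toy complex generated by denshot",
    sprintf("REMARK   1 chains: %s",
            paste(sprintf("%s=%d", names(spec$chains), spec$chains), collapse = " ")),
    sprintf("REMARK   1 contacts: %s",
            if (length(spec$contacts)) paste(vapply(spec$contacts, paste, "", collapse = "-"),
                                             collapse = " ") else "none"),
    sprintf("REMARK   1 spacing: %g", spec$spacing)
  )
  serial <- 0L
  for (i in ord) {
    serial <- serial + 1L
    ch <- sub(":.*$", "", refs[i])
    resno <- as.integer(sub("^.*:", "", refs[i]))
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      serial, ch, resno, pos[i, 1], pos[i, 2], pos[i, 3], 1.0, 0.0))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

# k points with pairwise distances in (2, 5.8): a compact integer-grid
# cluster inside a ball of radius 2.9, scaled from unit spacing 2 A
clique_coords <- function(k) {
  cand <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * 2.0
  cand <- cand[order(rowSums(cand^2)), , drop = FALSE]
  if (k > nrow(cand)) abort_input("clique of %d residues is not realisable", k)
  cand[seq_len(k), , drop = FALSE]
}

# classical MDS embedding of a target distance matrix into 3D
embed_component <- function(dmat) {
  k <- nrow(dmat)
  xy <- stats::cmdscale(dmat, k = min(3L, k - 1L))
  cbind(xy, matrix(0, k, 3L - ncol(xy)))
}

# realised inter-chain contact pattern must equal the requested one
verify_toy_geometry <- function(refs, pos, adj) {
  n <- length(refs)
  if (n < 2L) return(invisible(TRUE))
  ch <- sub(":.*$", "", refs)
  d <- as.matrix(stats::dist(pos))
  inter <- outer(ch, ch, "!=")
  realised <- d <= CARBON_CONTACT & inter
  want <- adj & inter
  # leave a safety band on both sides of the threshold
  tight_ok <- all(d[want] <= CARBON_CONTACT - 0.05) &&
    all(d[inter & !want] >= CARBON_CONTACT + 0.05)
  if (!identical(realised[upper.tri(realised)], want[upper.tri(want)]) || !tight_ok) {
    abort_input("requested contact pattern is not realisable in 3D (geometry verification failed)")
  }
  invisible(TRUE)
}
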