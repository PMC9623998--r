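# Shared fixture graphs, built in code.

k_n <- function(n, prefix = "") {
  denshot::ds_graph(t(combn(paste0(prefix, seq_len(n)), 2L)))
}

# K4 on vertices 1..4
g_k4 <- function() k_n(4)

# triangle {1,2,3} plus pendant vertex 4 attached to 3
g_tri_pendant <- function() {
  ds_graph(rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))
}

# two vertex-disjoint triangles a1..a3, b1..b3
g_two_triangles <- function() {
  ds_graph(rbind(t(combn(paste0("a", 1:3), 2L)), t(combn(paste0("b", 1:3), 2L))))
}

# disjoint K4 (a*), K3 (b*), K2 (c*): the hand-peeled worked example
g_k4_k3_k2 <- function() worked_example_graph()

# sorted canonical form for set-of-sets comparison
canon_sets <- function(sets) {
  sets <- lapply(sets, function(s) sort(unname(s)))
  sets[order(vapply(sets, paste, "", collapse = "\r"))]
}

oracle_union <- function(bf) sort(unique(unlist(bf$sets)))

# two single-carbon residues on chains A and B, exactly d Angstrom apart
toy_residue_pair <- function(d) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            1L, "A", 1L, 0, 0, 0, 1, 0),
    sprintf("ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            2L, "B", 1L, d, 0, 0, 1, 0),
    "END"), f)
  denshot::build_rin(denshot::parse_structure(f))
}

# canonical sorted edge signature of a graph, for set comparisons
edge_sig <- function(g) {
  em <- igraph::as_edgelist(g)
  sort(apply(em, 1L, function(r) paste(sort(r), collapse = "|")))
}
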