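# Residue interaction network construction: radii, contact rule, parsing,
# and the network invariants.

test_that("van der Waals radii come from the configured table with fallback", {
  expect_equal(vdw_radius("C"), 1.70)
  expect_equal(vdw_radius("N"), 1.55)
  expect_equal(vdw_radius(c("O", "S", "H", "P")), c(1.52, 1.80, 1.20, 1.80))
  expect_message(r <- vdw_radius("X"), "fallback")
  expect_equal(r, 1.80)
  expect_equal(vdw_radius("C", radii = c(C = 2.0)), 2.0)
})

test_that("the contact rule is the printed inequality and is symmetric", {
  a <- data.frame(element = "C", x = 0, y = 0, z = 0)
  at <- function(d) data.frame(element = "C", x = d, y = 0, z = 0)
  expect_true(residues_in_contact(a, at(6.10)))   # threshold 6.15
  expect_false(residues_in_contact(a, at(6.20)))
  expect_true(residues_in_contact(a, at(6.149)))  # boundary is inclusive (<=)
  expect_identical(residues_in_contact(at(6.10), a), residues_in_contact(a, at(6.10)))
  # mixed elements: C-N threshold 1.70 + 1.55 + 2.75 = 6.00
  b <- data.frame(element = "N", x = 5.95, y = 0, z = 0)
  expect_true(residues_in_contact(a, b))
  expect_false(residues_in_contact(a, data.frame(element = "N", x = 6.05, y = 0, z = 0)))
  expect_error(residues_in_contact(a, a[0, ]), class = "denshot_input_error")
})

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

atom_line <- function(serial, name, res, chain, resno, x, y, z,
                      occ = 1, alt = " ", type = "ATOM", elem = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, paste0(" ", name), alt, res, chain, resno, x, y, z, occ, 0, elem)
}

test_that("parsing keeps first model, drops waters, resolves altlocs, maps MSE", {
  f <- write_mini_pdb(c(
    atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    atom_line(2, "CA", "GLY", "A", 1, 9, 9, 9, occ = 0.4, alt = "B"),
    atom_line(3, "CA", "MSE", "A", 2, 3, 0, 0, type = "HETATM"),
    atom_line(4, "O", "HOH", "A", 90, 1, 1, 1, type = "HETATM"),
    atom_line(5, "CA", "GLY", "B", 1, 5, 0, 0),
    atom_line(6, "FE", "HEM", "B", 99, 2, 2, 2, type = "HETATM"),
    "ENDMDL",
    atom_line(7, "CA", "GLY", "C", 1, 7, 7, 7)
  ))
  at <- parse_structure(f)
  expect_equal(nrow(at), 3)                       # altloc collapsed, HOH/HEM/model-2 gone
  expect_false("C" %in% at$chain)                 # first model only
  expect_equal(at$x[at$chain == "A" & at$resno == 1], 0)  # highest occupancy kept
  expect_equal(at$resname[at$chain == "A" & at$resno == 2], "MET")
  expect_error(parse_structure(tempfile()), class = "denshot_input_error")
})

test_that("network has only inter-chain edges and no isolated vertices", {
  # A:1 contacts B:1; A:2 contacts nothing; B:2 contacts C:1
  f <- write_mini_pdb(c(
    atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 100, 0, 0),
    atom_line(3, "CA", "GLY", "B", 1, 5, 0, 0),
    atom_line(4, "CA", "GLY", "B", 2, 200, 0, 0),
    atom_line(5, "CA", "GLY", "C", 1, 204, 0, 0)
  ))
  net <- build_rin(parse_structure(f))
  expect_identical(graph_vertices(net),
                   c("A:1:GLY", "B:1:GLY", "B:2:GLY", "C:1:GLY"))
  em <- igraph::as_edgelist(net)
  chains <- cbind(sub(":.*", "", em[, 1]), sub(":.*", "", em[, 2]))
  expect_true(all(chains[, 1] != chains[, 2]))
  expect_equal(igraph::ecount(net), 2)            # A1-B1 and B2-C1, no A-C edge
  expect_true(all(igraph::degree(net) >= 1))
})

test_that("single-chain structures are rejected", {
  f <- write_mini_pdb(c(
    atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 3, 0, 0)
  ))
  expect_error(build_rin(parse_structure(f)), class = "denshot_input_error")
})

test_that("the network is invariant under rigid-body motion", {
  spec <- toy_complex_spec(c(A = 3, B = 3),
                           list(c("A:1", "B:1"), c("A:2", "B:2"), c("A:2", "B:1")))
  f <- tempfile(fileext = ".pdb")
  write_toy_structure(spec, f)
  at <- parse_structure(f)
  net1 <- build_rin(at)
  # rotate about z by 40 degrees, then translate
  th <- 40 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at2 <- at
  at2$x <- xyz[, 1] + 11.3; at2$y <- xyz[, 2] - 4.7; at2$z <- xyz[, 3] + 101
  net2 <- build_rin(at2)
  expect_identical(canon_sets(as.list(as.data.frame(t(igraph::as_edgelist(net1))))),
                   canon_sets(as.list(as.data.frame(t(igraph::as_edgelist(net2))))))
})

test_that("grid neighbour search equals the all-pairs scan", {
  for (seed in 1:5) {
    set.seed(seed)
    spec <- toy_complex_spec(c(A = 4, B = 4),
                             contacts = list(c("A:1", "B:1"), c("A:2", "B:2")))
    f <- tempfile(fileext = ".pdb")
    write_toy_structure(spec, f)
    at <- parse_structure(f)
    e1 <- edge_sig(build_rin(at, method = "grid"))
    e2 <- edge_sig(build_rin(at, method = "allpairs"))
    expect_identical(e1, e2)
  }
})

test_that("gzipped structures parse identically to plain ones", {
  spec <- toy_complex_spec(c(A = 2, B = 2), list(c("A:1", "B:1")))
  f <- tempfile(fileext = ".pdb")
  write_toy_structure(spec, f)
  fz <- paste0(f, ".gz")
  con <- gzfile(fz, "w"); writeLines(readLines(f), con); close(con)
  a1 <- parse_structure(f); a2 <- parse_structure(fz)
  expect_equal(a1$x, a2$x)
  expect_identical(a1$chain, a2$chain)
})

test_that("edge list with sidecar round-trips through read_edge_list", {
  spec <- toy_complex_spec(c(A = 2, B = 2), list(c("A:1", "B:1"), c("A:2", "B:2")))
  f <- tempfile(fileext = ".pdb")
  write_toy_structure(spec, f)
  net <- build_rin(parse_structure(f))
  out <- tempfile(fileext = ".edges")
  write_rin(net, out)
  g2 <- read_edge_list(out)
  expect_identical(graph_vertices(g2), graph_vertices(net))
  sidecar <- jsonlite::read_json(paste0(out, ".json"))
  expect_equal(sidecar$n_edges, igraph::ecount(net))
  expect_equal(sidecar$radii$C, 1.70)
})
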