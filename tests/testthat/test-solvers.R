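# Worked examples and structural properties of the four extraction methods.

test_that("BasicLP objective equals the maximum density on worked examples", {
  expect_equal(solve_basic_lp(g_k4())$objective, 1.5, tolerance = 1e-8)
  single <- ds_graph(rbind(c("u", "v")))
  s <- solve_basic_lp(single)
  expect_equal(s$objective, 0.5, tolerance = 1e-8)
  expect_equal(unname(s$vertex_values), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(solve_basic_lp(g_two_triangles())$objective, 1, tolerance = 1e-8)
  expect_error(solve_basic_lp(ds_graph(NULL, vertices = c("a", "b"))),
               class = "denshot_input_error")
})

test_that("extraction returns an oracle-densest set with exact recounted density", {
  r <- find_densest(g_k4())
  expect_identical(r$vertices, as.character(1:4))
  expect_equal(rho_cmp(r$density, rho(3, 2)), 0)
  bf <- brute_force_densest(g_tri_pendant())
  r2 <- find_densest(g_tri_pendant())
  expect_true(any(vapply(bf$sets, setequal, logical(1), r2$vertices)))
  expect_equal(rho_value(r2$density), 1)
  bf3 <- brute_force_densest(g_two_triangles())
  r3 <- find_densest(g_two_triangles())
  expect_true(any(vapply(bf3$sets, setequal, logical(1), r3$vertices)))
})

test_that("one minimal densest subgraph is inclusion-minimal, deterministic on ties", {
  expect_identical(find_one_minimal_densest(g_tri_pendant())$vertices,
                   c("1", "2", "3"))
  expect_identical(find_one_minimal_densest(g_k4())$vertices, as.character(1:4))
  # two equal triangles: the lexicographically least one wins
  expect_identical(find_one_minimal_densest(g_two_triangles())$vertices,
                   paste0("a", 1:3))
})

test_that("Min-DS returns exactly the inclusion-minimal densest subgraphs", {
  res <- find_all_minimal_densest(g_two_triangles())
  expect_length(res, 2)
  expect_identical(canon_sets(lapply(res, `[[`, "vertices")),
                   canon_sets(list(paste0("a", 1:3), paste0("b", 1:3))))
  res2 <- find_all_minimal_densest(g_tri_pendant())
  expect_length(res2, 1)
  expect_identical(res2[[1]]$vertices, c("1", "2", "3"))
  # K4 with a disjoint triangle: only the K4 reaches density 3/2
  g <- ds_graph(rbind(t(combn(paste0("a", 1:4), 2L)), t(combn(paste0("b", 1:3), 2L))))
  res3 <- find_all_minimal_densest(g)
  expect_length(res3, 1)
  expect_identical(res3[[1]]$vertices, paste0("a", 1:4))
})

test_that("the maximal densest subgraph is the union of all densest subgraphs", {
  expect_identical(find_maximal_densest_ilp(g_tri_pendant())$vertices,
                   as.character(1:4))
  expect_identical(find_maximal_densest_ilp(g_two_triangles())$vertices,
                   sort(c(paste0("a", 1:3), paste0("b", 1:3))))
  expect_identical(find_maximal_densest_ilp(g_k4())$vertices, as.character(1:4))
})

test_that("iterated MaxLP growth reproduces the ILP maximal densest subgraph", {
  for (g in list(g_tri_pendant(), g_two_triangles(), g_k4(), g_k4_k3_k2())) {
    expect_identical(find_maximal_densest_iterative(g)$vertices,
                     find_maximal_densest_ilp(g)$vertices)
  }
})

test_that("MaxLP growth step extends a proper densest subset", {
  tp <- g_tri_pendant()
  D <- rho(4, 4)
  s <- solve_max_lp(tp, D, c("1", "2", "3"))
  expect_true(all(c("1", "2", "3", "4") %in% s))
  k4 <- g_k4()
  expect_identical(solve_max_lp(k4, rho(3, 2), c("1", "2", "4")), as.character(1:4))
  tt <- g_two_triangles()
  s3 <- solve_max_lp(tt, rho(1, 1), paste0("a", 1:3))
  expect_identical(s3, sort(c(paste0("a", 1:3), paste0("b", 1:3))))
  expect_error(solve_max_lp(k4, rho(3, 2), as.character(1:4)),
               class = "denshot_input_error")
})

test_that("isolated vertices never enter any extracted subgraph", {
  g <- ds_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                vertices = c("x", "y"))
  expect_identical(find_densest(g)$vertices, c("a", "b", "c"))
  expect_identical(find_maximal_densest_ilp(g)$vertices, c("a", "b", "c"))
  expect_identical(find_one_minimal_densest(g)$vertices, c("a", "b", "c"))
})

test_that("minimal subgraphs are disjoint and contained in the maximal one", {
  for (seed in c(3, 14, 27, 58)) {
    g <- random_graph(10, 0.4, seed)
    if (igraph::ecount(g) == 0) next
    mins <- find_all_minimal_densest(g)
    mx <- find_maximal_densest_ilp(g)
    all_v <- unlist(lapply(mins, `[[`, "vertices"))
    expect_equal(anyDuplicated(all_v), 0)
    expect_true(all(all_v %in% mx$vertices))
  }
})
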