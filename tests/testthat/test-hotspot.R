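# ddG arithmetic, hot-spot labelling and evaluation metrics.

test_that("binding free energy follows dG = RT ln Kd at 298.15 K", {
  expect_equal(delta_g(1), 0)
  expect_equal(delta_g(exp(1)), (8.314 / 4184) * (273.15 + 25.0))
  expect_equal(delta_g(1e-9), RT_KCAL * log(1e-9))
  expect_equal(delta_g(1e-9), -12.2775, tolerance = 1e-4)
  expect_error(delta_g(0), class = "denshot_input_error")
  expect_error(delta_g(-1e-9), class = "denshot_input_error")
})

test_that("ddG is RT ln(mut/wt), antisymmetric, zero for no change", {
  expect_equal(ddg(1e-9, 1e-7), RT_KCAL * log(100))
  expect_equal(ddg(1e-9, 1e-7), 2.7283, tolerance = 1e-3)
  expect_equal(ddg(3e-8, 3e-8), 0)
  expect_equal(ddg(1e-7, 1e-9), -ddg(1e-9, 1e-7))
  # exactly the two-call difference
  expect_identical(ddg(2e-8, 5e-6), delta_g(5e-6) - delta_g(2e-8))
})

# a tiny two-chain network to label against: A:1 GLY, A:2 GLY, B:1 GLY
toy_network <- function() {
  spec <- toy_complex_spec(c(A = 2, B = 1),
                           list(c("A:1", "B:1"), c("A:2", "B:1")))
  f <- tempfile(fileext = ".pdb")
  write_toy_structure(spec, f)
  build_rin(parse_structure(f))
}

rec <- function(chain, resno, mut = "A", wt_kd = 1e-9, fold = 100, wt_aa = "G") {
  tibble::tibble(structure_id = "TOY", chain = chain, wt_aa = wt_aa,
                 resno = resno, icode = "", mut_aa = mut,
                 affinity_wt = wt_kd, affinity_mut = wt_kd * fold)
}

test_that("labelling is alanine-only, max-aggregated, inclusive at 2.0", {
  net <- toy_network()
  # ddG exactly 2.0: fold = exp(2 / RT)
  exact2 <- exp(2 / RT_KCAL)
  records <- rbind(
    rec("A", 1, fold = exact2),                  # boundary: hot spot
    rec("A", 2, fold = 10),                      # 1.36 kcal/mol: not
    rec("A", 2, fold = 80),                      # 2.60: max rule flips it
    rec("B", 1, mut = "G", fold = 1e5)           # non-alanine: ignored
  )
  labs <- label_hotspots(records, net)
  expect_equal(nrow(labs), 2)                    # B:1 carries no label
  a1 <- labs[labs$chain == "A" & labs$resno == 1, ]
  expect_true(a1$is_hotspot)
  expect_equal(a1$ddg, 2.0, tolerance = 1e-9)
  a2 <- labs[labs$chain == "A" & labs$resno == 2, ]
  expect_true(a2$is_hotspot)
  expect_equal(a2$n_records, 2)
  # mean aggregation is the documented alternative
  labs_mean <- label_hotspots(records, net, aggregate = "mean")
  expect_false(labs_mean[labs_mean$resno == 2 & labs_mean$chain == "A", ]$is_hotspot)
})

test_that("labelling is order-independent and flags wild-type mismatches", {
  net <- toy_network()
  records <- rbind(rec("A", 1, fold = 200), rec("A", 2, fold = 150))
  l1 <- label_hotspots(records, net)
  l2 <- label_hotspots(records[2:1, ], net)
  expect_identical(l1, l2)
  bad <- rec("A", 1, wt_aa = "W")                # structure says GLY
  expect_warning(l3 <- label_hotspots(rbind(bad, rec("A", 2)), net), "disagrees")
  expect_equal(nrow(l3), 1)
})

test_that("metrics follow the F-beta formulas with zero conventions", {
  net <- toy_network()
  labs <- label_hotspots(rbind(rec("A", 1, fold = 1000), rec("A", 2, fold = 2)), net)
  hot <- labs$residue[labs$is_hotspot]
  m <- evaluate_prediction(hot, labs)
  expect_equal(unlist(m[c("precision", "recall", "f1", "f2")]),
               c(precision = 1, recall = 1, f1 = 1, f2 = 1))
  # P = 0.5, R = 1: F2 = 5 * 0.5 * 1 / (4 * 0.5 + 1) = 0.8333
  m2 <- evaluate_prediction(c(hot, "A:2:GLY"), labs)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 1)
  expect_equal(m2$f2, 5 * 0.5 / (4 * 0.5 + 1))
  expect_equal(m2$f2, 0.8333, tolerance = 1e-4)
  # empty prediction: precision defined as 0
  m3 <- evaluate_prediction(character(0), labs)
  expect_equal(unlist(m3[c("precision", "recall", "f1", "f2")]),
               c(precision = 0, recall = 0, f1 = 0, f2 = 0))
  # unlabelled predicted residues count as false positives
  m4 <- evaluate_prediction(c(hot, "B:1:GLY"), labs)
  expect_equal(m4$fp, 1)
})

test_that("hot spots absent from the network are excluded or counted by mode", {
  net <- toy_network()
  records <- rbind(rec("A", 1, fold = 1000), rec("A", 7, fold = 1000))  # A:7 not in net
  labs <- suppressWarnings(label_hotspots(records, net))
  m_net <- evaluate_prediction("A:1:GLY", labs, fn_universe = "network")
  expect_equal(m_net$fn, 0)
  m_all <- evaluate_prediction("A:1:GLY", labs, fn_universe = "all")
  expect_equal(m_all$fn, 1)
})

test_that("metric invariants hold across random confusion counts", {
  set.seed(4)
  for (i in 1:50) {
    tp <- sample(0:10, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    f2 <- if (4 * p + r == 0) 0 else 5 * p * r / (4 * p + r)
    expect_true(all(c(p, r, f1, f2) >= 0 & c(p, r, f1, f2) <= 1))
    expect_lte(f1, max(p, r) + 1e-12)
    if (r > p && p > 0) {
      expect_true(f1 - 1e-12 <= f2 && f2 <= r + 1e-12)
    }
  }
})

test_that("aggregation is the unweighted mean over complexes", {
  m1 <- tibble::tibble(tp = 1, fp = 1, fn = 0, precision = 0.5, recall = 1, f1 = 2/3, f2 = 5/6)
  m2 <- tibble::tibble(tp = 2, fp = 8, fn = 3, precision = 0.2, recall = 0.4, f1 = 4/15, f2 = 1/3)
  agg <- aggregate_metrics(rbind(m1, m2))
  expect_equal(agg$recall, 0.7)
  expect_equal(agg$precision, 0.35)
  expect_equal(agg$n_complexes, 2)
  expect_identical(aggregate_metrics(rbind(m2, m1)), agg)
  expect_equal(aggregate_metrics(m1)$f2, 5/6)
  expect_error(aggregate_metrics(m1[0, ]), class = "denshot_input_error")
})

test_that("SKEMPI-style tables parse to single-point mutation records", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "#Pdb;Mutation(s)_cleaned;Affinity_mut_parsed;Affinity_wt_parsed;Notes",
    "1ABC_A_B;TI17A;1.2E-07;3.4E-09;single",
    "1ABC_A_B;TI17A,GB20A;1E-06;3.4E-09;double point - dropped",
    "2XYZ_C_D;RC100aG;5E-08;5E-09;insertion code"
  ), f)
  tab <- read_skempi(f)
  expect_equal(nrow(tab), 2)
  expect_identical(tab$structure_id, c("1ABC", "2XYZ"))
  expect_identical(tab$chain, c("I", "C"))
  expect_equal(tab$resno, c(17L, 100L))
  expect_identical(tab$icode, c("", "A"))
  expect_identical(tab$mut_aa, c("A", "G"))
  expect_equal(tab$affinity_wt, c(3.4e-09, 5e-09))
  expect_error(read_skempi(f, columns = list(pdb = "nope", mutation = "m",
                                             affinity_wt = "w", affinity_mut = "m2")),
               class = "denshot_input_error")
})
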