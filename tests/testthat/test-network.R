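mk_tally <- function(target, support, n_act = NULL, ids = NULL) {
  all_ids <- unique(unlist(support))
  structure(list(target_id = target, support = support,
                 n_actives = if (is.null(n_act)) length(all_ids) else n_act,
                 active_ids = if (is.null(ids)) all_ids else ids),
            class = "scaffold_tally")
}

test_that("tallies count each compound once per scaffold", {
  act <- data.frame(compound_id = c("a", "b", "c"), target_id = "T1",
                    standardized_smiles = "x", ppot = 6)
  rows <- data.frame(compound_id = c("a", "b", "c", "a"),
                     scaffold_key = c("S1", "S1", "S1", "S1"),
                     amide_class = "lactam", ring_count = 2,
                     attachment_positions = "")
  t1 <- tally_scaffolds(rows, act, "T1")
  expect_equal(lengths(t1$support), c(S1 = 3L))
  expect_error(
    tally_scaffolds(data.frame(compound_id = "zz", scaffold_key = "S1",
                               amide_class = "lactam", ring_count = 2,
                               attachment_positions = ""), act, "T1"),
    "zz")
})

test_that("minimum support filter is inclusive at the boundary", {
  ta <- mk_tally("T1", list(S1 = paste0("c", 1:5), S2 = paste0("c", 1:4)))
  out <- apply_min_support(ta, 5)
  expect_named(out$support, "S1")
  expect_identical(apply_min_support(ta, 1)$support, ta$support)
  empty <- apply_min_support(mk_tally("T1", list()), 5)
  expect_length(empty$support, 0)
})

test_that("coverage fraction and compound-to-core ratio", {
  ta <- mk_tally("T1", list(S1 = c("a", "b"), S2 = c("a", "c")),
                 n_act = 4, ids = c("a", "b", "c", "d"))
  expect_equal(coverage_fraction(ta), 0.75)
  full <- mk_tally("T1", list(S1 = c("a", "b")), n_act = 2, ids = c("a", "b"))
  expect_equal(coverage_fraction(full), 1.0)
  none <- mk_tally("T1", list(), n_act = 3, ids = c("a", "b", "c"))
  expect_equal(coverage_fraction(none), 0.0)
  expect_error(coverage_fraction(mk_tally("T1", list(), n_act = 0,
                                          ids = character(0))), "undefined")
  # 10 compounds over 2 scaffolds -> 5
  ta2 <- mk_tally("T1", list(S1 = paste0("c", 1:10), S2 = paste0("c", 1:8)))
  expect_equal(compound_to_core_ratio(ta2), 5)
  expect_equal(compound_to_core_ratio(mk_tally("T1", list(S1 = "a"))), 1)
  expect_error(compound_to_core_ratio(mk_tally("T1", list())), "undefined")
})

test_that("network is bipartite with support and evidence attributes", {
  ta <- mk_tally("T1", list(S1 = c("a", "b"), S2 = c("c", "d", "e")))
  tb <- mk_tally("T2", list(S1 = c("f", "g"), S3 = c("h", "i")))
  ev <- data.frame(compound_id = c("a", "zz", ""), target_id = c("T1", "T2", "T1"),
                   pdb_code = c("1ABC", "2DEF", "3GHI"))
  expect_warning(net <- build_scaffold_network(list(ta, tb), ev), "malformed")
  kind <- setNames(igraph::V(net)$kind, igraph::V(net)$name)
  el <- igraph::as_edgelist(net)
  # bipartite: every edge joins a scaffold and a target
  expect_true(all(kind[el[, 1]] != kind[el[, 2]]))
  expect_true(igraph::is_bipartite(net))
  # shared scaffold S1 has degree 2
  expect_equal(unname(igraph::degree(net)[c("S1", "S2", "S3")]), c(2, 1, 1))
  # evidence flag only where a supporting compound is in the table
  e1 <- igraph::get_edge_ids(net, c("S1", "T1"))
  e2 <- igraph::get_edge_ids(net, c("S1", "T2"))
  expect_true(igraph::E(net)$pdb_evidence[e1])
  expect_false(igraph::E(net)$pdb_evidence[e2])
  expect_equal(igraph::E(net)$support_count[e1], 2)
})

test_that("shared scaffolds are ranked by evidence, support, then key", {
  ta <- mk_tally("T1", list(A = paste0("a", 1:6), B = paste0("b", 1:9),
                            C = paste0("c", 1:6), X = paste0("x", 1:7)))
  tb <- mk_tally("T2", list(A = paste0("d", 1:6), B = paste0("e", 1:5),
                            C = paste0("f", 1:6), Y = paste0("y", 1:9)))
  ev <- data.frame(compound_id = "b1", target_id = "T1", pdb_code = "1AAA")
  net <- build_scaffold_network(list(ta, tb), ev)
  sh <- shared_scaffolds(net)
  expect_equal(sh$scaffold_key, c("B", "A", "C"))  # B has evidence; A/C tie on
  expect_true(sh$pdb_evidence[1])                  # support, lexicographic order
  # disjoint tallies: no shared scaffolds
  net2 <- build_scaffold_network(list(
    mk_tally("T1", list(S1 = c("a", "b"))),
    mk_tally("T2", list(S2 = c("c", "d")))))
  expect_equal(nrow(shared_scaffolds(net2)), 0)
  expect_error(shared_scaffolds(net, targets = "T1"), "pairwise")
})

test_that("raising min_support never adds shared scaffolds", {
  set.seed(1)
  sup_a <- lapply(setNames(1:6, paste0("S", 1:6)), function(i) {
    paste0("a", seq_len(sample(3:10, 1)))
  })
  sup_b <- lapply(setNames(c(1, 2, 3, 7, 8), paste0("S", c(1, 2, 3, 7, 8))),
                  function(i) paste0("b", seq_len(sample(3:10, 1))))
  prev <- NULL
  for (ms in c(1, 3, 5, 7, 9)) {
    net <- build_scaffold_network(list(
      apply_min_support(mk_tally("T1", sup_a), ms),
      apply_min_support(mk_tally("T2", sup_b), ms)))
    cur <- shared_scaffolds(net)$scaffold_key
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("growth vector profiles and overlap", {
  rows_a <- data.frame(compound_id = c("a1", "a2", "a3"),
                       scaffold_key = "S1", amide_class = "lactam",
                       ring_count = 2,
                       attachment_positions = c("3", "3,5", "3"))
  rows_b <- data.frame(compound_id = c("b1", "b2"),
                       scaffold_key = "S1", amide_class = "lactam",
                       ring_count = 2, attachment_positions = c("3,7", "7"))
  pa <- growth_vector_profile(rows_a, "S1", "T1")
  pb <- growth_vector_profile(rows_b, "S1", "T2")
  expect_equal(pa$freq[["3"]], 3L)
  expect_equal(pa$freq[["5"]], 1L)
  expect_equal(growth_vector_overlap(pa, pb), 3L)
  expect_equal(growth_vector_overlap(pa, pa), c(3L, 5L))
  pd <- growth_vector_profile(
    data.frame(compound_id = "x", scaffold_key = "S1", amide_class = "lactam",
               ring_count = 2, attachment_positions = "9"), "S1", "T2")
  expect_length(growth_vector_overlap(pa, pd), 0)
  p_other <- growth_vector_profile(rows_a, "S2", "T1")
  expect_error(growth_vector_overlap(pa, p_other), "different scaffolds")
})

test_that("network exports round-trip and line counts match", {
  ta <- mk_tally("T1", list(S1 = c("a", "b"), S2 = c("c")))
  tb <- mk_tally("T2", list(S1 = c("d")))
  ev <- data.frame(compound_id = "a", target_id = "T1", pdb_code = "1ABC")
  net <- build_scaffold_network(list(ta, tb), ev)
  f <- tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g2)$name, igraph::V(net)$name)
  expect_equal(igraph::ecount(g2), igraph::ecount(net))
  for (s in c("S1", "S2")) {
    for (t in c("T1", "T2")) {
      e1 <- igraph::get_edge_ids(net, c(s, t), error = FALSE)
      e2 <- igraph::get_edge_ids(g2, c(s, t), error = FALSE)
      expect_equal(e1 > 0, e2 > 0)
      if (e1 > 0) {
        expect_equal(igraph::E(net)$support_count[e1],
                     as.numeric(igraph::E(g2)$support_count[e2]))
        expect_equal(igraph::E(net)$pdb_evidence[e1],
                     as.logical(igraph::E(g2)$pdb_evidence[e2]))
      }
    }
  }
  kind2 <- setNames(igraph::V(g2)$kind, igraph::V(g2)$name)
  expect_equal(unname(kind2[c("S1", "T1")]), c("scaffold", "target"))
  # SIF: one line per edge, scaffold first
  fs <- tempfile(fileext = ".sif")
  export_network(net, fs, "sif")
  lines <- readLines(fs)
  expect_length(lines, igraph::ecount(net))
  expect_true(all(grepl("^S[0-9]+\tinteracts\tT[0-9]+$", lines)))
  # empty network still exports valid documents
  empty <- build_scaffold_network(list(mk_tally("T1", list(), n_act = 1,
                                                ids = "a")))
  fe <- tempfile(fileext = ".graphml")
  export_network(empty, fe, "graphml")
  expect_s3_class(igraph::read_graph(fe, format = "graphml"), "igraph")
  expect_error(export_network(net, tempfile(), "dot"), "graphml, sif, csv")
})

test_that("frequency table ranks scaffolds by support", {
  ta <- mk_tally("T1", list(S1 = paste0("a", 1:3), S2 = paste0("b", 1:7),
                            S3 = paste0("c", 1:5)))
  tab <- scaffold_frequency_table(ta, n = 2)
  expect_equal(tab$scaffold_key, c("S2", "S3"))
  expect_equal(tab$support, c(7, 5))
  expect_equal(tab$rank, 1:2)
})
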