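mk_records <- function(rel, value, units, type = "IC50",
                       cid = paste0("c", seq_along(rel)), tid = "T1",
                       smiles = "c1ccccc1") {
  data.frame(compound_id = cid, smiles = smiles, target_id = tid,
             type = type, relation = rel, value = value, units = units,
             stringsAsFactors = FALSE)
}

test_that("relation filter keeps '=' and '<' and drops '>' and '~'", {
  rec <- mk_records(c("=", ">", "~", "<"), c(100, 10, 1, 50),
                    c("nM", "uM", "uM", "nM"))
  out <- filter_relations(rec)
  expect_equal(out$value, c(100, 50))
  expect_equal(out$relation, c("=", "<"))
  expect_equal(nrow(filter_relations(rec[0, ])), 0)
  expect_equal(nrow(filter_relations(mk_records(c(">", ">"), c(1, 2),
                                               c("uM", "uM")))), 0)
  expect_warning(filter_relations(mk_records("?", 1, "uM")),
                 "unknown relation")
})

test_that("pPOT conversion is exact at the unit boundaries", {
  expect_identical(to_ppot(1, "uM"), 6)
  expect_identical(to_ppot(10, "uM"), 5)    # the 10 uM activity cutoff
  expect_equal(to_ppot(500, "nM"), 6.301, tolerance = 5e-4)
  expect_identical(to_ppot(1, "M"), 0)
  expect_equal(to_ppot(c(1, 1), c("nM", "pM")), c(9, 12))
  expect_error(to_ppot(-1, "uM"), "positive")
  expect_error(to_ppot(0, "uM"), "positive")
  expect_error(to_ppot(1, "furlong"), "unknown unit")
})

test_that("aggregation takes the maximum pPOT across measurement types", {
  rec <- data.frame(compound_id = "a", target_id = "T1",
                    ppot = c(6.0, 5.2, 7.1))
  expect_equal(aggregate_potency(rec)$ppot, 7.1)
  expect_equal(aggregate_potency(rec[2, , drop = FALSE])$ppot, 5.2)
  # IC50 1 uM and Ki 100 nM: brute-force conversion gives max(6, 7) = 7
  two <- data.frame(compound_id = "a", target_id = "T1",
                    ppot = to_ppot(c(1, 100), c("uM", "nM")))
  expect_identical(aggregate_potency(two)$ppot, 7)
  # never below every input nor above the max
  expect_true(all(aggregate_potency(rec)$ppot >= min(rec$ppot)))
})

test_that("activity threshold is inclusive at pPOT = 5", {
  ann <- data.frame(compound_id = c("a", "b", "c"), target_id = "T1",
                    ppot = c(5.0, 4.999, 6.2))
  out <- filter_actives(ann)
  expect_setequal(out$compound_id, c("a", "c"))
  expect_equal(nrow(filter_actives(ann[0, ])), 0)
  # output size is monotonically non-increasing in the threshold
  sizes <- vapply(c(4, 5, 5.5, 6.5), function(th) {
    nrow(filter_actives(ann, th))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("full curation is invariant to input row order", {
  rec <- rbind(
    mk_records(c("=", "=", ">", "<"), c(100, 50, 10, 2000),
               c("nM", "nM", "uM", "nM"), cid = c("a", "b", "a", "c")),
    mk_records("=", 5, "uM", cid = "d", smiles = "CCO"))
  ref <- curate_activities(rec, standardize = FALSE)
  set.seed(3)
  for (r in 1:5) {
    shuffled <- rec[sample(nrow(rec)), ]
    out <- curate_activities(shuffled, standardize = FALSE)
    expect_identical(out[order(out$compound_id), ],
                     ref[order(ref$compound_id), ], ignore_attr = TRUE)
  }
})

test_that("curation validates schema, logs drops, and deduplicates by structure", {
  rec <- rbind(
    mk_records("=", 100, "nM", cid = "a1", smiles = "c1ccccc1O"),
    mk_records("=", 10, "nM", cid = "a2", smiles = "Oc1ccccc1"),  # same structure
    mk_records("=", 1, "parsec", cid = "bad_units"),
    mk_records("=", 1, "uM", type = "AC50", cid = "bad_type"),
    mk_records("=", 1, "uM", cid = "off", tid = "T2"))
  expect_warning(out <- curate_activities(rec, targets = "T1"),
                 "unknown units")
  # duplicate structures pooled under one representative id, max rule applies
  expect_equal(nrow(out), 1)
  expect_equal(out$compound_id, "a1")
  expect_equal(out$ppot, 8)
  log <- attr(out, "drop_log")
  expect_setequal(log$reason[log$compound_id == "bad_units"], "unknown_units")
  expect_setequal(log$reason[log$compound_id == "bad_type"],
                  "unsupported_measure_type")
  expect_setequal(log$reason[log$compound_id == "off"], "off_target")
  map <- attr(out, "id_map")
  expect_equal(map$representative[map$original == "a2"], "a1")
})

test_that("bioactivity tables read with column mapping from YAML config", {
  df <- data.frame(id = "x", structure = "CCO", tgt = "T1", kind = "IC50",
                   rel = "=", val = 1, u = "uM")
  csv <- tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE)
  cfgf <- tempfile(fileext = ".yaml")
  writeLines(c("columns:", "  compound_id: id", "  smiles: structure",
               "  target_id: tgt", "  type: kind", "  relation: rel",
               "  value: val", "  units: u"), cfgf)
  out <- read_bioactivity(csv, cfgf)
  expect_named(out, c("compound_id", "smiles", "target_id", "type",
                      "relation", "value", "units"))
  expect_equal(out$value, 1)
  expect_error(read_bioactivity(csv), "missing column")
})
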