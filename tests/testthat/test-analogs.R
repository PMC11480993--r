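test_that("R-group specs require exactly one attachment marker", {
  rg <- rgroup_spec("acetamido", "*NC(C)=O")
  expect_s3_class(rg, "rgroup_spec")
  expect_error(rgroup_spec("bad", "CCO"), "exactly one attachment")
  expect_error(rgroup_spec("bad", "C(*)*"), "exactly one attachment")
})

test_that("single attachment gives an additive product", {
  slot <- scaffold_slot("benzene", "c1ccccc1", 1)
  rg <- rgroup_spec("methyl", "*C")
  out <- enumerate_analogs(slot, rg)
  expect_equal(nrow(out), 1)
  expect_equal(out$smiles, canonical_smiles("Cc1ccccc1"))
  expect_equal(out$hac, 7)   # 6 + 1: heavy atoms are additive
})

test_that("the design matrix enumerates 4 scaffolds x 3 substituents = 12", {
  slots <- fixture_scaffold_slots()
  rgs <- fixture_rgroups()
  expect_length(slots, 4)
  expect_length(rgs, 3)
  prods <- enumerate_analogs(slots, rgs)
  expect_equal(nrow(prods), 12)
  # every product is a valid, parseable structure with additive atom count
  for (i in seq_len(nrow(prods))) {
    expect_s3_class(parse_smiles(prods$smiles[i]), "an_mol")
    sl <- slots[[match(prods$scaffold_id[i], vapply(slots, `[[`, "", "id"))]]
    rg <- rgs[[match(prods$rgroup_id[i], vapply(rgs, `[[`, "", "id"))]]
    expect_equal(prods$hac[i],
                 heavy_atom_count(sl$scaffold_key) +
                   length(rg$mol$elem) - 1L)
  }
})

test_that("phenanthridinone slot plus the sulfonamide gives the drawn product", {
  slots <- fixture_scaffold_slots()
  rgs <- fixture_rgroups()
  prods <- enumerate_analogs(slots, rgs)
  hf2 <- canonical_smiles(fixture_smiles("HF2"))
  row <- prods[prods$scaffold_id == "phenanthridinone" &
                 prods$rgroup_id == "fluoromethylbenzenesulfonamido", ]
  expect_equal(row$smiles, hf2)
  # the tetrahydro scaffold with the same substituent gives the HF1 structure
  hf1 <- canonical_smiles(fixture_smiles("HF1"))
  row1 <- prods[prods$scaffold_id == "tetrahydrophenanthridinone" &
                  prods$rgroup_id == "fluoromethylbenzenesulfonamido", ]
  expect_equal(row1$smiles, hf1)
})

test_that("valence violations are skipped and logged", {
  # position 1 of the phenanthridinone key is the carbonyl carbon (no H)
  key <- canonical_smiles("O=C1Nc2ccccc2c2ccccc21")
  m <- parse_smiles(key)
  noh <- which(m$hcount == 0 & m$elem == "C")[1]
  slot <- scaffold_slot("bad", key, noh)
  out <- enumerate_analogs(list(slot), fixture_rgroups()[1])
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "skip_log")$reason, "valence")
})

test_that("SAR matrix layout is order-invariant with explicit absent markers", {
  prods <- enumerate_analogs(fixture_scaffold_slots(), fixture_rgroups())
  m0 <- sar_matrix(prods)
  expect_equal(dim(m0), c(4, 3))
  expect_true(all(m0 == "."))
  scores <- data.frame(
    scaffold_id = c("phenanthridinone", "phenanthridinone"),
    rgroup_id = "fluoromethylbenzenesulfonamido",
    target_id = c("PARP1", "BRD4"), score = c(-8.1, -7.2))
  m1 <- sar_matrix(prods, scores)
  expect_equal(m1["phenanthridinone", "fluoromethylbenzenesulfonamido"],
               "BRD4=-7.2; PARP1=-8.1")
  set.seed(2)
  m2 <- sar_matrix(prods[sample(nrow(prods)), ],
                   scores[sample(nrow(scores)), ])
  expect_identical(m1, m2)
  expect_error(
    sar_matrix(prods, data.frame(scaffold_id = "nope", rgroup_id = "x",
                                 target_id = "PARP1", score = 1)),
    "unknown product")
})
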