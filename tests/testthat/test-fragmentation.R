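test_that("preserved bonds cover ring bonds and ring-attached primary amides", {
  # benzamide: C(aryl)-C(=O), amide C-N and C=O all preserved
  m <- parse_smiles("NC(=O)c1ccccc1")
  pres <- identify_preserved_bonds(m)
  b <- m$bonds
  ci <- which(m$elem == "C" & vapply(seq_along(m$elem), function(i) {
    any((b$a1 == i | b$a2 == i) & b$order == 2 &
          m$elem[ifelse(b$a1 == i, b$a2, b$a1)] == "O")
  }, logical(1)))
  carbonyl_bonds <- which(b$a1 == ci | b$a2 == ci)
  expect_true(all(carbonyl_bonds %in% pres))
  expect_length(fragment_compound(m), 1)   # nothing is cleaved

  # N-methylbenzamide: the amide is secondary, so nothing is preserved and
  # the molecule disassembles completely (ring, C=O, N, CH3)
  m2 <- parse_smiles("CNC(=O)c1ccccc1")
  expect_length(fragment_compound(m2), 4)

  # toluene: only the ring bonds are preserved
  m3 <- parse_smiles("Cc1ccccc1")
  expect_equal(sort(identify_preserved_bonds(m3)),
               which(amidenet:::ring_bond_flags(m3)))
})

test_that("fragmentation recovers the known scaffolds of marketed inhibitors", {
  frag_keys <- function(name) {
    frs <- fragment_compound(fixture_smiles(name))
    vapply(frs, function(f) mol_to_smiles(f$mol), character(1))
  }
  expect_true(canonical_smiles("O=c1[nH]ncc2ccccc12") %in%
                frag_keys("olaparib"))                  # phthalazin-1(2H)-one
  expect_true(canonical_smiles("NC(=O)c1cccc2c[nH]nc12") %in%
                frag_keys("niraparib"))                 # indazole carboxamide
  expect_true(canonical_smiles("O=c1[nH]ccc2c1[nH]cc2") %in%
                frag_keys("mivebresib"))                # pyrrolopyridinone
  # talazoparib: one tricyclic lactam scaffold
  scs <- Filter(Negate(is.null),
                lapply(fragment_compound(fixture_smiles("talazoparib")),
                       make_scaffold))
  expect_length(scs, 1)
  expect_equal(scs[[1]]$amide_class, "lactam")
  expect_equal(scs[[1]]$ring_count, 3L)
})

test_that("primary amides survive fragmentation intact", {
  scs <- Filter(Negate(is.null),
                lapply(fragment_compound(fixture_smiles("niraparib")),
                       make_scaffold))
  expect_length(scs, 1)
  expect_equal(scs[[1]]$amide_class, "primary_on_ring")
  key_mol <- parse_smiles(scs[[1]]$canonical_key)
  nh2 <- which(key_mol$elem == "N" & key_mol$hcount == 2)
  expect_length(nh2, 1)
})

test_that("amide classification distinguishes lactam, primary, none", {
  expect_equal(classify_amide_scaffold("O=c1[nH]ncc2ccccc12"), "lactam")
  expect_equal(classify_amide_scaffold("NC(=O)c1nc2ccccc2[nH]1"),
               "primary_on_ring")   # benzimidazole carboxamide
  expect_equal(classify_amide_scaffold("c1ccc2ccccc2c1"), "none")
  expect_equal(classify_amide_scaffold("CNC(=O)c1ccccc1"), "none")
})

test_that("scaffold records keep only bi/tricyclic amides", {
  benzamide <- fragment_compound("NC(=O)c1ccccc1")[[1]]
  expect_null(make_scaffold(benzamide))        # monocyclic
  tet <- fragment_compound("O=c1[nH]c2ccccc2c2c1ccc1ccccc12")[[1]]
  expect_null(make_scaffold(tet))              # tetracyclic
  ok <- Filter(Negate(is.null),
               lapply(fragment_compound(fixture_smiles("HF1")),
                      make_scaffold))
  expect_length(ok, 1)
  expect_equal(ok[[1]]$ring_count, 3L)
  expect_length(ok[[1]]$attachment_positions, 1)
})

test_that("fragmenting a scaffold key returns the same scaffold (idempotence)", {
  keys <- c("O=c1[nH]ncc2c1cccc2", "NC(=O)c1cccc2c1n[nH]c2",
            "O=c1[nH]c2ccccc2c2c1cccc2", "O=C1NCc2c(N1)cccc2")
  for (k in keys) {
    scs <- Filter(Negate(is.null), lapply(fragment_compound(k), make_scaffold))
    expect_length(scs, 1)
    expect_identical(scs[[1]]$canonical_key, canonical_smiles(k), label = k)
    expect_length(scs[[1]]$attachment_positions, 0)
  }
})

test_that("fragmentation conserves heavy atoms on every fixture", {
  cpds <- inpaper_compounds()
  for (i in seq_len(nrow(cpds))) {
    m <- parse_smiles(cpds$smiles[i])
    frs <- fragment_compound(m)
    expect_equal(sum(vapply(frs, function(f) length(f$mol$elem), integer(1))),
                 length(m$elem), label = cpds$name[i])
    # fragments partition the parent's atoms
    atoms <- sort(unlist(lapply(frs, `[[`, "parent_atoms")))
    expect_identical(atoms, seq_along(m$elem))
  }
})

test_that("scaffold keys are invariant to parent atom order", {
  set.seed(42)
  for (nm in c("olaparib", "HF2", "mivebresib")) {
    m <- parse_smiles(fixture_smiles(nm))
    ref <- sort(vapply(Filter(Negate(is.null),
                              lapply(fragment_compound(m), make_scaffold)),
                       `[[`, character(1), "canonical_key"))
    for (r in 1:5) {
      pm <- permute_mol(m, sample(length(m$elem)))
      keys <- sort(vapply(Filter(Negate(is.null),
                                 lapply(fragment_compound(pm), make_scaffold)),
                          `[[`, character(1), "canonical_key"))
      expect_identical(keys, ref, label = nm)
    }
  }
})

test_that("fragmentation matches the brute-force oracle on all fixtures", {
  cpds <- inpaper_compounds()
  for (i in seq_len(nrow(cpds))) {
    m <- parse_smiles(cpds$smiles[i])
    if (length(m$elem) > 30) next
    expect_identical(fragment_atom_sets(m), oracle_fragments(m),
                     label = cpds$name[i])
  }
  # plus assorted edge-case molecules
  extras <- c("CCCC", "C1CCCCC1", "NC(=O)c1ccccc1", "CNC(=O)c1ccccc1",
              "c1ccc(-c2ccccc2)cc1", "O=C(Nc1ccccc1)c1ccccc1",
              "NC(=O)C1CCCCC1", "C1CC2(CC1)CCN(C(N)=O)CC2")
  for (s in extras) {
    m <- parse_smiles(s)
    expect_identical(fragment_atom_sets(m), oracle_fragments(m), label = s)
  }
})

test_that("attachment positions land on the canonical scaffold form", {
  rows <- fragment_molecules(data.frame(
    compound_id = c("hf2", "chembl4469223"),
    smiles = c(fixture_smiles("HF2"), fixture_smiles("CHEMBL4469223"))))
  ph <- rows[rows$scaffold_key == canonical_smiles("O=C1Nc2ccccc2c2ccccc21"), ]
  expect_equal(nrow(ph), 2)
  # both parents substitute the same growth vector
  expect_equal(ph$attachment_positions[1], ph$attachment_positions[2])
})

test_that("a scaffold occurring twice in one parent is counted once", {
  bis <- "O=C1NN=C(Cc3n[nH]c(=O)c4ccccc34)c2ccccc12"
  rows <- fragment_molecules(data.frame(compound_id = "x", smiles = bis))
  expect_equal(nrow(rows), 1)
  expect_equal(rows$scaffold_key, canonical_smiles("O=c1[nH]ncc2ccccc12"))
})
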