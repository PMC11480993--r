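# Test helpers: atom permutation and an independent brute-force
# fragmentation oracle (kept deliberately separate from the package's
# implementation: acyclicity via pairwise reachability after edge deletion,
# the amide-preservation predicate as a direct per-bond scan, and fragment
# assembly via connected components).

permute_mol <- function(mol, perm) {
  remap <- match(seq_along(mol$elem), perm)
  b <- mol$bonds
  b$a1 <- remap[b$a1]
  b$a2 <- remap[b$a2]
  b <- b[sample(nrow(b)), , drop = FALSE]
  m <- amidenet:::an_mol(mol$elem[perm], mol$charge[perm], b,
                         hcount = mol$hcount[perm])
  m
}

.bond_order <- function(mol, i, j) {
  b <- mol$bonds
  k <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
  if (length(k)) b$order[k[1]] else 0L
}

oracle_fragments <- function(mol) {
  b <- mol$bonds
  n <- length(mol$elem)
  g <- amidenet:::mol_igraph(mol)
  acyclic <- vapply(seq_len(nrow(b)), function(k) {
    g2 <- igraph::delete_edges(g, k)
    d <- igraph::distances(g2, v = as.character(b$a1[k]),
                           to = as.character(b$a2[k]))
    is.infinite(d[1, 1])
  }, logical(1))
  ring_atom <- rep(FALSE, n)
  ring_atom[unique(c(b$a1[!acyclic], b$a2[!acyclic]))] <- TRUE
  nbl <- amidenet:::mol_neighbors(mol)
  # ring-attached primary amides: carbonyl C -> (amide N, ring atom)
  amides <- list()
  for (C in which(mol$elem == "C" & !ring_atom)) {
    js <- nbl[[C]]
    has_o <- any(vapply(js, function(j) {
      mol$elem[j] == "O" && .bond_order(mol, C, j) == 2
    }, logical(1)))
    aN <- js[vapply(js, function(j) {
      mol$elem[j] == "N" && .bond_order(mol, C, j) == 1 &&
        length(nbl[[j]]) == 1 && mol$hcount[j] == 2
    }, logical(1))]
    rj <- js[vapply(js, function(j) {
      ring_atom[j] && .bond_order(mol, C, j) == 1
    }, logical(1))]
    if (has_o && length(aN) && length(rj)) {
      amides[[length(amides) + 1]] <- list(C = C, keep = c(aN, rj))
    }
  }
  cut <- which(acyclic & b$order == 1)
  keep_bond <- vapply(cut, function(k) {
    i <- b$a1[k]; j <- b$a2[k]
    for (am in amides) {
      if ((i == am$C && j %in% am$keep) || (j == am$C && i %in% am$keep)) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  cut <- cut[!keep_bond]
  g2 <- igraph::delete_edges(g, cut)
  comp <- igraph::components(g2)
  parts <- lapply(split(seq_len(n), comp$membership),
                  function(a) as.integer(sort(unname(a))))
  unname(parts[order(vapply(parts, `[`, integer(1), 1))])
}

fragment_atom_sets <- function(mol) {
  frs <- fragment_compound(mol)
  parts <- lapply(frs, function(f) as.integer(sort(unname(f$parent_atoms))))
  unname(parts[order(vapply(parts, `[`, integer(1), 1))])
}
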