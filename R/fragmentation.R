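# Amide-preserving fragmentation.
#
# Compounds are decomposed by simultaneous cleavage of every acyclic single
# bond, with one exception: a primary amide (C(=O)NH2) whose carbonyl
# carbon sits directly on a ring atom stays attached to its ring system --
# the carbonyl-to-ring bond, the amide C-N bond and the C=O bond are never
# cut. Cleaved valences are capped with hydrogens, and each fragment
# records where substituents were removed (attachment points, the growth
# vectors of the parent series).

# Atom indices of primary amide groups attached to rings:
# list of (carbonyl C, amide N, carbonyl O, ring atom).
.an_primary_amides <- function(mol, ring_atoms, rb) {
  nb <- mol_neighbors(mol)
  b <- mol$bonds
  out <- list()
  for (i in which(mol$elem == "C")) {
    if (i %in% ring_atoms) next
    ks <- which(b$a1 == i | b$a2 == i)
    o <- n <- r <- NA_integer_
    for (k in ks) {
      j <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
      if (b$order[k] == 2 && mol$elem[j] == "O") o <- j
      if (b$order[k] == 1 && mol$elem[j] == "N" &&
          length(nb[[j]]) == 1 && mol$hcount[j] == 2 &&
          mol$charge[j] == 0) n <- j
      if (b$order[k] == 1 && j %in% ring_atoms) r <- j
    }
    if (!is.na(o) && !is.na(n) && !is.na(r)) {
      out[[length(out) + 1]] <- c(C = i, N = n, O = o, ring = r)
    }
  }
  out
}

#' Bonds preserved during fragmentation
#'
#' Returns the indices (rows of the molecule's bond table) of all bonds
#' that survive fragmentation: ring bonds, the internal bonds of any
#' ring-attached primary amide (its C-N and C=O bonds), and the single bond
#' connecting that carbonyl carbon to the ring.
#'
#' @param mol a molecule object or SMILES string.
#' @return integer vector of preserved bond indices.
#' @export
identify_preserved_bonds <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  rb <- ring_bond_flags(mol)
  preserved <- which(rb)
  b <- mol$bonds
  ring_atoms <- unique(c(b$a1[rb], b$a2[rb]))
  for (am in .an_primary_amides(mol, ring_atoms, rb)) {
    ks <- which((b$a1 == am[["C"]] & b$a2 %in% am[c("N", "O", "ring")]) |
                (b$a2 == am[["C"]] & b$a1 %in% am[c("N", "O", "ring")]))
    preserved <- union(preserved, ks)
  }
  sort(preserved)
}

#' Fragment a compound by simultaneous acyclic single-bond cleavage
#'
#' All acyclic single bonds outside the preserved set (see
#' [identify_preserved_bonds()]) are broken at once. Each resulting
#' connected fragment is returned with hydrogen-capped valences and an
#' attachment annotation: for every fragment atom, the number of
#' substituent bonds cleaved there.
#'
#' @param mol a molecule object or SMILES string.
#' @return a list of fragments, each a list with elements `mol` (the
#'   fragment as a molecule object), `attachments` (integer vector per
#'   fragment atom: number of cleaved bonds), and `parent_atoms` (the atom
#'   indices in the parent).
#' @export
fragment_compound <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  b <- mol$bonds
  preserved <- identify_preserved_bonds(mol)
  cut <- setdiff(which(b$order == 1), preserved)
  cut <- cut[!ring_bond_flags(mol)[cut]]
  n_cut <- integer(length(mol$elem))
  for (k in cut) {
    n_cut[b$a1[k]] <- n_cut[b$a1[k]] + 1L
    n_cut[b$a2[k]] <- n_cut[b$a2[k]] + 1L
  }
  keep <- setdiff(seq_len(nrow(b)), cut)
  g <- igraph::graph_from_data_frame(
    d = b[keep, c("a1", "a2"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = seq_along(mol$elem)))
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(ci) {
    atoms <- unname(which(comp$membership == ci))
    sub <- mol_subset(mol, atoms, add_h = n_cut[atoms])
    list(mol = sub, attachments = n_cut[atoms], parent_atoms = atoms)
  })
}

#' Classify the amide character of a fragment
#'
#' A fragment is a `lactam` if an amide C(=O)-N bond lies inside a ring
#' (both carbonyl carbon and nitrogen are ring atoms), `primary_on_ring`
#' if it carries a preserved primary amide hanging off a ring atom, and
#' `none` otherwise. Fragments with both motifs are reported as `lactam`.
#'
#' @param fragment a fragment from [fragment_compound()], or a molecule
#'   object / SMILES string.
#' @return one of `"lactam"`, `"primary_on_ring"`, `"none"`.
#' @export
classify_amide_scaffold <- function(fragment) {
  mol <- if (is.list(fragment) && !inherits(fragment, "an_mol"))
    fragment$mol else fragment
  if (is.character(mol)) mol <- parse_smiles(mol)
  rb <- ring_bond_flags(mol)
  b <- mol$bonds
  has_exo_o <- function(i) {
    any((b$a1 == i | b$a2 == i) & b$order == 2 &
          mol$elem[ifelse(b$a1 == i, b$a2, b$a1)] == "O")
  }
  for (k in which(rb & b$order == 1)) {
    ij <- c(b$a1[k], b$a2[k])
    ci <- ij[mol$elem[ij] == "C"]
    ni <- ij[mol$elem[ij] == "N"]
    if (length(ci) == 1 && length(ni) == 1 && has_exo_o(ci)) return("lactam")
  }
  ring_atoms <- unique(c(b$a1[rb], b$a2[rb]))
  if (length(.an_primary_amides(mol, ring_atoms, rb))) {
    return("primary_on_ring")
  }
  "none"
}

# Canonical atom positions: indices of the reference molecule obtained by
# re-parsing the fragment's canonical SMILES. The mapping is the
# lexicographically smallest vertex-colored graph isomorphism, so positions
# are reproducible across runs and across parents. Bond orders inside
# aromatic rings are normalized before matching (two isomorphic molecules
# may carry different kekule assignments).
.an_canonical_map <- function(frag_mol, key_mol) {
  colorize <- function(m) {
    as.integer(factor(paste(m$elem, m$charge, m$hcount),
                      levels = sort(unique(c(
                        paste(frag_mol$elem, frag_mol$charge, frag_mol$hcount),
                        paste(key_mol$elem, key_mol$charge, key_mol$hcount))))))
  }
  ecolor <- function(m) {
    ar <- perceive_aromaticity(m)$bond
    ifelse(ar, 9L, m$bonds$order)
  }
  g1 <- mol_igraph(frag_mol); g2 <- mol_igraph(key_mol)
  isos <- igraph::graph.get.isomorphisms.vf2(
    g1, g2, vertex.color1 = colorize(frag_mol),
    vertex.color2 = colorize(key_mol),
    edge.color1 = ecolor(frag_mol), edge.color2 = ecolor(key_mol))
  if (!length(isos)) {
    stop("fragment does not map onto its canonical form", call. = FALSE)
  }
  maps <- lapply(isos, function(v) as.integer(v))
  ord <- do.call(order, as.data.frame(do.call(rbind, maps)))
  maps[[ord[1]]]
}

#' Build an amide scaffold record from a fragment
#'
#' A fragment qualifies as a scaffold when it contains an amide (lactam or
#' ring-attached primary amide) and its ring count is in `allowed_rings`
#' (bicyclic or tricyclic by default). The canonical key is the fragment's
#' canonical SMILES after hydrogen capping, so the same chemotype from
#' different parents collapses to one key; attachment positions are kept in
#' the coordinates of the canonical form.
#'
#' @param fragment a fragment from [fragment_compound()].
#' @param allowed_rings integer vector of admissible ring counts.
#' @return a list with `canonical_key`, `amide_class`, `ring_count` and
#'   `attachment_positions`, or `NULL` for non-qualifying fragments.
#' @export
make_scaffold <- function(fragment, allowed_rings = c(2L, 3L)) {
  mol <- fragment$mol
  rc <- nrow(mol$bonds) - length(mol$elem) + 1L
  if (!(rc %in% allowed_rings)) return(NULL)
  cls <- classify_amide_scaffold(fragment)
  if (cls == "none") return(NULL)
  key <- mol_to_smiles(mol)
  pos <- integer(0)
  att <- which(fragment$attachments > 0)
  if (length(att)) {
    key_mol <- parse_smiles(key)
    map <- .an_canonical_map(mol, key_mol)
    pos <- sort(map[att])
  }
  list(canonical_key = key, amide_class = cls, ring_count = rc,
       attachment_positions = pos)
}

#' Fragment a set of compounds into scaffold rows
#'
#' Batch driver: fragments every compound and collects its qualifying amide
#' scaffolds.
#'
#' @param compounds data.frame with columns `compound_id` and `smiles`
#'   (standardized SMILES).
#' @param allowed_rings admissible ring counts (default bicyclic/tricyclic).
#' @return data.frame with columns `compound_id`, `scaffold_key`,
#'   `amide_class`, `ring_count`, `attachment_positions` (comma-separated
#'   canonical positions). A scaffold occurring twice in one parent gives a
#'   single row (set semantics). The `discard_log` attribute counts
#'   non-qualifying fragments per reason.
#' @export
fragment_molecules <- function(compounds, allowed_rings = c(2L, 3L)) {
  rows <- list()
  discards <- c(acyclic = 0L, no_amide = 0L, ring_count = 0L)
  for (i in seq_len(nrow(compounds))) {
    frags <- fragment_compound(compounds$smiles[i])
    seen <- character(0)
    for (fr in frags) {
      rc <- nrow(fr$mol$bonds) - length(fr$mol$elem) + 1L
      if (rc == 0) { discards["acyclic"] <- discards["acyclic"] + 1L; next }
      sc <- make_scaffold(fr, allowed_rings)
      if (is.null(sc)) {
        reason <- if (!(rc %in% allowed_rings)) "ring_count" else "no_amide"
        discards[reason] <- discards[reason] + 1L
        next
      }
      if (sc$canonical_key %in% seen) next   # count each parent once
      seen <- c(seen, sc$canonical_key)
      rows[[length(rows) + 1]] <- data.frame(
        compound_id = compounds$compound_id[i],
        scaffold_key = sc$canonical_key,
        amide_class = sc$amide_class,
        ring_count = sc$ring_count,
        attachment_positions = paste(sc$attachment_positions, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    compound_id = character(), scaffold_key = character(),
    amide_class = character(), ring_count = integer(),
    attachment_positions = character(), stringsAsFactors = FALSE)
  attr(out, "discard_log") <- discards
  out
}
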