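# Ring perception and aromaticity.
#
# Ring bonds are the non-bridge edges of the heavy-atom graph. Ring systems
# are connected components of the ring-bond subgraph (fused and spiro rings
# share a system); the ring count of a system is its cyclomatic number,
# which equals the size of a smallest set of smallest rings.
#
# Aromaticity follows the common Hueckel electron-counting model on smallest
# rings of the kekulized graph: an in-ring double bond contributes one
# electron per atom, a carbonyl-type exocyclic double bond contributes zero,
# and a ring heteroatom with only single bonds contributes its lone pair
# (two). Rings whose electron count is 4n + 2 and whose atoms are all
# pi-capable are aromatic. This reproduces the widely used model in which
# 2-pyridone-type lactam rings are aromatic.

ring_bond_flags <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  g <- mol_igraph(mol)
  flags <- rep(TRUE, nb)
  flags[igraph::bridges(g)] <- FALSE
  flags
}

#' Ring systems of a molecule
#'
#' A ring system is a maximal set of atoms connected through ring bonds;
#' fused and spiro rings belong to one system. The number of rings in a
#' system is its cyclomatic number (equal to the smallest-set-of-smallest-
#' rings count).
#'
#' @param mol a molecule object or SMILES string.
#' @return a list with one entry per ring system: `atoms` (integer atom
#'   indices) and `ring_count`. Acyclic molecules give an empty list.
#' @examples
#' length(find_ring_systems("CCCC"))          # 0
#' find_ring_systems("O=C1Nc2ccccc2c2ccccc12")[[1]]$ring_count  # 3
#' @export
find_ring_systems <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  rb <- ring_bond_flags(mol)
  if (!any(rb)) return(list())
  b <- mol$bonds[rb, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    b[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = sort(unique(c(b$a1, b$a2)))))
  comp <- igraph::components(g)
  vnames <- as.integer(igraph::V(g)$name)
  lapply(seq_len(comp$no), function(ci) {
    atoms <- vnames[comp$membership == ci]
    n_edges <- sum(b$a1 %in% atoms & b$a2 %in% atoms)
    list(atoms = sort(atoms), ring_count = n_edges - length(atoms) + 1L)
  })
}

# Smallest rings: for every ring bond, the shortest cycle through it.
# Returned as a list of integer atom-index vectors (deduplicated).
smallest_rings <- function(mol) {
  rb <- which(ring_bond_flags(mol))
  if (!length(rb)) return(list())
  g <- mol_igraph(mol)
  rings <- list()
  seen <- character(0)
  for (k in rb) {
    a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
    g2 <- igraph::delete_edges(g, k)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(a1), to = as.character(a2))$vpath[[1]])
    if (length(sp) < 2) next
    ring <- as.integer(igraph::V(g)$name[sp])
    key <- paste(sort(ring), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

# Aromaticity perception; returns list(atom = logical, bond = logical).
perceive_aromaticity <- function(mol) {
  n <- length(mol$elem)
  arom_atom <- logical(n)
  arom_bond <- logical(nrow(mol$bonds))
  rings <- smallest_rings(mol)
  if (!length(rings)) return(list(atom = arom_atom, bond = arom_bond))

  rb <- ring_bond_flags(mol)
  b <- mol$bonds
  # per-atom multiple-bond bookkeeping
  dbl_ring <- rep(FALSE, n)      # has a double bond that is a ring bond
  dbl_exo_polar <- rep(FALSE, n) # exocyclic double bond to N/O/S
  dbl_exo_other <- rep(FALSE, n)
  dbl_partner_ring <- vector("list", n) # ring-bond double partners
  has_triple <- rep(FALSE, n)
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2) {
      for (side in 1:2) {
        at <- if (side == 1) b$a1[k] else b$a2[k]
        ot <- if (side == 1) b$a2[k] else b$a1[k]
        if (rb[k]) {
          dbl_ring[at] <- TRUE
          dbl_partner_ring[[at]] <- c(dbl_partner_ring[[at]], ot)
        } else if (mol$elem[ot] %in% c("N", "O", "S")) {
          dbl_exo_polar[at] <- TRUE
        } else {
          dbl_exo_other[at] <- TRUE
        }
      }
    } else if (b$order[k] >= 3) {
      has_triple[b$a1[k]] <- TRUE; has_triple[b$a2[k]] <- TRUE
    }
  }
  deg <- integer(n)
  for (k in seq_len(nrow(b))) {
    deg[b$a1[k]] <- deg[b$a1[k]] + 1L
    deg[b$a2[k]] <- deg[b$a2[k]] + 1L
  }
  conn <- deg + mol$hcount

  for (ring in rings) {
    if (length(ring) < 5 || length(ring) > 7) next
    electrons <- 0L
    ok <- TRUE
    for (at in ring) {
      el <- mol$elem[at]
      if (!(el %in% c("C", "N", "O", "S")) || has_triple[at] || conn[at] > 3) {
        ok <- FALSE; break
      }
      if (dbl_ring[at]) {
        electrons <- electrons + 1L
      } else if (dbl_exo_polar[at] && el == "C") {
        electrons <- electrons + 0L
      } else if (dbl_exo_other[at]) {
        electrons <- electrons + 0L
      } else if (el == "C") {
        ok <- FALSE; break      # sp3 carbon cannot be aromatic
      } else {
        electrons <- electrons + 2L  # heteroatom lone pair
      }
    }
    if (ok && electrons %% 4L == 2L) {
      arom_atom[ring] <- TRUE
      inring <- b$a1 %in% ring & b$a2 %in% ring & rb
      arom_bond[inring] <- TRUE
    }
  }
  list(atom = arom_atom, bond = arom_bond)
}
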