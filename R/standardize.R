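# Structure standardization.
#
# Re-implements a registration-style cleaning cascade: keep the largest
# covalent component (salt stripping), neutralize protonation-state charges
# where chemically valid, unify ring lactim forms to the lactam tautomer,
# and emit a canonical SMILES. The cascade is deterministic and idempotent.

.an_components <- function(mol) {
  g <- mol_igraph(mol)
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(ci) which(comp$membership == ci))
}

# Neutralize protonation-state charges: deprotonate cationic N-H, protonate
# anionic O/S/N -- unless the charge is balanced by a bonded opposite charge
# (nitro groups, N-oxides, quaternary ammonium stay untouched).
.an_neutralize <- function(mol) {
  nb <- mol_neighbors(mol)
  for (i in seq_along(mol$elem)) {
    chg <- mol$charge[i]
    if (chg == 0) next
    bonded_opp <- any(sign(mol$charge[nb[[i]]]) == -sign(chg))
    if (bonded_opp) next
    if (chg > 0 && mol$elem[i] == "N" && mol$hcount[i] >= chg) {
      mol$hcount[i] <- mol$hcount[i] - chg
      mol$charge[i] <- 0L
    } else if (chg < 0 && mol$elem[i] %in% c("O", "S", "N")) {
      mol$hcount[i] <- mol$hcount[i] - chg
      mol$charge[i] <- 0L
    }
  }
  mol
}

# Deterministic tautomer rule: ring lactim C(-OH)=N is rewritten to the
# lactam C(=O)-NH form, so lactam/lactim pairs collapse to one scaffold key.
.an_lactamize <- function(mol) {
  rb <- ring_bond_flags(mol)
  b <- mol$bonds
  repeat {
    changed <- FALSE
    for (i in which(mol$elem == "C")) {
      k_oh <- which((b$a1 == i | b$a2 == i) & b$order == 1)
      k_oh <- k_oh[vapply(k_oh, function(k) {
        j <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
        mol$elem[j] == "O" && mol$hcount[j] >= 1 && mol$charge[j] == 0 && !rb[k]
      }, logical(1))]
      k_cn <- which((b$a1 == i | b$a2 == i) & b$order == 2 & rb)
      k_cn <- k_cn[vapply(k_cn, function(k) {
        j <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
        mol$elem[j] == "N"
      }, logical(1))]
      if (length(k_oh) && length(k_cn)) {
        k1 <- k_oh[1]; k2 <- k_cn[1]
        o <- if (b$a1[k1] == i) b$a2[k1] else b$a1[k1]
        nn <- if (b$a1[k2] == i) b$a2[k2] else b$a1[k2]
        mol$bonds$order[k1] <- 2L
        mol$bonds$order[k2] <- 1L
        mol$hcount[o] <- mol$hcount[o] - 1L
        mol$hcount[nn] <- mol$hcount[nn] + 1L
        b <- mol$bonds
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mol
}

#' Standardize a chemical structure
#'
#' Applies a deterministic cleaning cascade: (1) keep the largest covalent
#' component by heavy atom count (ties broken by molecular weight), (2)
#' neutralize protonation-state charges where chemically valid, (3) rewrite
#' ring lactim forms to the lactam tautomer, (4) canonicalize. The result is
#' idempotent: standardizing a standardized SMILES returns it unchanged.
#'
#' @param smiles a single SMILES string.
#' @return the standardized canonical SMILES string.
#' @examples
#' standardize_structure("c1ccccc1.[Na+].[Cl-]")  # "c1ccccc1"
#' standardize_structure("CC(=O)[O-]")            # neutralized acetate
#' @export
standardize_structure <- function(smiles) {
  mol <- tryCatch(parse_smiles(smiles), error = function(e) {
    stop(structure(
      class = c("amidenet_parse_error", "error", "condition"),
      list(message = conditionMessage(e), call = sys.call(-1),
           smiles = smiles)))
  })
  comps <- .an_components(mol)
  if (length(comps) > 1) {
    size <- vapply(comps, length, integer(1))
    best <- which(size == max(size))
    if (length(best) > 1) {
      mw <- vapply(comps[best], function(a) {
        mol_weight(mol_subset(mol, a))
      }, numeric(1))
      best <- best[which.max(mw)]
    } else {
      best <- best[1]
    }
    mol <- mol_subset(mol, comps[[best]])
  }
  mol <- .an_neutralize(mol)
  mol <- .an_lactamize(mol)
  mol_to_smiles(mol)
}
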