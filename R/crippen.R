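# Wildman-Crippen atomic-contribution logP.
#
# Implements the atom classification scheme of Wildman & Crippen (1999):
# each atom (including implicit hydrogens) is assigned one of ~70 types by
# an ordered rule list over element, aromaticity, hydrogen count, charge and
# neighborhood; cLogP is the sum of the per-type contributions. The rule
# order mirrors the published priority: the first matching type wins.

.crippen_values <- c(
  C1 = 0.1441,  C2 = 0,       C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
  C6 = 0.1551,  C7 = 0.0017,  C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
  C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0,    C15 = 0.245,
  C16 = 0.198,  C17 = 0,      C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
  C21 = 0.136,  C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
  C26 = 0.264,  C27 = 0.2148, CS = 0.08129,
  H1 = 0.123,   H2 = -0.2677, H3 = 0.2142,  H4 = 0.298,   HS = 0.1125,
  N1 = -1.019,  N2 = -0.7096, N3 = -1.027,  N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836,  N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.95,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552,  O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189,  O8 = 0.1788,  O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  F = 0.4202,   Cl = 0.6895,  Br = 0.8456,  I = 0.8857,   Hal = -2.996,
  P = 0.8612,   S1 = 0.6482,  S2 = -0.0024, S3 = 0.6237,
  Me1 = -0.3808, Me2 = -0.0025
)

.crippen_het <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")
.crippen_me1 <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
                  "B", "Al", "Ga", "In", "Tl", "Si", "Ge", "Sn", "Pb",
                  "As", "Sb", "Bi", "Se", "Te", "Po")

# Per-molecule typing context.
.crippen_ctx <- function(mol) {
  arom <- perceive_aromaticity(mol)
  n <- length(mol$elem)
  nbrs <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    e <- list(
      list(j = b$a2[k], order = b$order[k], arom = arom$bond[k]),
      list(j = b$a1[k], order = b$order[k], arom = arom$bond[k]))
    nbrs[[b$a1[k]]] <- c(nbrs[[b$a1[k]]], e[1])
    nbrs[[b$a2[k]]] <- c(nbrs[[b$a2[k]]], e[2])
  }
  list(arom = arom$atom, nbrs = nbrs)
}

.crippen_type_heavy <- function(mol, i, ctx) {
  el <- mol$elem[i]
  chg <- mol$charge[i]
  h <- mol$hcount[i]
  ar <- ctx$arom[i]
  nb <- ctx$nbrs[[i]]
  deg <- length(nb)
  X <- deg + h
  jel <- vapply(nb, function(e) mol$elem[e$j], character(1))
  jar <- vapply(nb, function(e) ctx$arom[e$j], logical(1))
  jord <- vapply(nb, function(e) e$order, numeric(1))
  jab <- vapply(nb, function(e) e$arom, logical(1))

  if (el == "C") {
    if (!ar) {
      sp3 <- all(jord == 1)
      if (sp3) {
        all_ali <- all(!jar)
        allC_ali <- all_ali && all(jel == "C")
        het_ali <- any(jel %in% .crippen_het & !jar)
        if (h == 4 || (h == 3 && deg == 1 && allC_ali) ||
            (h == 2 && deg == 2 && allC_ali)) return("C1")
        if ((h == 1 && deg == 3 && allC_ali) ||
            (h == 0 && deg == 4 && allC_ali)) return("C2")
        if (h == 3 && deg == 1 && het_ali) return("C3")
        if (h == 2 && deg == 2 && het_ali && all_ali) return("C3")
        if (h == 1 && deg == 3 && het_ali && all_ali) return("C4")
        if (h == 0 && deg == 4 && het_ali && all_ali) return("C4")
        if (h == 3 && deg == 1 && jar[1]) {
          return(if (jel[1] == "C") "C8" else "C9")
        }
        if (any(jar)) {
          if (h == 2) return("C10")
          if (h == 1) return("C11")
          if (h == 0) return("C12")
        }
        if (any(!jar & !jel %in% c(.crippen_het, "C", "H"))) return("C27")
        return("CS")
      }
      dbl <- jord == 2
      if (any(dbl & jel != "C" & !jar)) return("C5")
      dblC_ali <- any(dbl & jel == "C" & !jar)
      if (dblC_ali) {
        rest_ali <- all(!jar[!dbl])
        if (h == 2 && deg == 1) return("C6")
        if (h == 1 && deg == 2 && rest_ali) return("C6")
        if (h == 0 && deg == 3 && rest_ali) return("C6")
        if (sum(dbl & jel == "C") >= 2) return("C6")   # allene
      }
      if (X == 2 && any(jord >= 3 & !jar)) return("C7")
      if (any(dbl & jar)) return("C26")                # [C]=c
      if (dblC_ali && any(jar)) return("C26")
      return("CS")
    }
    # aromatic carbon
    subst <- !jab                                      # non-aromatic bonds
    if (h == 0 && any(subst & jord == 1 & !jar &
                      !jel %in% c(.crippen_het, "C", "H"))) return("C13")
    if (any(jel == "F")) return("C14")
    if (any(jel == "Cl")) return("C15")
    if (any(jel == "Br")) return("C16")
    if (any(jel == "I")) return("C17")
    if (h >= 1) return("C18")
    if (sum(jab) >= 3) return("C19")
    if (any(subst & jord == 1 & jar)) return("C20")
    if (any(subst & jord == 1 & jel == "C" & !jar)) return("C21")
    if (any(subst & jord == 1 & jel == "N" & !jar)) return("C22")
    if (any(subst & jord == 1 & jel == "O" & !jar)) return("C23")
    if (any(subst & jord == 1 & jel == "S" & !jar)) return("C24")
    if (any(subst & jord == 2 & jel %in% c("C", "N", "O"))) return("C25")
    return("CS")
  }

  if (el == "N") {
    if (chg > 0) {
      if (h >= 1 && !ar) return("N10")
      if (ar) return("N12")
      if (deg == 4 && all(jord == 1)) return("N13")
      if (any(jord == 2) && deg == 3) return("N13")
      if (any(jord >= 3)) return("N14")
      return("NS")
    }
    if (chg < 0) return("N14")
    if (ar) return("N11")
    if (h == 2 && deg == 1) return(if (jar[1]) "N3" else "N1")
    if (h == 1 && deg == 2 && any(jord == 2)) return("N5")
    if (h == 1 && deg == 2) return(if (any(jar)) "N4" else "N2")
    if (h == 0 && any(jord >= 3)) return("N9")
    if (h == 0 && any(jord == 2) && deg == 2) return("N6")
    if (h == 0 && deg == 3 && all(jord == 1)) {
      return(if (any(jar)) "N8" else "N7")
    }
    return("NS")
  }

  if (el == "O") {
    if (ar) return("O1")
    if (h >= 1 && chg == 0) return("O2")
    if (chg < 0) {
      if (deg == 1) {
        j <- nb[[1]]$j
        if (jel[1] == "N") return("O5")
        if (jel[1] == "S") return("O6")
        if (jel[1] == "C") {
          cnb <- ctx$nbrs[[j]]
          if (any(vapply(cnb, function(e) {
            e$order == 2 && mol$elem[e$j] == "O"
          }, logical(1)))) return("O12")
        }
      }
      return("O7")
    }
    if (deg == 2 && all(jord == 1)) {
      return(if (any(jar)) "O4" else "O3")
    }
    if (deg == 1 && jord[1] == 2) {
      if (jel[1] %in% c("N", "O")) return("O5")
      if (jel[1] == "S") return("O6")
      if (jel[1] == "C" && jar[1]) return("O8")
      if (jel[1] == "C") {
        # classify by the carbonyl carbon's other neighbors
        j <- nb[[1]]$j
        cnb <- Filter(function(e) e$j != i, ctx$nbrs[[j]])
        oel <- vapply(cnb, function(e) mol$elem[e$j], character(1))
        oar <- vapply(cnb, function(e) ctx$arom[e$j], logical(1))
        ch <- mol$hcount[j]
        if (ch == 1 && length(cnb) == 1) {
          if (oel == "C" && !oar) return("O9")       # aliphatic aldehyde
          if (oel %in% c("N", "O") && !oar) return("O9")
          if (oel == "C" && oar) return("O10")       # aryl aldehyde
        }
        if (ch == 2 && length(cnb) == 0) return("O9") # formaldehyde
        if (length(cnb) == 2) {
          if (all(oel != "C")) return("O11")          # e.g. urea, carbamate
          if (any(oel == "C" & !oar) && all(!oar)) return("O9")
          if (any(oel == "C") && any(oar)) return("O10")
          if (any(oel == "C" & oar)) return("O10")
        }
      }
    }
    return("OS")
  }

  if (el == "S") {
    if (chg != 0) return("S2")
    if (any(jord == 2 & jel %in% c("N", "O", "P", "S"))) return("S2")
    if (ar) return("S3")
    return("S1")
  }

  if (el %in% c("F", "Cl", "Br", "I")) {
    if (chg < 0) return("Hal")
    if (el == "I" && chg > 0) return("Hal")
    return(el)
  }
  if (el == "P") return("P")
  if (el %in% c("Li", "Na", "K", "Rb", "Cs") && chg > 0) return("Hal")
  if (el %in% .crippen_me1) return("Me1")
  "Me2"
}

.crippen_type_h <- function(mol, i, ctx) {
  el <- mol$elem[i]
  if (el == "C") return("H1")
  if (el == "N") return("H3")
  if (el == "O") {
    nb <- ctx$nbrs[[i]]
    if (length(nb) == 0) return("HS")
    j <- nb[[1]]$j
    jel <- mol$elem[j]
    if (jel == "N") return("H3")
    if (jel %in% c("O", "S")) return("H4")
    if (jel == "C") {
      if (ctx$arom[j]) return("H2")                 # phenol-type
      cnb <- ctx$nbrs[[j]]
      sp3 <- all(vapply(cnb, function(e) e$order, numeric(1)) == 1)
      if (sp3) return("H2")                         # alcohol
      enol <- any(vapply(cnb, function(e) {
        e$order == 2 && mol$elem[e$j] %in% c("C", "N", "O", "S")
      }, logical(1)))
      if (enol) return("H4")                        # acid / enol
      return("HS")
    }
    return("H2")                                    # O on P, B, ...
  }
  "H2"                                              # H on S and others
}

#' Per-atom Wildman-Crippen typing and contributions
#'
#' @param mol a molecule object or SMILES string.
#' @return a data.frame with one row per heavy atom: element, assigned atom
#'   type, the atom's own contribution, the number of attached hydrogens,
#'   their type, and the total contribution (atom plus its hydrogens).
#' @export
crippen_contributions <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  ctx <- .crippen_ctx(mol)
  n <- length(mol$elem)
  type <- character(n); htype <- character(n)
  for (i in seq_len(n)) {
    type[i] <- .crippen_type_heavy(mol, i, ctx)
    htype[i] <- if (mol$hcount[i] > 0) .crippen_type_h(mol, i, ctx) else NA
  }
  atom_c <- unname(.crippen_values[type])
  h_c <- ifelse(is.na(htype), 0,
                mol$hcount * unname(.crippen_values[htype]))
  data.frame(
    atom = seq_len(n), element = mol$elem, type = type,
    contribution = atom_c, n_h = mol$hcount, h_type = htype,
    total = atom_c + h_c, stringsAsFactors = FALSE
  )
}

#' Wildman-Crippen cLogP
#'
#' Calculated octanol/water partition coefficient by the atomic-contribution
#' method of Wildman & Crippen: the sum over all atoms (hydrogens included)
#' of their type contributions.
#'
#' @param mol a molecule object or SMILES string.
#' @return numeric cLogP (unitless).
#' @examples
#' crippen_logp("c1ccccc1")    # benzene, about 1.69
#' @export
crippen_logp <- function(mol) {
  sum(crippen_contributions(mol)$total)
}
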