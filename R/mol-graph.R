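# Internal molecular graph model.
#
# Molecules are handled as plain graphs of heavy atoms: element, formal
# charge, implicit hydrogen count, and a bond table with kekulized orders.
# SMILES/molfile interconversion is delegated to OpenBabel via ChemmineOB;
# everything downstream (rings, aromaticity, fragmentation, atom typing)
# operates on this representation.

# Default valences used to derive implicit hydrogen counts from a kekulized
# bond order sum. Multi-valent S and P use the smallest admissible valence.
.an_valences <- list(
  C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1, B = 3, Si = 4,
  P = c(3, 5), S = c(2, 4, 6)
)

.an_implicit_h <- function(elem, charge, bosum) {
  v <- .an_valences[[elem]]
  if (is.null(v)) return(0L)          # metals and exotica: no implicit H
  # common charge adjustments for organic elements
  if (elem %in% c("N", "O")) v <- v + charge
  if (elem == "C" && charge != 0) v <- 3
  if (elem %in% c("F", "Cl", "Br", "I", "S") && charge < 0) v <- v + charge
  v <- v[v >= bosum]
  if (length(v) == 0) return(0L)
  as.integer(max(0, min(v) - bosum))
}

an_mol <- function(elem, charge, bonds, hcount = NULL, name = NA_character_) {
  n <- length(elem)
  charge <- as.integer(charge)
  bonds <- as.data.frame(bonds)
  names(bonds) <- c("a1", "a2", "order")[seq_len(ncol(bonds))]
  if (is.null(hcount)) {
    bosum <- integer(n)
    if (nrow(bonds)) {
      for (k in seq_len(nrow(bonds))) {
        bosum[bonds$a1[k]] <- bosum[bonds$a1[k]] + bonds$order[k]
        bosum[bonds$a2[k]] <- bosum[bonds$a2[k]] + bonds$order[k]
      }
    }
    hcount <- vapply(seq_len(n), function(i) {
      .an_implicit_h(elem[i], charge[i], bosum[i])
    }, integer(1))
  }
  structure(
    list(elem = elem, charge = charge, hcount = as.integer(hcount),
         bonds = bonds, name = name),
    class = "an_mol"
  )
}

#' @export
print.an_mol <- function(x, ...) {
  cat(sprintf("<an_mol%s: %d heavy atoms, %d bonds> %s\n",
              if (!is.na(x$name)) paste0(" ", x$name) else "",
              length(x$elem), nrow(x$bonds), mol_to_smiles(x)))
  invisible(x)
}

# Neighbor list (heavy atoms only), as a list of integer vectors.
mol_neighbors <- function(mol) {
  n <- length(mol$elem)
  nb <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$a1[k]]] <- c(nb[[b$a1[k]]], b$a2[k])
    nb[[b$a2[k]]] <- c(nb[[b$a2[k]]], b$a1[k])
  }
  nb
}

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_along(mol$elem))
  )
}

# --- parsing -----------------------------------------------------------------

# Extract per-record formal charges from raw SDF text ("M  CHG" property
# lines override the legacy atom-block charge column).
.an_chg_lines <- function(rec_lines, n_atoms) {
  charge <- integer(n_atoms)
  legacy <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  atom_lines <- rec_lines[5:(4 + n_atoms)]
  code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  code[is.na(code)] <- 0L
  hit <- as.character(code) %in% names(legacy)
  charge[hit] <- legacy[as.character(code[hit])]
  chg <- grep("^M  CHG", rec_lines, value = TRUE)
  if (length(chg)) {
    charge[] <- 0L
    for (ln in chg) {
      f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      k <- f[1]
      for (j in seq_len(k)) charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  charge
}

.an_mol_from_sdf_text <- function(sdf_text, name = NA_character_) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms == 0)
    stop("empty molecule record", call. = FALSE)
  atom_lines <- lines[5:(4 + n_atoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  charge <- .an_chg_lines(lines, n_atoms)
  if (n_bonds > 0) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  # fold explicit hydrogens into implicit counts of their heavy neighbor
  is_h <- elem == "H"
  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- match(seq_along(elem), keep)
    extra_h <- integer(length(keep))
    drop <- logical(nrow(bonds))
    for (k in seq_len(nrow(bonds))) {
      h1 <- is_h[bonds$a1[k]]; h2 <- is_h[bonds$a2[k]]
      if (h1 || h2) {
        heavy <- if (h1) bonds$a2[k] else bonds$a1[k]
        if (!is_h[heavy]) extra_h[remap[heavy]] <- extra_h[remap[heavy]] + 1L
        drop[k] <- TRUE
      }
    }
    bonds <- bonds[!drop, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    m <- an_mol(elem[keep], charge[keep], bonds, name = name)
    m$hcount <- m$hcount + extra_h
    return(m)
  }
  an_mol(elem, charge, bonds, name = name)
}

#' Parse SMILES strings into internal molecule objects
#'
#' Conversion goes through OpenBabel (ChemmineOB), which kekulizes the
#' structure; the result is a heavy-atom graph with formal charges and
#' implicit hydrogen counts.
#'
#' @param smiles character vector of SMILES strings.
#' @param names optional character vector of molecule names.
#' @return a list of molecule objects (class `an_mol`); for a single input
#'   SMILES, the bare molecule object.
#' @examples
#' m <- parse_smiles("c1ccccc1C(N)=O")
#' heavy_atom_count(m)
#' @export
parse_smiles <- function(smiles, names = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  single <- length(smiles) == 1
  if (is.null(names)) names <- rep(NA_character_, length(smiles))
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    s <- trimws(smiles[i])
    if (!nzchar(s)) stop("empty SMILES at position ", i, call. = FALSE)
    sdf <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", source = s)),
      error = function(e) "")
    ok <- nzchar(sdf) && length(grep("V2000", sdf)) > 0
    if (ok) {
      m <- tryCatch(.an_mol_from_sdf_text(sdf, name = names[i]),
                    error = function(e) NULL)
      ok <- !is.null(m)
    }
    if (!ok) {
      stop(sprintf("unparseable SMILES at position %d: '%s'", i, smiles[i]),
           call. = FALSE)
    }
    out[[i]] <- m
  }
  if (single) out[[1]] else out
}

# --- writing -----------------------------------------------------------------

mol_to_molfile <- function(mol) {
  n <- length(mol$elem)
  b <- mol$bonds
  legacy <- function(chg) {
    switch(as.character(chg), `3` = 1L, `2` = 2L, `1` = 3L,
           `-1` = 5L, `-2` = 6L, `-3` = 7L, 0L)
  }
  hdr <- c(if (!is.na(mol$name)) mol$name else "", " amidenet", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  atoms <- vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, mol$elem[i], legacy(mol$charge[i]))
  }, character(1))
  bonds <- if (nrow(b)) vapply(seq_len(nrow(b)), function(k) {
    sprintf("%3d%3d%3d  0  0  0  0", b$a1[k], b$a2[k], b$order[k])
  }, character(1)) else character(0)
  chg <- which(mol$charge != 0)
  mlines <- if (length(chg)) {
    vapply(split(chg, ceiling(seq_along(chg) / 8)), function(idx) {
      paste0(sprintf("M  CHG%3d", length(idx)),
             paste0(sprintf("%4d%4d", idx, mol$charge[idx]), collapse = ""))
    }, character(1))
  } else character(0)
  paste(c(hdr, atoms, bonds, mlines, "M  END", "$$$$"), collapse = "\n")
}

#' Canonical SMILES of a molecule object
#'
#' Canonicalization is delegated to OpenBabel's canonical SMILES writer, so
#' the output is invariant to atom ordering of the input.
#'
#' @param mol a molecule object from [parse_smiles()].
#' @return a single SMILES string.
#' @export
mol_to_smiles <- function(mol) {
  stopifnot(inherits(mol, "an_mol"))
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = mol_to_molfile(mol))
  sub("[\t\n].*$", "", out)
}

#' Canonicalize a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES.
#' @export
canonical_smiles <- function(smiles) mol_to_smiles(parse_smiles(smiles))

# Induced sub-molecule on a set of atom indices (1-based, parent order).
# Returns the sub-molecule plus the mapping parent index -> new index.
mol_subset <- function(mol, atoms, add_h = NULL) {
  atoms <- sort(unique(as.integer(atoms)))
  remap <- match(seq_along(mol$elem), atoms)
  keep <- !is.na(remap[mol$bonds$a1]) & !is.na(remap[mol$bonds$a2])
  b <- mol$bonds[keep, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  hc <- mol$hcount[atoms]
  if (!is.null(add_h)) hc <- hc + add_h
  m <- an_mol(mol$elem[atoms], mol$charge[atoms], b, hcount = hc)
  m$parent_index <- atoms
  m
}

# --- elementary properties ---------------------------------------------------

# IUPAC 2021 standard atomic weights (abridged), used for average-isotope
# molecular weight.
.an_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971,
  Br = 79.904, I = 126.904, Li = 6.94
)

#' Write molecules to an SD file
#'
#' @param x a molecule object, a list of molecule objects, or a character
#'   vector of SMILES.
#' @param path output SDF path.
#' @param names optional molecule names (record titles).
#' @return the path, invisibly.
#' @export
write_sdf <- function(x, path, names = NULL) {
  if (is.character(x)) x <- parse_smiles(x, names = names)
  if (inherits(x, "an_mol")) x <- list(x)
  if (!is.null(names)) {
    for (i in seq_along(x)) x[[i]]$name <- names[i]
  }
  writeLines(vapply(x, mol_to_molfile, character(1)), path)
  invisible(path)
}

#' Heavy atom count (HAC)
#'
#' @param mol a molecule object, or a SMILES string.
#' @return integer number of non-hydrogen atoms.
#' @export
heavy_atom_count <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  length(mol$elem)
}

#' Average-isotope molecular weight
#'
#' Uses standard (average) atomic weights, including implicit hydrogens.
#'
#' @param mol a molecule object, or a SMILES string.
#' @return molecular weight in Dalton.
#' @export
mol_weight <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  w <- .an_weights[mol$elem]
  if (anyNA(w)) stop("no atomic weight for element(s): ",
                     paste(unique(mol$elem[is.na(w)]), collapse = ", "))
  sum(w) + sum(mol$hcount) * .an_weights[["H"]]
}
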