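# Analog enumeration and SAR-matrix layout.
#
# Scaffold slots (a scaffold canonical key plus a designated attachment
# atom) are combined with R-groups (substituents with one marked attachment
# point, written "*" in SMILES) into a full scaffold x substituent product
# set, arranged as a SAR matrix: scaffolds as rows, substituents as
# columns, per-cell score annotations supplied externally (docking scores,
# predicted potencies).

.an_dummy_elems <- c("*", "Du", "R", "R#", "Xx", "X")

#' Define an R-group from a marked SMILES
#'
#' @param id substituent identifier.
#' @param smiles SMILES with exactly one attachment marker atom `*` whose
#'   single neighbor is a heavy atom (e.g. `"*NC(C)=O)"` for acetamido).
#' @return object of class `rgroup_spec`.
#' @export
rgroup_spec <- function(id, smiles) {
  mol <- parse_smiles(smiles)
  dummy <- which(mol$elem %in% .an_dummy_elems)
  if (length(dummy) != 1) {
    stop("R-group '", id, "' must contain exactly one attachment marker *",
         call. = FALSE)
  }
  nb <- mol_neighbors(mol)[[dummy]]
  if (length(nb) != 1 || mol$elem[nb] %in% .an_dummy_elems) {
    stop("attachment marker of R-group '", id,
         "' must bond a single heavy atom", call. = FALSE)
  }
  structure(list(id = id, smiles = smiles, mol = mol, dummy = dummy,
                 attach = nb), class = "rgroup_spec")
}

#' Define a scaffold slot
#'
#' @param scaffold_id identifier for the scaffold row.
#' @param scaffold_key canonical scaffold SMILES.
#' @param position attachment atom index in the canonical form (as reported
#'   in `attachment_positions` by [make_scaffold()]).
#' @return object of class `scaffold_slot`.
#' @export
scaffold_slot <- function(scaffold_id, scaffold_key, position) {
  mol <- parse_smiles(scaffold_key)
  position <- as.integer(position)
  if (position < 1 || position > length(mol$elem)) {
    stop("slot position out of range for scaffold '", scaffold_id, "'",
         call. = FALSE)
  }
  structure(list(id = scaffold_id, scaffold_key = scaffold_key, mol = mol,
                 position = position), class = "scaffold_slot")
}

# Attach an R-group to a slot; returns the product molecule or NULL when
# the slot atom has no hydrogen to give up (valence violation).
.an_attach <- function(slot, rg) {
  smol <- slot$mol
  if (smol$hcount[slot$position] < 1) return(NULL)
  rmol <- rg$mol
  keep <- setdiff(seq_along(rmol$elem), rg$dummy)
  remap <- match(seq_along(rmol$elem), keep) + length(smol$elem)
  rb <- rmol$bonds
  rb <- rb[rb$a1 != rg$dummy & rb$a2 != rg$dummy, , drop = FALSE]
  rb$a1 <- remap[rb$a1]; rb$a2 <- remap[rb$a2]
  elem <- c(smol$elem, rmol$elem[keep])
  charge <- c(smol$charge, rmol$charge[keep])
  hcount <- c(smol$hcount, rmol$hcount[keep])
  hcount[slot$position] <- hcount[slot$position] - 1L
  bonds <- rbind(smol$bonds, rb,
                 data.frame(a1 = slot$position, a2 = remap[rg$attach],
                            order = 1L))
  an_mol(elem, charge, bonds, hcount = hcount)
}

#' Enumerate scaffold x substituent analogs
#'
#' Forms every product of a scaffold slot and an R-group by bonding the
#' slot atom to the R-group's attachment neighbor. Products are
#' canonicalized; combinations that would violate the slot atom's valence
#' are skipped and counted in the `skip_log` attribute.
#'
#' @param slots list of [scaffold_slot()] objects.
#' @param rgroups list of [rgroup_spec()] objects.
#' @return data.frame with one row per valid product: `scaffold_id`,
#'   `rgroup_id`, `smiles`, `hac`, `mw`, `clogp`.
#' @export
enumerate_analogs <- function(slots, rgroups) {
  if (inherits(slots, "scaffold_slot")) slots <- list(slots)
  if (inherits(rgroups, "rgroup_spec")) rgroups <- list(rgroups)
  rows <- list()
  skips <- list()
  for (sl in slots) {
    for (rg in rgroups) {
      prod <- .an_attach(sl, rg)
      if (is.null(prod)) {
        skips[[length(skips) + 1]] <- data.frame(
          scaffold_id = sl$id, rgroup_id = rg$id, reason = "valence")
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        scaffold_id = sl$id, rgroup_id = rg$id,
        smiles = mol_to_smiles(prod),
        hac = heavy_atom_count(prod),
        mw = mol_weight(prod),
        clogp = crippen_logp(prod),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    scaffold_id = character(), rgroup_id = character(), smiles = character(),
    hac = integer(), mw = numeric(), clogp = numeric())
  attr(out, "skip_log") <- if (length(skips)) do.call(rbind, skips) else
    data.frame(scaffold_id = character(), rgroup_id = character(),
               reason = character())
  out
}

#' Arrange analogs and scores as a SAR matrix
#'
#' @param products result of [enumerate_analogs()].
#' @param scores optional data.frame `scaffold_id`, `rgroup_id`,
#'   `target_id`, `score`; every scored product must exist.
#' @return a character matrix with scaffolds as rows and substituents as
#'   columns; each cell holds the per-target scores as `"t1=s1; t2=s2"`, or
#'   `"."` when no score is available. Cell content is independent of
#'   product/score row order.
#' @export
sar_matrix <- function(products, scores = NULL) {
  scaffs <- sort(unique(products$scaffold_id))
  rgs <- sort(unique(products$rgroup_id))
  m <- matrix(".", nrow = length(scaffs), ncol = length(rgs),
              dimnames = list(scaffold = scaffs, substituent = rgs))
  if (!is.null(scores) && nrow(scores)) {
    pk <- paste(products$scaffold_id, products$rgroup_id)
    bad <- !(paste(scores$scaffold_id, scores$rgroup_id) %in% pk)
    if (any(bad)) {
      stop("scores refer to unknown product(s): ",
           paste(unique(paste(scores$scaffold_id[bad],
                              scores$rgroup_id[bad])), collapse = "; "),
           call. = FALSE)
    }
    scores <- scores[order(scores$target_id), , drop = FALSE]
    cells <- split(sprintf("%s=%g", scores$target_id, scores$score),
                   paste(scores$scaffold_id, scores$rgroup_id, sep = "\r"))
    for (key in names(cells)) {
      parts <- strsplit(key, "\r")[[1]]
      m[parts[1], parts[2]] <- paste(cells[[key]], collapse = "; ")
    }
  }
  m
}
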