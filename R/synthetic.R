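# Synthetic bioactivity data with planted scaffold structure.
#
# The generator emulates a two-target curated bioactivity extract at desk
# scale: compounds are built by decorating known amide scaffolds (shared
# between both targets or exclusive to one) with small acyclic substituents
# at random open ring-carbon positions, potencies are drawn from a
# truncated-normal active / uniform inactive mixture straddling the 10 uM
# cutoff, and a configurable fraction of extra measurement rows carries
# approximate relation symbols to exercise the curation filters. A manifest
# records the ground truth (scaffold membership, substitution positions,
# true pPOT) for every compound, so pipeline recovery can be checked
# exactly.

.an_syn_shared <- c(
  phenanthridinone = "O=c1[nH]c2ccccc2c2ccccc12",
  phthalazinone = "O=c1[nH]ncc2ccccc12",
  pyrrolopyridinone = "O=c1[nH]ccc2c1[nH]cc2"
)
.an_syn_excl_a <- c(
  benzimidazole_carboxamide = "NC(=O)c1cccc2[nH]cnc12",
  indazole_carboxamide = "NC(=O)c1cccc2c[nH]nc12",
  quinazolinone = "O=c1[nH]cnc2ccccc12"
)
.an_syn_excl_b <- c(
  isoquinolinone = "O=c1[nH]ccc2ccccc12",
  quinolinone = "O=c1ccc2ccccc2[nH]1",
  dihydroquinazolinone = "O=C1NCc2ccccc2N1"
)
.an_syn_substituents <- c("C", "CC", "OC", "F", "Cl", "N(C)C",
                          "C(F)(F)F", "S(C)(=O)=O")

#' Specify a synthetic bioactivity dataset
#'
#' Defaults describe the benchmark condition used throughout the package:
#' two targets with 100 compounds each, three planted shared scaffolds and
#' three exclusive scaffolds per target, active pPOT ~ Normal(6.5, 1)
#' truncated at 5, an inactive fraction of 0.2 with pPOT ~ Uniform(3.5, 5),
#' and a 0.1 fraction of extra approximate-relation measurement rows.
#'
#' @param n_targets number of targets (currently 2).
#' @param n_compounds compounds per target.
#' @param shared_scaffolds named character vector of scaffold SMILES
#'   planted under both targets.
#' @param exclusive_scaffolds list of per-target named character vectors of
#'   scaffold SMILES planted under one target only.
#' @param substituents pool of acyclic substituent SMILES used to decorate
#'   scaffolds (attached via a new single bond).
#' @param ppot_mean,ppot_sd active potency distribution (truncated at
#'   `threshold`).
#' @param frac_inactive fraction of compounds drawn below the threshold.
#' @param frac_approx fraction of compounds receiving an extra approximate
#'   (">" or "~") measurement row.
#' @param threshold activity cutoff in pPOT units.
#' @param target_ids character vector of target identifiers.
#' @param seed integer random seed; a fixed seed gives identical output.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_dataset_spec <- function(
    n_targets = 2L, n_compounds = 100L,
    shared_scaffolds = .an_syn_shared,
    exclusive_scaffolds = list(.an_syn_excl_a, .an_syn_excl_b),
    substituents = .an_syn_substituents,
    ppot_mean = 6.5, ppot_sd = 1.0,
    frac_inactive = 0.2, frac_approx = 0.1,
    threshold = 5.0,
    target_ids = c("CHEMBL3105", "CHEMBL1163125"),
    seed = 20221001L) {
  if (n_targets != 2L) stop("the generator models a target pair", call. = FALSE)
  if (length(target_ids) != n_targets) {
    stop("need one target id per target", call. = FALSE)
  }
  if (length(exclusive_scaffolds) != n_targets) {
    stop("need one exclusive scaffold set per target", call. = FALSE)
  }
  n_scaff <- length(shared_scaffolds) +
    min(lengths(exclusive_scaffolds))
  if (n_scaff > n_compounds) {
    stop("more planted scaffolds than compounds per target", call. = FALSE)
  }
  structure(list(
    n_targets = n_targets, n_compounds = n_compounds,
    shared_scaffolds = shared_scaffolds,
    exclusive_scaffolds = exclusive_scaffolds,
    substituents = substituents,
    ppot_mean = ppot_mean, ppot_sd = ppot_sd,
    frac_inactive = frac_inactive, frac_approx = frac_approx,
    threshold = threshold, target_ids = target_ids, seed = seed
  ), class = "synthetic_spec")
}

# Ring-carbon positions with a free hydrogen, excluding the carbonyl
# carbon; substitution there keeps the scaffold's amide class and identity.
.an_open_positions <- function(mol) {
  rb <- ring_bond_flags(mol)
  ring_atoms <- unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb]))
  has_exo_o <- vapply(ring_atoms, function(i) {
    any((mol$bonds$a1 == i | mol$bonds$a2 == i) & mol$bonds$order == 2 &
          mol$elem[ifelse(mol$bonds$a1 == i, mol$bonds$a2,
                          mol$bonds$a1)] == "O")
  }, logical(1))
  ring_atoms[mol$elem[ring_atoms] == "C" & mol$hcount[ring_atoms] >= 1 &
               !has_exo_o]
}

.an_decorate <- function(scaffold_mol, substituent_smiles, positions) {
  mol <- scaffold_mol
  for (k in seq_along(positions)) {
    rg <- rgroup_spec("s", paste0("*", substituent_smiles[k]))
    slot <- structure(list(id = "x", mol = mol, position = positions[k]),
                      class = "scaffold_slot")
    mol <- .an_attach(slot, rg)
    if (is.null(mol)) stop("decoration valence failure", call. = FALSE)
  }
  mol
}

#' Generate a synthetic bioactivity dataset
#'
#' @param spec a [synthetic_dataset_spec()].
#' @return list with `bioactivity` (canonical-schema measurement table),
#'   `pdb_evidence` (compound/target/pdb-code table), and `manifest`
#'   (per-compound ground truth: planted scaffold key, substitution
#'   positions on the scaffold's canonical form, true pPOT, active flag).
#'   Output is byte-identical for a fixed seed.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  scaffold_pool <- lapply(seq_len(spec$n_targets), function(t) {
    c(spec$shared_scaffolds, spec$exclusive_scaffolds[[t]])
  })
  # canonical scaffold keys and open positions, computed once
  all_smiles <- unique(unlist(scaffold_pool))
  info <- lapply(all_smiles, function(s) {
    mol <- parse_smiles(s)
    key <- mol_to_smiles(mol)
    cmap <- .an_canonical_map(mol, parse_smiles(key))
    list(mol = mol, key = key, open = .an_open_positions(mol), cmap = cmap)
  })
  names(info) <- all_smiles

  bio <- list(); man <- list(); pdb <- list()
  seen_structures <- character(0)
  cpd_counter <- 0L
  for (t in seq_len(spec$n_targets)) {
    tid <- spec$target_ids[t]
    pool <- scaffold_pool[[t]]
    assign_scaffold <- rep(seq_along(pool), length.out = spec$n_compounds)
    for (i in seq_len(spec$n_compounds)) {
      cpd_counter <- cpd_counter + 1L
      cid <- sprintf("SYN-%05d", cpd_counter)
      s_smiles <- pool[assign_scaffold[i]]
      inf <- info[[s_smiles]]
      # draw decorations until the structure is unique in the dataset, so
      # the manifest stays in one-to-one correspondence with curated ids
      for (try in 1:50) {
        k <- min(sample(1:3, 1), length(inf$open))
        pos <- inf$open[sample.int(length(inf$open), k)]
        subs <- sample(spec$substituents, k, replace = TRUE)
        mol <- .an_decorate(inf$mol, subs, pos)
        smi <- mol_to_smiles(mol)
        if (!smi %in% seen_structures) break
      }
      seen_structures <- c(seen_structures, smi)
      active <- runif(1) >= spec$frac_inactive
      ppot <- if (active) {
        repeat {
          p <- rnorm(1, spec$ppot_mean, spec$ppot_sd)
          if (p >= spec$threshold) break
        }
        p
      } else {
        runif(1, 3.5, spec$threshold - 1e-6)
      }
      value_nm <- 10^(9 - ppot)
      in_um <- runif(1) < 0.5
      bio[[length(bio) + 1]] <- data.frame(
        compound_id = cid, smiles = smi, target_id = tid,
        type = sample(c("IC50", "Ki", "Kd", "EC50"), 1),
        relation = "=",
        value = if (in_um) value_nm / 1000 else value_nm,
        units = if (in_um) "uM" else "nM",
        stringsAsFactors = FALSE)
      if (runif(1) < spec$frac_approx) {
        # extra approximate row; dropped by the relation filter
        bio[[length(bio) + 1]] <- data.frame(
          compound_id = cid, smiles = smi, target_id = tid,
          type = "IC50", relation = sample(c(">", "~"), 1),
          value = 10, units = "uM", stringsAsFactors = FALSE)
      }
      man[[length(man) + 1]] <- data.frame(
        compound_id = cid, target_id = tid,
        scaffold_key = inf$key,
        scaffold_role = if (s_smiles %in% spec$shared_scaffolds) "shared"
                        else "exclusive",
        positions = paste(sort(inf$cmap[pos]), collapse = ","),
        ppot_true = ppot, active = active,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, man)
  # structural evidence for a few active shared-scaffold compounds
  for (t in seq_len(spec$n_targets)) {
    tid <- spec$target_ids[t]
    cands <- manifest$compound_id[
      manifest$target_id == tid & manifest$active &
        manifest$scaffold_role == "shared"]
    take <- head(cands, 3)
    for (j in seq_along(take)) {
      pdb[[length(pdb) + 1]] <- data.frame(
        compound_id = take[j], target_id = tid,
        pdb_code = sprintf("9S%d%d", t, j), stringsAsFactors = FALSE)
    }
  }
  list(bioactivity = do.call(rbind, bio),
       pdb_evidence = do.call(rbind, pdb),
       manifest = manifest)
}

#' Write a generated dataset to disk
#'
#' Writes the measurement table and evidence table in the curation module's
#' CSV dialect plus a JSON manifest.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("bioactivity.csv", "pdb_evidence.csv",
                            "manifest.json"))
  write.csv(dataset$bioactivity, paths[1], row.names = FALSE)
  write.csv(dataset$pdb_evidence, paths[2], row.names = FALSE)
  jsonlite::write_json(dataset$manifest, paths[3], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
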