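# Physicochemical property panel: MW, HAC, Wildman-Crippen cLogP, and the
# ligand efficiency index LEI = pPOT / HAC.

# Half-up rounding for reported values (R's round() is banker's rounding).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Ligand efficiency index
#'
#' LEI = pPOT / HAC: the negative log molar potency normalized by heavy
#' atom count. Reported values are conventionally rounded half-up to two
#' decimals.
#'
#' @param ppot numeric pPOT (e.g. pIC50) value(s).
#' @param hac heavy atom count.
#' @param digits decimals for reporting; `NULL` returns full precision.
#' @return numeric LEI.
#' @examples
#' ligand_efficiency(to_ppot(1210, "nM"), 25)   # 0.24
#' @export
ligand_efficiency <- function(ppot, hac, digits = 2) {
  stopifnot(hac >= 1)
  lei <- ppot / hac
  if (is.null(digits)) lei else round_half_up(lei, digits)
}

#' Compute the property bundle of a molecule
#'
#' @param mol molecule object or SMILES string.
#' @param ppot optional named numeric vector of pPOT annotations keyed by
#'   target id; a ligand efficiency index is reported for each.
#' @return object of class `property_bundle`: a list with `mw` (Dalton,
#'   average isotopes), `hac`, `clogp` (Wildman-Crippen), and `lei` (named
#'   vector, full precision) with `lei_report` (half-up, 2 decimals).
#' @examples
#' compute_properties("c1ccccc1C(N)=O", ppot = c(PARP1 = 6.0))
#' @export
compute_properties <- function(mol, ppot = NULL) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  hac <- heavy_atom_count(mol)
  out <- list(mw = mol_weight(mol), hac = hac, clogp = crippen_logp(mol))
  if (!is.null(ppot) && length(ppot)) {
    out$lei <- ppot / hac
    out$lei_report <- round_half_up(out$lei, 2)
  } else {
    out$lei <- numeric(0)
    out$lei_report <- numeric(0)
  }
  structure(out, class = "property_bundle")
}

#' @export
print.property_bundle <- function(x, ...) {
  cat(sprintf("MW = %.1f Da, HAC = %d, cLogP = %.2f\n",
              x$mw, x$hac, x$clogp))
  if (length(x$lei)) {
    for (t in names(x$lei)) {
      cat(sprintf("LEI(%s) = %.2f\n", t, x$lei_report[[t]]))
    }
  }
  invisible(x)
}
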