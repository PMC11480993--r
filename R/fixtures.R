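# Reference compounds.
#
# Named PARP1/BRD4 inhibitors and designed analogs, transcribed from their
# published depictions. Transcriptions are cross-checked in the test suite
# against printed reference values (heavy atom count, molecular weight,
# cLogP), and every fixture must round-trip structure standardization with
# an unchanged heavy-atom count.

.an_fixtures <- list(
  list(name = "olaparib",
       smiles = "O=C1NN=C(Cc2ccc(F)c(C(=O)N3CCN(C(=O)C4CC4)CC3)c2)c2ccccc12",
       provenance = "FDA-approved PARP1 inhibitor; phthalazinone lactam scaffold"),
  list(name = "rucaparib",
       smiles = "CNCc1ccc(-c2[nH]c3cc(F)cc4c3c2CCNC4=O)cc1",
       provenance = "FDA-approved PARP1 inhibitor; azepinoindolone tricyclic lactam"),
  list(name = "talazoparib",
       smiles = "O=C1NN=C2C(c3ncnn3C)C(c3ccc(F)cc3)Nc3cc(F)cc1c23",
       provenance = "FDA-approved PARP1 inhibitor; tricyclic lactam (stereo dropped, scaffold identity is 2-D)"),
  list(name = "niraparib",
       smiles = "NC(=O)c1cccc2cn(-c3ccc(C4CCCNC4)cc3)nc12",
       provenance = "FDA-approved PARP1 inhibitor; indazole carboxamide (primary amide on ring)"),
  list(name = "PJ34",
       smiles = "O=C1Nc2ccc(NC(=O)CN(C)C)cc2-c2ccccc21",
       provenance = "nonselective PARP1 tool compound; phenanthridinone lactam"),
  list(name = "JQ-1",
       smiles = "Cc1sc2c(c1C)C(=N[C@@H](CC(=O)OC(C)(C)C)c1nnc(C)n1-2)c1ccc(Cl)cc1",
       provenance = "BET bromodomain tool compound (thienotriazolodiazepine)"),
  list(name = "mivebresib",
       smiles = "CCS(=O)(=O)Nc1ccc(Oc2ccc(F)cc2F)c(-c2cn(C)c(=O)c3[nH]ccc23)c1",
       provenance = "BRD4 inhibitor; pyrrolo[2,3-c]pyridin-7-one scaffold, tertiary amide"),
  list(name = "RVX-208",
       smiles = "Cc1cc(-c2nc3cc(OC)cc(OC)c3c(=O)[nH]2)cc(C)c1OCCO",
       provenance = "BET BD2-selective inhibitor (apabetalone); quinazolinone lactam"),
  list(name = "BI 2536",
       smiles = "CC[C@H]1N(C2CCCC2)c2nc(Nc3ccc(C(=O)NC4CCN(C)CC4)cc3OC)ncc2N(C)C1=O",
       provenance = "PLK1/BRD4 inhibitor; pteridinone with tertiary amide"),
  list(name = "PFI-1",
       smiles = "COc1ccccc1S(=O)(=O)Nc1ccc2c(c1)CNC(=O)N2",
       provenance = "BET chemical probe; dihydroquinazolinone sulfonamide"),
  list(name = "HF1",
       smiles = "O=C1Nc2ccc(NS(=O)(=O)c3ccc(F)c(C)c3)cc2C2=C1CCCC2",
       provenance = "designed dual inhibitor: 1,2,3,4-tetrahydrophenanthridin-6(5H)-one + 4-fluoro-3-methylbenzenesulfonamide (synthesis route)"),
  list(name = "HF2",
       smiles = "O=C1Nc2ccc(NS(=O)(=O)c3ccc(F)c(C)c3)cc2-c2ccccc21",
       provenance = "designed dual inhibitor: phenanthridin-6(5H)-one + 4-fluoro-3-methylbenzenesulfonamide (synthesis route)"),
  list(name = "HF3",
       smiles = "O=C1Nc2ccc(NC(=O)CN(C)C)cc2C2=C1CCCC2",
       provenance = "designed dual inhibitor: HF1 scaffold + dimethylglycinamide (synthesis route)"),
  list(name = "HF4",
       smiles = "CCC1=Cc2cc(NS(=O)(=O)c3ccc(F)c(C)c3)ccc2NC1=O",
       provenance = "designed dual inhibitor: 3-ethylquinolin-2(1H)-one + 4-fluoro-3-methylbenzenesulfonamide; printed HAC 25, MW 360.4 Da"),
  list(name = "HF5",
       smiles = "CCC1=Cc2cc(NC(=O)CN(C)C)ccc2NC1=O",
       provenance = "designed dual inhibitor: 3-ethylquinolin-2(1H)-one + dimethylglycinamide (synthesis route)"),
  list(name = "CHEMBL372303",
       smiles = "O=C1Nc2ccc(NC(=O)CN(C)C)cc2-c2ccccc21",
       provenance = "PARP1 inhibitor carrying the shared phenanthridinone scaffold (PDB 4UXB ligand; same structure as PJ34)"),
  list(name = "CHEMBL4469223",
       smiles = "O=C1Nc2ccc(NS(=O)(=O)c3ccc(F)c(C)c3)cc2-c2ccccc21",
       provenance = "BRD4 inhibitor carrying the shared phenanthridinone scaffold; synthetic stand-in transcribed from the depicted sulfonamide substituent")
)

#' Reference inhibitors and designed analogs
#'
#' Returns the package's named compound set: FDA-approved and tool PARP1
#' and BRD4 inhibitors, the designed HF1-HF5 series, and the two parent
#' compounds of the shared phenanthridinone scaffold. Each entry carries a
#' provenance note; structures are 2-D transcriptions (stereochemistry does
#' not enter scaffold identity).
#'
#' @return data.frame with columns `name`, `smiles`, `provenance`.
#' @examples
#' cpds <- inpaper_compounds()
#' subset(cpds, name == "HF4")$smiles
#' @export
inpaper_compounds <- function() {
  do.call(rbind, lapply(.an_fixtures, function(x) {
    data.frame(name = x$name, smiles = x$smiles, provenance = x$provenance,
               stringsAsFactors = FALSE)
  }))
}

#' Fixture SMILES by name
#'
#' @param name compound name as listed by [inpaper_compounds()].
#' @return SMILES string.
#' @export
fixture_smiles <- function(name) {
  cpds <- inpaper_compounds()
  i <- match(name, cpds$name)
  if (is.na(i)) stop("unknown fixture compound: ", name, call. = FALSE)
  cpds$smiles[i]
}

# Amino-substituted parents used to derive the designated attachment
# position of each design scaffold: fragmenting the parent cuts off the
# exocyclic amine and reports the growth-vector position on the canonical
# scaffold. The four tricyclic/bicyclic lactams are the design scaffold
# set; attachment sites are para to the lactam nitrogen's ring carbon, as
# in the depicted parent series.
.an_design_scaffolds <- list(
  list(id = "phenanthridinone",      parent = "Nc1ccc2[nH]c(=O)c3ccccc3c2c1"),
  list(id = "tetrahydrophenanthridinone",
       parent = "O=C1Nc2ccc(N)cc2C2=C1CCCC2"),
  list(id = "quinolinone",           parent = "Nc1ccc2[nH]c(=O)ccc2c1"),
  list(id = "cyclopentaquinolinone", parent = "O=C1Nc2ccc(N)cc2C2=C1CCC2")
)

#' Design scaffold slots
#'
#' The four lactam scaffolds used for analog design, each with its
#' designated growth-vector position derived by fragmenting an
#' amino-substituted parent (the attachment site is recovered from the
#' cleavage annotation, not hand-indexed).
#'
#' @return list of [scaffold_slot()] objects.
#' @export
fixture_scaffold_slots <- function() {
  lapply(.an_design_scaffolds, function(d) {
    frags <- fragment_compound(d$parent)
    for (fr in frags) {
      sc <- make_scaffold(fr)
      if (!is.null(sc)) {
        return(scaffold_slot(d$id, sc$canonical_key,
                             sc$attachment_positions[1]))
      }
    }
    stop("design scaffold parent yielded no amide scaffold: ", d$id)
  })
}

#' Design substituent set
#'
#' The three substituents of the analog matrix: the depicted
#' arylsulfonamide, the dimethylglycinamide of the phenanthridinone tool
#' series, and a methoxy-substituted arylsulfonamide analog.
#'
#' @return list of [rgroup_spec()] objects.
#' @export
fixture_rgroups <- function() {
  list(
    rgroup_spec("fluoromethylbenzenesulfonamido",
                "*NS(=O)(=O)c1ccc(F)c(C)c1"),
    rgroup_spec("dimethylglycinamido", "*NC(=O)CN(C)C"),
    rgroup_spec("methoxybenzenesulfonamido", "*NS(=O)(=O)c1ccccc1OC")
  )
}
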