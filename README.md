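# amidenet

Amide scaffold networks for dual-target inhibitor design.

`amidenet` is an R package for medicinal chemists and cheminformaticians who
want to find **shared pharmacophores** between two protein targets from
public bioactivity data and use them to seed **merged dual-target inhibitor
design**. The motivating application is the PARP1/BRD4 target pair, where
bicyclic and tricyclic ring systems carrying an amide — a primary amide
hanging off the ring, or a lactam — are the recurring recognition element.

The pipeline:

1. **Curation.** Potency measurements (Ki, Kd, IC50, EC50) are standardized
   (salt stripping, charge neutralization, lactim→lactam), filtered by
   relation symbol (only `=` and `<` are kept), converted to
   pPOT = −log10(molar potency), aggregated per compound–target pair by the
   maximum, and thresholded at pPOT ≥ 5 (10 µM).
2. **Fragmentation.** Every acyclic single bond is cleaved simultaneously,
   *except* the bonds tying a primary amide to its ring system. Fragments
   that are bicyclic or tricyclic amides (lactam or primary-amide-on-ring)
   become scaffolds with a canonical key and recorded attachment positions
   (growth vectors).
3. **Network.** Scaffolds are tallied per target (minimum support: five
   active compounds), organized as a bipartite scaffold–target network with
   crystallographic-evidence edge flags, and scaffolds adjacent to both
   targets are ranked as shared-pharmacophore candidates.
4. **Design.** Scaffold × substituent analogs are enumerated in a
   SAR-matrix layout and scored with a property panel: molecular weight,
   heavy atom count (HAC), Wildman–Crippen cLogP (implemented from the
   published atomic-contribution table), and the ligand efficiency index
   LEI = pPOT / HAC.

A seeded synthetic-data generator plants known scaffolds into emulated
bioactivity tables so the whole pipeline is testable offline, with exact
ground truth.

## Worked example

Properties of the designed dual PARP1/BRD4 inhibitor HF4
(N-(3-ethyl-2-oxo-1,2-dihydroquinolin-6-yl)-4-fluoro-3-methylbenzene-
sulfonamide), with its measured potencies (IC50 1210 nM on BRD4, ~2.0 µM
on PARP1):

```r
library(amidenet)
hf4 <- fixture_smiles("HF4")
compute_properties(hf4, ppot = c(BRD4  = to_ppot(1210, "nM"),
                                 PARP1 = to_ppot(2.0, "uM")))
#> MW = 360.4 Da, HAC = 25, cLogP = 3.34
#> LEI(BRD4) = 0.24
#> LEI(PARP1) = 0.23
```

A LEI near 0.24 on both targets at 25 heavy atoms marks HF4 as a compact,
balanced dual binder.

End-to-end on synthetic data with planted scaffolds:

```r
spec <- synthetic_dataset_spec()       # 2 targets x 100 compounds, seeded
ds   <- generate_dataset(spec)
res  <- run_pipeline(run_config(out = "run1"),
                     bioactivity = ds$bioactivity,
                     pdb_evidence = ds$pdb_evidence)
res$shared_scaffolds
#> [1] "O=c1[nH]c2ccccc2c2c1cccc2" "O=c1[nH]ncc2c1cccc2"
#> [3] "O=c1[nH]ccc2c1[nH]cc2"
```

The three recovered keys are exactly the three planted shared scaffolds
(phenanthridinone, phthalazinone, pyrrolopyridinone); per-target coverage
is 1.0 and the compound-to-core ratio ≈ 13 under the default generator
conditions. `run1/` holds the annotations, scaffold tables, GraphML
network, shared-scaffold ranking, drop log and a JSON summary.

Scaffold assignment of a marketed inhibitor:

```r
scs <- Filter(Negate(is.null),
              lapply(fragment_compound(fixture_smiles("olaparib")),
                     make_scaffold))
scs[[1]]$canonical_key    # "O=c1[nH]ncc2c1cccc2"  (phthalazin-1(2H)-one)
```

A command-line front end with `simulate`, `curate`, `fragment`, `run`,
`design` and `props` subcommands is installed at
`system.file("cli", "amidenet.R", package = "amidenet")`.

## Documentation

The methods vignette (`vignettes/merged-pharmacophore-design.Rmd`) explains
the models and rules in detail: the fragmentation exception, the scaffold
filters, the aromaticity model behind the cLogP implementation, canonical
attachment positions, the synthetic generator's assumptions, and known
limitations.
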