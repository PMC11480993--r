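---
title: "Merged-pharmacophore design from amide scaffold networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merged-pharmacophore design from amide scaffold networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(amidenet)
```

## The problem

Polypharmacology programs — here, joint inhibition of the DNA-repair
enzyme PARP1 and the epigenetic reader BRD4 in breast cancer — can follow
two routes: *linking* two target-specific fragments into one large
molecule, or *merging* on a single substructure that both binding sites
accept. Merging yields smaller, more ligand-efficient compounds, but
requires finding a substructure that is genuinely shared by the active
chemistry of both targets. `amidenet` operationalizes that search: it
mines target-annotated bioactivity tables for ring systems that recur
among actives of both targets, then enumerates analogs around them.

For PARP1, the recognition element is well understood: a benzamide-like
amide (primary amide on a ring, or a lactam) that hydrogen-bonds to the
catalytic-site backbone. The pipeline therefore keys its scaffold
definition on amides.

## Curation model

One potency annotation per compound–target pair is derived as follows,
with every dropped record logged with a reason code:

* **Measure types.** Ki, Kd, IC50 and EC50 are accepted and pooled; they
  are not comparable assay-theoretically, but for scaffold counting only
  an order-of-magnitude activity call is needed.
* **Relations.** `=` and `<` are kept; `>` and `~` are dropped. A `<`
  value is used as stated (the compound is at least that potent, and the
  downstream threshold errs permissive).
* **pPOT.** Values are converted to −log10(molar). The unit table is fixed
  to M/mM/µM/nM/pM; the conversion uses integer decimal exponents so that
  10 µM gives pPOT = 5 *exactly*, making the inclusive threshold
  `ppot >= 5` numerically safe at its boundary.
* **Aggregation.** Multiple surviving measurements aggregate by the
  maximum (the most optimistic annotation), matching the permissive intent
  of the activity call.
* **Standardization.** Structures pass a deterministic cascade: largest
  covalent component by heavy-atom count (ties by molecular weight),
  neutralization of protonation-state charges (charge-separated groups
  like nitro are left alone), and a targeted tautomer rule that rewrites
  explicit ring lactim forms C(–OH)=N to the lactam C(=O)–NH, so
  lactam/lactim pairs share one scaffold key. Full tautomer enumeration is
  *not* attempted; the cascade is idempotent, which the tests assert on
  every fixture. Compounds from different sources that standardize to the
  same structure are pooled under one representative id (an id map is
  attached for re-keying external tables, e.g. crystallographic evidence).

## Fragmentation and scaffold definition

All acyclic single bonds are cleaved **simultaneously**, with one
exception: for a primary amide C(=O)NH2 whose carbonyl carbon sits
directly on a ring atom, the carbonyl-to-ring bond (and the amide's
internal bonds) are preserved. Secondary and tertiary amides are never
preserved as appendages — they only survive inside rings, as lactams.
"Acyclic single bond" includes biaryl links, so ring systems separate
from each other; fused and spiro rings stay together. Cleaved valences
are capped with hydrogens.

A fragment becomes a scaffold when (a) it contains an amide — a lactam
(C and N of the amide both ring atoms) or a preserved ring-attached
primary amide — and (b) its ring count is 2 or 3. The ring count is the
cyclomatic number of the fragment, which equals the size of a smallest
set of smallest rings; monocycles are too generic and tetra+ systems too
"bulky" to transfer between targets. If a fragment contains both amide
motifs it is reported as a lactam. Scaffold identity is 2-D: stereo
descriptors play no role, and the canonical key is the canonical SMILES
of the hydrogen-capped fragment, so the same chemotype from different
parents collapses to one key.

```{r}
scs <- Filter(Negate(is.null),
              lapply(fragment_compound(fixture_smiles("olaparib")),
                     make_scaffold))
scs[[1]][c("canonical_key", "amide_class", "ring_count")]
```

**Attachment positions (growth vectors).** Each scaffold records where
substituents were cleaved, in the atom numbering of its canonical form.
The mapping from a fragment onto its re-parsed canonical SMILES is a
vertex-colored VF2 isomorphism (colors: element, charge, hydrogen count;
edge colors: bond order, with bonds inside aromatic rings normalized so
that different kekulé assignments compare equal); among all isomorphisms
the lexicographically smallest is chosen, so positions are reproducible
across runs and parents. For scaffolds with non-trivial symmetry,
symmetric sites are interchangeable under this convention — they are
chemically equivalent, so growth-vector comparisons are unaffected.

## Network analysis

Per target, each scaffold's support is the *set* of active compounds
containing it (a scaffold occurring twice in one parent counts once). The
support filter keeps scaffolds with at least `min_support = 5` compounds
(inclusive), the point at which a scaffold carries interpretable SAR. The
bipartite scaffold–target network connects a scaffold to a target iff it
was retained for that target; edges carry the support count and a logical
crystallographic-evidence flag (true when at least one supporting
compound appears in the structural-evidence table for that target).

Shared scaffolds — adjacent to both targets of the queried pair — are
ranked by evidence first, then by the smaller per-target support, then
lexicographically. The rank formalizes the qualitative prioritization of
the design workflow (structure-enabled scaffolds first); the
substitution-site comparison is deliberately *not* folded into the rank
but exposed separately as `growth_vector_overlap()`, because vector
compatibility is a hard design constraint, not a soft preference. The
final step of the original workflow — visual comparison of 3-D binding
poses — is inherently manual and out of scope here.

## Property panel

* **MW** uses standard average atomic weights.
* **HAC** is the heavy-atom count.
* **cLogP** is the Wildman–Crippen atomic-contribution method,
  implemented in the package: every atom (including implicit hydrogens)
  receives one of the published atom types via an ordered rule list, and
  cLogP is the sum of the type contributions — by construction it equals
  the sum of the per-atom table that `crippen_contributions()` returns.
  The aromaticity model matches the toolkit convention under which
  2-pyridone-type lactam rings are aromatic (in-ring double bond: one
  electron per atom; carbonyl-type exocyclic double bond: zero; ring
  heteroatom lone pair: two; Hückel 4n+2 on smallest rings of size 5–7).
  This choice was validated against an independent implementation of the
  same published method across the whole fixture set in the test suite.
* **LEI** = pPOT / HAC, with reported values rounded *half-up* to two
  decimals (base R's `round()` is banker's rounding, which would turn
  0.225 into 0.22).

```{r}
compute_properties(fixture_smiles("HF4"),
                   ppot = c(BRD4 = to_ppot(1210, "nM"),
                            PARP1 = to_ppot(2.0, "uM")))
```

## Analog enumeration

A scaffold slot (canonical key + designated attachment atom) and an
R-group (SMILES with one `*` marker) combine by a single bond from the
slot atom to the marker's neighbor; the slot atom must have a hydrogen to
give up, otherwise the combination is skipped and logged. The design
fixture set — four lactam scaffolds by three substituents, giving twelve
analogs — encodes the depicted design matrix; since the alternative
scaffolds and substituents are shown only graphically in the source
figures, the fixture set is a transcription choice, and each slot's
attachment position is *derived* by fragmenting an amino-substituted
parent rather than hand-indexed. Products are arranged as a SAR matrix
(scaffolds × substituents) whose cells accept externally supplied
per-target scores (e.g. docking scores); scoring itself is out of scope,
but products export to SDF for external docking programs.

## Synthetic data: what it does and does not emulate

`generate_dataset()` emulates a curated two-target bioactivity extract at
desk scale. Defaults (chosen once as the package's benchmark condition):
two targets × 100 compounds; three shared and three per-target exclusive
planted scaffolds, all drawn from real inhibitor chemotypes; 1–3 acyclic
substituents (from an 8-member pool chosen so decoration can never create
or destroy an amide scaffold) at random open ring-carbon positions;
active pPOT ~ Normal(6.5, 1) truncated at 5 with a 0.2 inactive fraction
~ Uniform(3.5, 5), straddling the 10 µM cutoff; 10% extra
approximate-relation rows to exercise the relation filter; values emitted
in mixed nM/µM units. Structures are drawn unique, and a manifest records
every compound's scaffold, substitution positions and true pPOT, so
pipeline recovery can be checked exactly (and is, in the test suite: the
recovered shared set equals the planted set with no false positives).

What the generator does **not** model: the chemotype diversity and scale
of real databases (thousands of compounds, hundreds of scaffolds),
inter-assay noise and unit errors, stereochemistry, counterions and
mixtures beyond simple salts, or scaffolds that overlap each other.
Passing the recovery tests therefore demonstrates correctness of the
bookkeeping and the fragmentation/tally/network logic — not robustness to
the messiness of real extracts.

## Numerical and degenerate-input choices

* pPOT conversion by integer decimal exponents (exact at unit boundaries).
* Thresholds are inclusive: `ppot >= 5`, `support >= 5`.
* Acyclic molecules fragment to acyclic pieces and yield no scaffolds;
  empty inputs give empty outputs except where a quantity is undefined
  (coverage with zero actives, ratio with zero scaffolds), which raise
  explicit errors.
* Unknown relation symbols and unit strings drop the record with a warning
  and a reason code, rather than failing the run.
* Tie-breaks are lexicographic everywhere (shared-scaffold ranking,
  representative id in deduplication, isomorphism choice), making reruns
  byte-stable; the generator and pipeline are deterministic under a fixed
  seed.

## Known limitations

* Scaffold identity ignores stereochemistry and tautomers beyond the
  lactim rule; exotic tautomer pairs can split into two keys.
* The aromaticity model covers rings of size 5–7 and the elements
  C/N/O/S; unusual ring chemistry (e.g. in-ring sulfones) falls back to
  non-aromatic typing.
* Charge neutralization is rule-based and leaves zwitterions whose
  charges are adjacent-bonded (correct for nitro/N-oxides, conservative
  for betaines).
* Shared-scaffold semantics are pairwise; multi-target intersections are
  repeated pairwise calls.
* The test-suite problem sizes (100 compounds per target, ≤ 30 heavy
  atoms for oracle comparisons) are the package's benchmark scale; the
  code is not optimized for database-scale inputs.
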