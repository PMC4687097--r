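---
title: "Predicting xenobiotic biotransformation from reaction-center lookup tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting xenobiotic biotransformation from reaction-center lookup tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proximal)
```

## The problem and the model

When a foreign chemical — a drug, a plasticizer, a persistent pollutant —
enters the body, liver enzymes transform it. Phase I enzymes (mostly
cytochrome P450 oxidoreductases, "CYPs") functionalize the molecule:
aromatic hydroxylation, arene epoxidation, N/O-dealkylation, oxidation of
hydroxyls to carbonyls. Phase II transferases then conjugate the activated
sites with glucuronide, sulfate, glutathione, methyl or acetyl groups. The
derivatives can be more bioactive than the parent compound, so predicting
*which* derivatives can form, and *how likely* each is, matters for
toxicology and drug metabolism.

`proximal` implements a substructure-specific predictor built on three
ideas:

1. **Mining.** Every known reactant–product pair is atom-aligned by a
   maximum common subgraph search. An aligned reactant atom whose KEGG
   atom type differs from its product image is a *reaction center*. For
   each center, a lookup key is stored: the center's type, the type
   multiset of its adjacent neighbors (one bond away) and of its distant
   neighbors (two bonds away; the center itself is always a member,
   being a neighbor of each of its neighbors). The associated value
   records the transformation: product center type, added fragment with
   attachment bonds, removed leaving groups, bond-order and
   hydrogen-count changes. Phase I and Phase II reactions feed separate
   tables.
2. **Generation.** Every heavy atom of a query molecule is a candidate
   center. Sites with identical key tuples form one symmetry class and
   only the lowest-index representative is transformed — this is what
   collapses bisphenol A's 17 atoms to 7 unique substructures and
   4-chlorobiphenyl's 13 to 8 (the two biphenyl link carbons share a key
   without being related by an automorphism, which is why class equality
   is defined on keys, not on graph symmetry). Matching against the
   tables is exact on all three key fields; matched values are replayed
   as graph edits to produce explicit product structures. Phase II is
   applied to the query and, at the default depth of 2, to each Phase I
   product — restricted there to the atoms the Phase I step introduced,
   since the functionalization step is what creates the conjugation
   site.
3. **Ranking.** A Phase I product's plausibility score is
   $\mathrm{score} = \sum_k \overline{\mathrm{activity}}_k \cdot
   \overline{\mathrm{abundance}}_k$ over the CYPs $k$ annotated as
   catalyzing it, using per-CYP averages derived from multi-study liver
   data. More enzymes, and more active/abundant enzymes, mean a higher
   rank. Enzymes without liver data (1A1, 1B1, 2C18, 3A5) contribute
   nothing and are flagged. Phase II products are not ranked: the
   corresponding transferase data are too sparse for a comparable score.

## The molecular graph model

Structures are MDL V2000 molfiles (or SMILES, converted through
ChemmineR/Open Babel to the identical graph model). Hydrogens are
implicit: explicit H atoms are folded into their heavy neighbor's count,
and counts are derived from standard valences and Kekulé bond orders.
Stereochemistry is parsed and discarded — every pattern in this method is
constitution-only. V3000 records are rejected.

Aromaticity is perceived with a Hückel-style alternation test on rings up
to size 8: an atom contributes 1 π electron for an in-ring double bond, 0
if it is a carbon bearing an exocyclic double bond to O/N/S
(carbonyl-type members, as in pyrazolones), 2 if it is an N/O/S lone-pair
donor, and a saturated carbon disqualifies the ring; a count of $4n+2
\ge 6$ flags the ring aromatic. This reproduces the published atom types
of the antipyrine pyrazolone system (N4y / C8y / C8x) as well as plain
benzenoids.

Atom typing itself is a data-driven decision table
(`inst/extdata/kegg_atom_types.yaml`), evaluated top to bottom; it covers
the sp3/sp2/aromatic carbon families (C1a–C1d by heavy-neighbor count,
ring variants C1x–C1z, C2*, C5*, C6a, C8x/C8y), amine/amide/aromatic
nitrogen, the oxygen classes (O1a hydroxyl, O2a/O2x ether, O5a carbonyl,
O6a carboxyl, O1d/O3c on sulfur), sulfur classes and the single halogen
class X. Environments outside the table receive the flagged fallback
`"<El>?"`, which is excluded from all matching — an unknown environment
can never silently fire a rule. The table is editable without code
changes; full fidelity to all ~68 KEGG codes is an extension point, not a
requirement of the case studies.

## Alignment

The aligner searches for a maximum common connected subgraph under two
deliberate relaxations. Atoms align only if their *elements* match —
types may differ, which is exactly what makes reaction centers visible.
Bond orders are ignored during matching, because oxidation-state changes
at or near the center would otherwise sever the alignment; order changes
are compared afterwards, during rule extraction. Every reactant bond
between aligned atoms must map to a product bond (monomorphism), the
search runs in both directions and keeps the larger result, and ties are
broken by a fixed ascending enumeration order, so results are
deterministic. The branch-and-bound search is seeded with the
identity-index prefix alignment (reaction pairs share their leading atoms
in file order) and prunes with an element-wise reachability bound; a
configurable node budget caps worst-case inputs, degrading to the best
alignment found rather than failing. An exhaustive oracle
(`brute_force_mcs`, connected-subset enumeration plus the independent LAD
solver) covers molecules up to 12 atoms and backs the property tests.

## Rule extraction and replay

A minimal value schema (product center type, neighbor types, added
groups) cannot by itself regenerate real structures, so the stored rule
carries a faithful superset:

* the added fragment as an explicit subgraph with attachment bonds
  (glucuronosyl, sulfo, glutathionyl, acetyl, methyl fragments live in
  `inst/extdata/fragments.yaml` as data, not code);
* removed atoms (leaving groups such as the methyl of an
  N-demethylation);
* bond-order/aromaticity changes and per-atom hydrogen-count deltas,
  *including those outside the two-level substructure*. These are needed
  because some transformations are chemically non-local: oxidizing a
  phenol to the quinone-like cyclohexadienone rearranges ring bonds three
  bonds from the center, and forming N-acetyl-p-benzoquinone imine from
  acetaminophen changes the para amide as well. Such atoms join an
  extended match pattern at element-level specificity. Additions and
  removals outside the two-level substructure still reject the rule — the
  key could not license them.

The pattern is finally closed over the immediate neighbors of every
pattern atom ("context" atoms, matched by element only). Two-level keys
are deliberately coarse; on substituted rings a rule extracted two bonds
from the edit can otherwise slide onto a mirror-equivalent site and emit
a positional isomer. The closure pins the replay to the exemplar's actual
environment without changing which sites *match* — matching remains exact
two-level key equality.

Replay embeds the pattern into the query (type-exact inside the
substructure, element-level beyond), deletes removals, grafts the
fragment, applies bond and hydrogen deltas, and then re-derives the
Kekulé orders of every formerly aromatic bond the rule did not set
explicitly, by exact constraint propagation against standard valences.
This makes application independent of which Kekulé rendering the query
happened to arrive in; it is also what lets one dienone rule produce the
correct diene pattern in any phenol ring. A product that cannot satisfy
valence is rejected individually with a diagnostic; the run continues.
Products are deduplicated by a canonical key (BLISS canonical ordering on
a vertex-colored encoding in which aromatic bonds form one class), so the
products of symmetry-equivalent sites and of alternative Kekulé
renderings collapse correctly.

## Normalization and ranking numerics

Activity (pmol substrate/min/mg protein) and abundance (pmol CYP/mg
protein) matrices have enzymes as rows and studies as columns, with
missing cells. The routine iterates: fill missing cells with the current
estimate (initially the row mean of the observed values) → min–max scale
each column to $[0,1]$ → quantile-normalize across columns → re-estimate
the missing cells from row means of the normalized matrix — until the
largest relative change of any imputed entry is below 0.1 %. Quantile
normalization assigns tied values the mean of the reference distribution
over their tied ranks. Because the scale/rank pipeline is discontinuous,
the raw iteration can oscillate between two rank assignments; the update
therefore uses a running average of the estimates (step size $1/k$),
which preserves any fixed point and always settles. Per-enzyme averages
are finally divided by their sum so each kind totals 1; row min/max are
carried as descriptive metadata only (they are not forced to bracket the
sum-normalized average).

The packaged `cyp_stats.tsv` holds the resulting per-CYP averages and
ranges for the nine liver CYPs; `case_enzyme_sets.tsv` holds the CYP
annotations of the bisphenol A and 4-chlorobiphenyl Phase I derivatives.
Reported scores are rounded to 4 decimals; full precision is kept
internally and ranks are assigned on full precision, descending, with
stable input order inside ties (tied products get distinct consecutive
ranks).

## The synthetic-reaction generator

`generate_synthetic_reactions()` exists to make the whole
mine→match→apply pipeline testable without any external database. It
samples small aromatic scaffolds — benzene with up to three substituents
drawn from CH3, OH, NH2, NHCH3, N(CH3)2, OCH3, Cl, plus occasional arene
oxides so that glutathione conjugation has a substrate — and applies one
randomly chosen applicable edit per scaffold, emitting the pair with its
ground truth attached. These scaffolds mirror the simple aromatic
xenobiotics of the case studies; one substituent shell and a single ring
keep every edit unambiguous at the two-level key. What the generator does
*not* emulate: fused ring systems, charged species, stereochemistry,
reaction-frequency statistics, or molecules on the scale of real drug
databases — passing its round-trip property therefore demonstrates
internal consistency of mining and replay, not coverage of
database-scale chemistry.

The curated tables are built the same way: exemplar reactions constructed
by the deterministic edit functions on the packaged case-study molecules
(plus the packaged acetaminophen/N-acetyl-p-benzoquinone-imine and
antipyrine pairs), mined through the ordinary pipeline, and annotated
with the published CYP sets. Exact three-field matching means a
hydroxylation rule mined from one ring environment does not fire on a
different one; the curated set therefore carries one rule per distinct
case-study environment rather than a single generic rule — that
specificity is the method's point. The attachment positions of some
conjugates are committed to chemically standard sites where published
reports leave them unspecified; they are transcriptions, not derivations.

## Problem sizes and determinism

The test suite runs the exhaustive-oracle comparison on 1000 seeded
random molecule pairs of up to 12 atoms, the round-trip recovery on 200
seeded synthetic reactions, and normalization invariants on seeded 9×6
matrices; the demo predicts and ranks both case studies from a cold start
in a few seconds. All randomness flows through explicit seeds; every
search, enumeration and serialization path is ordered, so repeated runs
are byte-identical (table files included).

## Known limitations

* Aromaticity perception handles single rings and simple fused
  benzenoids; exotic polycycles and charged aromatics are out of scope.
* The atom-type table is a documented subset of the KEGG codes; unknown
  environments fall back to a flagged type and never match.
* Multi-step degradation beyond one Phase I plus one Phase II application
  is not chained by default (a depth option exists); glutathione-conjugate
  catabolism (mercapturic acids) is out of scope.
* Phase II products receive no score — the activity/abundance data basis
  exists only for the CYPs.
* Ranking reflects enzyme capacity only: no reaction energetics, no
  CYP induction/inhibition by the xenobiotic itself, no product
  reactivity or cofactor availability.
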