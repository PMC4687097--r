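# proximal

Prediction of xenobiotic metabolism from reaction-center lookup tables.

Foreign chemicals — drugs, plasticizers, persistent pollutants — are
transformed in the liver: Phase I cytochrome P450 (CYP) enzymes
functionalize them (hydroxylation, epoxidation, dealkylation, oxidation)
and Phase II transferases conjugate the activated sites (glucuronide,
sulfate, glutathione, methyl, acetyl). The derivatives can be more
bioactive than the parent, so toxicologists and drug-metabolism
scientists need to know which derivatives can form and which are likely.

`proximal` predicts them by mining reactant–product reaction pairs into
lookup tables and replaying the mined transformations on a query
molecule:

1. **Mining.** Each reaction pair is atom-aligned by maximum common
   subgraph search. An aligned reactant atom whose KEGG atom type differs
   from its product image is a *reaction center*; the table key is
   (center type; adjacent-neighbor type multiset; distant-neighbor type
   multiset, which always contains the center itself), and the value
   stores the replayable transformation (product center type, added
   fragment, removed leaving groups, bond and hydrogen changes, enzymes).
   Phase I and Phase II reactions fill separate tables.
2. **Generation.** Every heavy atom of the query is a candidate center;
   sites with identical keys form one symmetry class and only one
   representative is transformed. Matching is exact on all three key
   fields; matched values are applied as graph edits to yield explicit
   product structures, with Phase II optionally chained onto Phase I
   products.
3. **Ranking.** Each Phase I product is scored as

   score = Σ_k (average activity)_k × (average abundance)_k

   over the CYPs *k* that catalyze it, using normalized multi-study
   human-liver averages (packaged); products are ranked by descending
   score. Enzymes without liver data are skipped and flagged.

The package also contains the full normalization pipeline for the enzyme
data (iterative missing-value imputation, per-study min–max scaling,
quantile normalization across studies, sum-normalized averages), a
deterministic synthetic-reaction generator used to verify the
mine→match→apply pipeline round-trip, and curated tables for the
bisphenol A (BPA) and 4-chlorobiphenyl (PCB3) case studies.

## Worked example

Acetaminophen, with the packaged curated tables:

```r
library(proximal)
ac <- fixture_mol("acetaminophen")
prods <- predict_metabolites(ac, curated_tables())
products_summary(prods)
#>    id phase_chain site   formula     enzymes     rule_provenance
#> 1 P01           I    4   C8H7NO2 1A2,2E1,3A4 acetaminophen_napqi
#> 2 P02          II   11 C14H17NO8    2.4.1.17  phenol_glucuronide
#> 3 P03          II   11  C8H9NO5S     2.8.2.1      phenol_sulfate
```

The three products are N-acetyl-p-benzoquinone imine (C8H7NO2, the
reactive Phase I quinone imine), acetaminophen glucuronide (C14H17NO8)
and acetaminophen sulfate (C8H9NO5S) — the conjugates arise at the
phenolic oxygen, atom 11. Scoring the BPA Phase I derivatives from the
packaged CYP averages:

```r
sets <- load_case_enzyme_sets("BPA")
rank_predictions(data.frame(id = sets$metabolite, enzymes = sets$enzymes))
#>        id         enzymes  score rank no_data_enzymes
#> 1 BPA_I_1 1A1,1A2,1B1,3A4 0.0395    1         1A1,1B1
#> 2 BPA_I_2     1A2,2D6,2E1 0.0361    2
#> 3 BPA_I_3             2E1 0.0317    3
```

The aromatic hydroxylation product ranks first: four CYPs can form it and
two of them (1A2, 3A4) are among the most active and abundant; 1A1 and
1B1 carry no liver activity/abundance data and contribute nothing.

`proximal_demo()` runs both case studies (BPA and PCB3) end to end and
prints the product and ranking tables. A command-line interface is
installed as `exec/proximal` with `transform`, `rank`, `tables` and
`demo` subcommands.

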