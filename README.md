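# fragpath

Predicting the biological pathway(s) of a chemical compound from its
structure alone — for computational biologists and cheminformaticians who
need to place new metabolites, drug candidates or xenobiotics into known
metabolic, signalling or biodegradation routes, and to see *which*
substructures drive each assignment.

## The method

Compounds are encoded as binary fingerprints over molecular fragments:
all linear atom/bond paths of 2–7 atoms and all atom-centered
neighbourhoods of 2–4 atoms, with canonical labels so that atom numbering
and kekulization do not matter. Each pathway is then summarised as a
profile of per-fragment enrichment p-values against the whole-database
background, computed with the cumulative hypergeometric upper tail:

$$Pv_i = \sum_{j=x}^{N} \binom{K}{j}\binom{M-K}{N-j} \Big/ \binom{M}{N}$$

where *M* is the number of compounds in the database, *K* of them carry
fragment *i*, the pathway has *N* compounds and *x* of those carry the
fragment. A query compound *X* is scored against a pathway as the mean
negative log enrichment of the fragments it contains,

$$Sc = -\textstyle\sum_i \log(Pv_i) X_i \,/\, \sum_i X_i ,$$

and scores are made comparable across pathways by a permutation null
model: fragment columns are permuted (preserving every *K*), the
randomized fingerprints are scored, and a maximum-Gumbel extreme-value
distribution fitted to the z-scored null sample converts z-scores into
analytic p-values. Pathways are ranked per compound by increasing
p-value; taking the top-*n* ranks as predictions and sweeping *n* traces
the ROC curve whose area (AUC) summarises accuracy (0.5 = chance). A
Tanimoto *k*-nearest-neighbour baseline and a tenfold cross-validation
harness that reuses the same folds for both methods are included, along
with seeded synthetic generators with planted, known-truth enrichment.

## Worked example

```r
library(fragpath)

# a small annotated corpus: three scaffold families as pathways
lib  <- generate_toy_smiles_library(seed = 1)
mols <- lapply(seq_len(nrow(lib$smiles)), function(i)
  parse_smiles(lib$smiles$smiles[i], lib$smiles$id[i]))
names(mols) <- lib$smiles$id

mat      <- build_matrix(mols)               # fingerprints + vocabulary
merged   <- merge_redundant(mat, lib$map)    # collapse identical vectors
profiles <- build_profiles(merged$matrix, merged$map)
nulls    <- build_nulls(merged$matrix, profiles, n_random = 2000, seed = 2)

query <- parse_smiles("OCC(O)C(O)COP(=O)(O)O", "erythritol_phosphate")
x     <- fingerprint(query, colnames(merged$matrix$values))
predict_pathways(x, profiles, nulls, compound_id = "erythritol_phosphate")
```

```
<fingerprint_matrix> 38 compounds x 168 fragments; density 0.174
<prediction_result> erythritol_phosphate
     pathway_id           sc         z           p rank
1 phospho_sugar 1.468975e+01  4.924829 0.004490154    1
2  alcohol_acid 4.930945e-01 -1.477606 0.933972239    2
3     benzenoid 1.228081e-09 -2.564861 0.999880634    3
```

The query — a sugar phosphate never seen by the model — lands on the
phospho-sugar pathway at rank 1 with p ≈ 0.004: its score sits almost
5 standard deviations above that pathway's random-score mean. The other
two pathways are correctly rejected (p ≈ 1). The substructures behind the
assignment are the pathway's most enriched fragments:

```r
enriched_fragments(profiles$phospho_sugar, k = 3)
```

```
     fragment          pv  K  x
1   C-C-C-O-P 5.39816e-10 12 12
2 C-C-C-O-P-O 5.39816e-10 12 12
3 C-C-C-O-P=O 5.39816e-10 12 12
```

— carbon-chain-to-phosphate paths carried by all 12 family members
(x = 12) and by nothing else in the corpus (K = 12), each with enrichment
p ≈ 5·10⁻¹⁰. With a query molecule, `enriched_fragments(..., compound =
query)` additionally maps each matched fragment to the atom indices at
which it occurs.

Cross-validated evaluation and the baseline:

```r
sim <- generate_planted_matrix(planted_design(seed = 21))
tenfold_cv(sim$matrix, sim$map, method = "profile", seed = 22)   # AUC ~ 1.0
tenfold_cv(sim$matrix, sim$map, method = "knn",     seed = 22)   # same folds
```

A command-line wrapper over the same functions is installed at
`inst/cli/fragpath.R` with subcommands `fragment`, `build`, `predict`,
`evaluate` and `simulate`.

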