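# ligfish

Ligand-based *in silico* target fishing: given a small molecule, rank a
library of protein targets by how likely the molecule is to bind each one,
using nothing but the targets' known active ligands.

## Who this is for

Cheminformaticians and chemical biologists who want a transparent,
fully-reproducible similarity-fusion baseline for target prediction,
polypharmacology profiling, or off-target triage — without black-box
models or external web services. The package also ships a synthetic
benchmark generator, so every part of the pipeline can be exercised and
validated without downloading any bioactivity database.

## The method

Each target *j* is represented solely by its set of *N<sub>j</sub>*
experimentally active ligands. A query molecule *q* is compared with every
reference ligand by the Tanimoto coefficient over circular (ECFP4-type,
radius-2) fingerprints,

&nbsp;&nbsp;&nbsp;&nbsp;Tc(A, B) = |A ∩ B| / |A ∪ B| ∈ [0, 1],

and the per-ligand similarities are fused into one score per target:

| Scheme   | Score for target *j* |
|----------|----------------------|
| Max (MS<sub>j</sub>)      | similarity to the single nearest reference ligand |
| KNN (KS<sub>j</sub>)      | mean similarity of the K nearest reference ligands (3NN, 5NN) |
| Centroid (CS<sub>j</sub>) | mean similarity over all N<sub>j</sub> reference ligands |

Max is exactly KNN with K = 1. All targets are sorted by descending fused
score; the ranking is the query's target-interaction profile.

Retrieval quality is measured over the top-*n* ranks: precision
PR<sub>n</sub> = TP<sub>n</sub>/n, recall RE<sub>n</sub> = TP<sub>n</sub>/m
(m = number of known targets of the query), their harmonic mean
F<sub>n</sub>, and the uninterpolated average precision PR′ — the mean,
over the m known targets, of the precision at each known target's rank,
where known targets ranked outside the top m contribute 0. PR′ = 1 exactly
when the m known targets fill ranks 1..m.

The curation pipeline turns raw bioactivity records into the reference
library: activity threshold (IC50/Ki/Kd/EC50 strictly below 10 µM, or
|ΔG| ≥ 28.53 kJ/mol), homology-based target merging via a supplied mapping
table, per-target structural deduplication (canonical largest-fragment
SMILES keys), and removal of targets with ≤ 10 unique ligands.

## Worked example

```r
library(ligfish)

# a clustered synthetic benchmark: 20 targets x 30 ligands
syn <- generate_fingerprint_library(synthetic_spec(seed = 42))
syn
#> <synthetic fingerprint-level benchmark: 20 targets, 40 queries>
#>   requested within/between Tanimoto: 0.70 / 0.20; realized: 0.622 / 0.187

# rank all targets for one hold-out query with 3NN fusion
q <- names(syn$queries)[1]
fish_targets(syn$queries[[q]], syn$library, fusion_config("knn", 3),
             query_id = q)
#> <target profile for 'Q_T001_01' (knn, k=3): 20 targets>
#>   rank target_id     score n_reference_ligands k_used
#> 1    1      T001 0.7697571                  32      3
#> 2    2      T010 0.4462302                  37      3
#> 3    3      T012 0.4024115                  34      3
#> ...
syn$truth[[q]]
#> [1] "T001"

# 10-fold cross-validation: every library ligand becomes a query while
# its whole fold is excluded from all reference sets
cross_validate(syn$library, folds = 10,
               config = fusion_config("knn", 3), seed = 42)
#> <10-fold cross-validation (knn, k=3): pooled PR' = 1.0000 (SE 0.0000), 600 queries>
```

The query's true target tops the ranking with a fused score near the
within-cluster similarity level (0.77), while the best decoy sits far
below (0.45 — inflated above the 0.2 between-cluster level by ligands
shared across targets); with clusters this well separated, cross-validated
PR′ saturates at 1.

A command-line wrapper over the same functions is installed at
`inst/cli/ligfish` (subcommands `simulate`, `build-library`, `fish`,
`evaluate`, `cv`, `bench-subsample`, `bench-bins`), e.g.

```sh
Rscript inst/cli/ligfish simulate --out bench --seed 7
Rscript inst/cli/ligfish cv --library bench/library.json \
    --scheme knn --k 3 --seed 7 --out-prefix bench/cv3nn
```

## Limitations

The synthetic benchmark controls similarity structure exactly but is
deliberately simple: one feature prototype per target. Real reference
libraries contain targets with several distinct chemotypes, which is the
regime where the set-averaging Centroid scheme falls behind nearest-
neighbour fusion; see the methods vignette
(`vignettes/target-fishing-by-similarity-fusion.Rmd`) for what the
synthetic results do and do not demonstrate about real data.
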