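---
title: "Target fishing by similarity fusion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target fishing by similarity fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligfish)
```

## The model

Chemically similar molecules tend to bind the same protein targets. This
package operationalizes that principle in its simplest robust form: a
target is *defined* as its set of experimentally active ligands, and a
query molecule is scored against a target by fusing its pairwise
fingerprint similarities to that set. No protein structure, sequence, or
learned model is involved; the entire prediction is a ranking of targets
by fused similarity.

For a query with fingerprint $q$ and target $j$ with reference
fingerprints $\{x_{j1},\dots,x_{jN_j}\}$, the pairwise similarity is the
Tanimoto coefficient $Tc(q,x)=|q\cap x|/|q\cup x|$ and the fusion schemes
are:

* **Max**: $\max_i Tc(q, x_{ji})$ — the nearest reference ligand;
* **KNN**: the mean of the $K$ largest pairwise similarities ($K=3,5$ in
  the conventional 3NN/5NN settings; Max is $K=1$);
* **Centroid**: the mean over all $N_j$ similarities.

Targets are returned in descending score order. Max asks "does this
target have *one* ligand like my query?", Centroid asks "is my query like
this target's *average* ligand?", and KNN interpolates. Because the mean
of the top $K$ values is monotone non-increasing in $K$, the per-pair
scores always satisfy Centroid ≤ KNN($K$) ≤ Max; the *rankings* they
induce can nonetheless differ, which is what the evaluation protocols
measure.

### Assumptions

The method assumes (i) the fingerprint captures binding-relevant
chemistry, (ii) each target's ligand set is a reasonable sample of its
chemotype space, and (iii) activity is a set-membership property (the
curation threshold makes "active" binary). It does not model binding
affinity magnitudes, activity cliffs, or target similarity beyond shared
ligands.

## Fingerprints

Fingerprints are hashed circular substructures in the
extended-connectivity family: atom environments of radius 0, 1, 2 are
encoded by iterated neighbourhood hashing of atom invariants (element,
heavy-atom degree, sum of bond orders) over the kekulized connection
table provided by ChemmineR/Open Babel. The default radius 2 corresponds
to the familiar diameter-4 (ECFP4) convention. Exact bit-compatibility
with any proprietary fingerprinter is neither attempted nor needed: every
result in the package depends only on Tanimoto *rankings*, which are
stable across reasonable circular-fingerprint implementations.

Fingerprints are kept as sparse sorted feature-id sets by default;
`bit_length` folds them to a fixed width (features mod `bit_length`) when
a dense representation is wanted. Folding trades a small collision rate
for compactness; the test suite checks that set-based and folded popcount
Tanimoto agree exactly on the folded features. Two empty fingerprints
score 0, not 1, so a structureless query can never rank targets.
Stereochemistry is retained in the canonical identity key (so enantiomers
deduplicate separately) but does not enter the 2D fingerprint at the
default settings.

## Curation parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `concentration_threshold_uM` | 10 | µM | conventional "active" cutoff for IC50/Ki/Kd/EC50; strict `<`, so a record at exactly 10 µM is inactive |
| `energy_threshold_kJ` | 28.53 | kJ/mol | the free-energy equivalent of 10 µM at 298 K ($-RT\ln K$); applied to $|\Delta G|$ with either sign accepted, since reported sign conventions vary |
| `min_ligands` | 10 | ligands | targets with ≤ 10 *unique* ligands are removed; below that, a ligand-set representation is too sparse to fuse over |
| `radius` / `bit_length` | 2 / unfolded | — | ECFP4 convention; folding optional |

The ΔG magnitude reading deserves a note: a favorable binding free energy
is negative, and thresholding the printed value "< 28.53 kJ/mol" literally
would keep *weak* binders. We therefore require magnitude ≥ 28.53 kJ/mol,
which is consistent with the 10 µM concentration cutoff, and accept either
sign convention in the input.

Curation order is fixed: activity filter → target merge → per-target
deduplication → size filter. Merging before deduplication means a ligand
reported against two merged homologs collapses to one entry; filtering
sizes after deduplication means the ≤ 10 rule counts unique structures,
not records. Deduplication is strictly per-target — one molecule active
on many targets stays in all of them, which is precisely the
polypharmacology the profile is meant to recover. Homology grouping
itself (sequence search) is an external concern; the package consumes a
ready merge-mapping table.

## Evaluation metrics and protocols

Precision, recall and F score are computed over the top-$n$ ranks for
$n = 1..N$ (default $N = 20$, the conventional depth for inspecting
target profiles). The headline scalar is PR′, uninterpolated average
precision capped at rank $m$: each of the query's $m$ known targets
contributes the precision at its own rank if it ranks within the top $m$,
and 0 otherwise. Two readings of this metric circulate — averaging
precision over ranks $1..m$ regardless of what occupies them, versus
crediting only correctly-placed targets — and they disagree whenever a
known target ranks outside the top $m$. We implement the second: it is
the only reading under which "a known target outside the top $m$ scores
0" is meaningful, and it makes PR′ = 1 characterize a perfect ranking.

**Cross-validation** splits *ligands* (not ligand–target pairs) into
folds: a molecule active on several targets leaves all its reference
sets simultaneously during its fold, so no query is ever compared with
itself under any of its targets. A true target whose reference set is
emptied by the exclusion stays in $m$ and contributes 0 — the task is
penalized, never silently shrunk. Targets emptied by an exclusion are
omitted from the ranking rather than scored 0, because 0 is a legitimate
similarity value and must not be conflated with "no evidence".

**Subsampling** measures accuracy versus reference-library size: per
replicate, 5 ligands per target are held out as queries, and the
remaining pool is subsampled at each fraction. Queries whose true target
loses all its ligands in a replicate keep it in $m$ (same penalty rule);
the number of dropped targets is reported per replicate.

**Binning** views the same per-query results two ways: by the query's
nearest-neighbour similarity to its own true-target reference set
(computed under the same fold exclusion, so the query itself never counts
as its own neighbour), and by target size deciles (equal-count bins of
targets sorted by ligand count). Empty bins are reported as missing, not
as 0.

Standard errors are reported two ways — over queries
($s/\sqrt{n_\text{queries}}$) and over fold means — because summary
tables in the literature rarely state which is meant; both are in the CV
output.

## The synthetic benchmark

The generator exists so that every pipeline stage can be tested, with
known ground truth, in seconds. Each target is a cluster: a feature
prototype of $F$ features, from which each ligand independently retains
each feature with probability $p$, plus a few ligand-specific noise
features from a disjoint pool. Prototypes share a common core fraction
$c$. Under independent retention the expected within-target Jaccard is
$p^2F / (F(2p-p^2)+2m_\text{noise})$ and the between-target analogue
replaces $p^2F$ with $cp^2F$ in the numerator (and $2pF$ in the union),
so $p$ and $c$ are solved in closed form from the requested
`within_similarity` and `between_similarity`; the generated library
reports its realized values, and a test pins the realization to within
±0.05 of the request.

Defaults and why:

* **20 targets × 30 ligands, within 0.7 / between 0.2** — the benchmark's
  study conditions: comfortably clustered chemistry with a realistic
  baseline of scaffold overlap between targets.
* **$F = 50$ prototype features** — the order of the unique
  circular-feature count of a drug-like molecule; it also sets the
  variance of pairwise similarities around their mean (an early draft
  used 200, which makes every pairwise similarity nearly equal to its
  expectation and is unrealistically clean).
* **3 noise features per ligand** — idiosyncratic substructure not shared
  with any clustermate.
* **multi-target fraction 0.1** — one ligand in ten is a hybrid of two
  targets' prototypes and joins both ligand sets, so evaluation routinely
  faces $m > 1$ queries (most ligands hit one target, a minority several,
  matching the long-tailed shape of real activity data). Hybrids also
  pull the realized pooled within-target mean below the single-target
  pair level (≈ 0.62 at the defaults) — the reported realized statistics
  make this visible.
* **2 hold-out queries per target** — fresh draws from each prototype for
  evaluation outside CV.

A second, SMILES-level mode generates each target as a chemical series —
a core scaffold decorated at two positions from a small R-group
vocabulary — and runs the real parser/fingerprinter end to end.
Similarity structure is then dictated by chemistry rather than
calibration; reusing a scaffold across two targets provides a
deliberately hard, high-cross-similarity fixture. The activity-table
generator attaches potencies strictly inside (0, 10) µM in mixed units to
the true pairs and supra-threshold potencies to a known number of decoy
records, so the curation report can be checked record-for-record.

### What the synthetic results do and do not show

At the default separation the fused score margin between a query's own
target (≈ 0.7) and the best decoy (≈ 0.2–0.45) is tens of standard
errors for every scheme, so 10-fold CV saturates: Max, 3NN, 5NN *and*
Centroid all reach PR′ = 1. This validates the machinery — fold
exclusion, multi-target truth handling, the metrics — but deliberately
cannot reproduce the scheme ordering observed on real libraries, where
Centroid trails nearest-neighbour fusion markedly. That ordering arises
from *multi-chemotype* targets: when a target's ligands form several
distinct structural families, the set mean dilutes toward whichever
family dominates while the nearest neighbours stay informative. The
generator draws each target from a single prototype, so this regime is
out of its reach by construction; the per-pair dominance property
(Centroid ≤ KNN ≤ Max), the saturation itself, and the degradation of
accuracy as `within_similarity` approaches `between_similarity` are the
testable consequences at desk scale. Synthetic libraries also do not
emulate real-data pathologies: assay noise and inter-lab variability,
activity cliffs, series bias from medicinal-chemistry campaigns, or the
heavy-tailed target-size distribution of curated databases.

## Numerical choices and degenerate inputs

* **Ties** are broken by ascending target id after descending score —
  deterministic across platforms; no principled ordering exists for
  exactly tied evidence.
* **$k > N_j$** (possible after CV exclusions): the mean runs over all
  $N_j$ available similarities, degrading gracefully toward Centroid
  instead of erroring.
* **Empty reference set after exclusion**: target omitted and recorded,
  not scored.
* **Rankings shorter than $n$**: precision keeps $n$ as divisor.
* **Hashing**: fingerprints use a 31-bit deterministic polynomial hash in
  exact double arithmetic, so identical structures give identical
  features on every platform; feature collisions are harmless at the
  ranking level.
* **Seeds**: every stochastic procedure (generation, fold assignment,
  subsampling) takes an explicit integer seed, and every CLI run writes a
  manifest with the full configuration and its hash; identical
  configuration and seed reproduce outputs byte for byte.

## Problem sizes

The shipped tests and the acceptance script run on 20 targets × 30
ligands (600 ligands, ~650 ligand–target pairs) for end-to-end
experiments, with 50 random toy libraries (≤ 20 targets × ≤ 30 ligands)
for the oracle-equivalence checks and 1000 random ranking/truth fixtures
for the metric oracle — sizes chosen so a complete validation of the full
pipeline, including four cross-validated schemes and a five-replicate
subsampling experiment, completes in about a minute on one core while
still exercising every code path at realistic per-target set sizes.

## Known limitations

Scores are raw fused similarities: no background correction or
significance model is applied, so scores are comparable across targets
within one profile but not calibrated across queries or libraries.
Fingerprint hashing is intentionally simple (no aromatic perception
beyond kekulized bond orders, no formal-charge invariant); it separates
chemotypes well but is not a drop-in replacement for any specific
commercial fingerprint. The curation stage trusts its input units and
does not attempt to reconcile duplicate measurements of the same pair
beyond structural deduplication.
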