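---
title: "Methods: screened negative samples for drug-pair ADR prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screened negative samples for drug-pair ADR prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcnsadr)
```

## The prediction task and its central difficulty

`hcnsadr` casts adverse-reaction prediction for two-drug combinations as
one binary classification problem per ADR: the input is a drug-pair
feature vector, the label is whether the pair is known to cause that
ADR. Positive examples come from curated drug–drug–ADR triples.
Negatives do not exist as data: no database certifies that a drug pair
is safe. The package's core assumption is pharmacological: combination
ADRs arise from pharmacokinetic or pharmacodynamic interaction between
the two drugs, so pairs with *no evidence of interaction* are the most
credible stand-ins for negatives. Evidence of interaction is read off a
drug–disease–gene tripartite network under three premises: interacting
drugs tend to share target genes; they tend to treat overlapping disease
sets; and their shared genes tend to be genes of their shared diseases.

## The interaction score

For drugs R₁, R₂ with associated gene sets G₁, G₂ and disease sets
D₁, D₂, and with DGₖ the gene set of their k-th shared disease:

* `inter_g = |G₁∩G₂| / |G₁∪G₂|` — Jaccard similarity of gene
  neighbourhoods;
* `inter_d = (|D₁∩D₂| / |D₁∪D₂|) × (|D₁∩D₂| / |V_d|)` — disease
  Jaccard damped by how much of the whole disease layer the pair
  shares, so two drugs sharing one rare indication score less than two
  drugs sharing many;
* `inter_gd = |⋃ₖ ((G₁∩G₂) ∩ DGₖ)| / |G₁∩G₂|` — the fraction of shared
  genes that mechanistically bridge to a shared disease;
* `inter_score` is their exact sum, in [0, 3].

The formulas are written as ratios of set cardinalities; each component
lies in [0, 1]. The numerator union in `inter_gd` is a deduplicated set
union over the shared diseases, not a sum over k: a gene covered by
three shared diseases counts once.

**Empty-set conventions.** Every 0/0 case is defined as 0: both gene
sets empty (`inter_g`), no associated diseases (`inter_d`), no shared
genes or no shared diseases (`inter_gd`). Zero is the conservative
choice — "no evidence of interaction" — and is exactly the behaviour
wanted when low scores mark credible negatives. A network with an empty
disease layer is a configuration error rather than a 0, since the
`inter_d` normalisation is undefined.

**Which gene sets.** Scoring uses the drugs' CTD-style gene
associations (`ctd_genes`), which are distinct from the target-protein
featurization namespace; the two come from different sources and play
different roles (network evidence vs classifier input).

## Ranking and negative selection

All `n(n−1)/2` canonical pairs are scored and sorted ascending by total
score. Ties — ubiquitous at score 0 — are broken by the lexicographic
pair identifier, which makes the ranking, and everything downstream of
it, a pure function of the input tables. For one ADR with P positives
and negative-sample ratio NSR, selection walks the ranking from the
head, skips that ADR's own positives, and stops after
`round(NSR × P)` pairs (round-half-to-even, R's native rounding).
Negatives exclude only the current ADR's positives, not all ADRs':
the candidate list deliberately contains every pair, including pairs
positive for other ADRs, because a pair can cause one reaction and not
another.

The whole-ranking computation is vectorised: gene and disease
intersection counts for all pairs come from sparse incidence-matrix
cross-products, and the bridge term is accumulated drug-by-drug against
that drug's own gene/disease neighbourhood, so cost scales with network
sparsity. A naive per-pair set-loop implementation is kept in the test
suite as an independent oracle; the two agree to 1e-12 on random
networks.

## Representation, reduction, classification

Drugs are binary vectors over four lexicographically ordered feature
namespaces (block order: substructures, targets, substituents,
pathways); a pair vector is the concatenation of its two drug vectors.
Pairs are stored once, in canonical (sorted-ID) orientation, not as two
mirrored training rows: the mirrored copy adds no information the
classifiers used here can exploit, and canonical storage keeps training
and prediction deterministic and half the size. Matrices are sparse,
with value-equivalent densification where a dense algorithm needs it.

Pair vectors are reduced by PCA before classification. The projection
is fit on the training fold only — the wording "all training vectors"
is taken strictly, so the test fold never influences the centring or
loadings; a regression test refits the projection on train-only rows
and checks it reproduces the pipeline's stored scores. On small
datasets the requested component count (`pcn`) can exceed the training
fold's rank; the pipeline caps it at `min(rows, cols)` of the training
matrix and echoes the effective value in the report, rather than
erroring deep inside cross-validation. Direct calls to `fit_reduce()`
keep the strict error.

Four classifiers are wrapped behind one interface with their
implementations' default settings: RBF-kernel SVM (cost 1, gamma
1/ncol), logistic regression, k-NN with k = 5, and random forest with
500 trees. Hard labels follow each algorithm's native rule (margin sign
for the SVM, probability > 0.5 otherwise); continuous scores feed the
AUC. Stochastic learners are seeded from the run seed.

## Evaluation protocol

Cross-validation is per-ADR, stratified, k = 5 by default. Stratification
is a deliberate strengthening of "five equal-sized subsets": with 10–20
samples per ADR, unstratified folds can easily go single-class, which
leaves fold-level AUC undefined. Fold sizes differ by at most one
(remainders are distributed round-robin across classes). Out-of-fold
predictions are pooled per ADR; precision, recall, accuracy and F1 use
the 0-denominator = 0 convention; macro metrics are unweighted means
over ADRs. An ADR whose pooled truth is single-class gets `NA` AUC,
excluded from the macro-AUC with a warning.

`predict_adrs()` ranks ADRs for a new pair using final models retrained
on each ADR's full dataset (not a CV fold), scores sorted descending
with ties broken by ADR identifier.

**Seeding.** One top-level seed is fanned out deterministically to
named sub-streams (fold shuffles, per-ADR negative draws, per-fold
classifier seeds, baseline repeats) via an integer hash, so any
subcommand rerun with the same configuration reproduces byte-identical
reports while sub-streams stay decoupled.

## Baselines

*RGNS* replaces screened negatives with a uniform sample of non-positive
pairs, repeated (default 5 times) and averaged. *Random assignment*
labels each test fold at the training prevalence; against truth of
prevalence p its expected accuracy is p² + (1−p)², which the tests
verify by Monte-Carlo. *One-class SVM* (RBF kernel, implementation
default nu = 0.5 and gamma) trains on positives only and is evaluated
on test sets completed with NSR = 1 negatives, either random
(`ocsvm_random`) or the lowest-ranked prefix of the screen list
(`ocsvm_screen`); "lowest prefix" mirrors the main pipeline's selection
rather than sampling from the low tail, which the comparison leaves
open. All methods share fold structure and positive sets where
applicable.

## What the synthetic generator emulates — and what it does not

The generator plants exactly the premises the score exploits. Each of
`n_interacting_pairs` planted pairs receives `shared_genes_per_pair`
fresh genes (given to both drugs) and one fresh shared disease whose
gene set contains those shared genes; every drug additionally owns
private genes and diseases from disjoint allocations. With
`noise_rate = 0` this makes the score separation *exact*: every
non-planted pair scores 0 and every planted pair scores at least the
analytic bound returned by `expected_separation()` (its `inter_gd`
component is exactly 1). ADR positives are drawn from the planted
pairs, and their drugs carry per-ADR signature feature bits with
probability `signal_strength`; background feature bits are drawn from
the non-signature pool, and `noise_rate` adds spurious bits and edges.

Defaults — 40 drugs, 30 planted pairs, 3 ADRs with 10 positives each,
3 private genes and 2 private diseases per drug, 2 shared genes per
pair, feature pools of 120/150/80/100 with 6 signature and 8 background
bits per namespace, `signal_strength = 0.9`, `noise_rate = 0` — are
chosen as a small but non-trivial regime: per-ADR datasets of 20
samples keep 5-fold stratified CV meaningful, sparsity (≈10 % feature
density) resembles fingerprint data, and a strong signal-to-noise ratio
reflects that signature features are meant to represent genuine shared
pharmacology. The test and reproduction scripts run this fixture over
5 seeds and, for enumeration checks, scale the same generator up to
1048 drugs (548,628 candidate pairs).

What the fixture does *not* model: real marginal distributions of
fingerprints or association degrees (hub drugs, hub genes), correlated
features, overlapping background gene pools across drugs, ADR
co-occurrence structure, or label noise in the positive set. Passing
the directional comparisons on this fixture therefore shows that the
implementation behaves as designed when its premises hold — it does not
certify absolute performance on real pharmacologic databases, which
depends on how well those premises hold there.

A subtlety worth knowing: drug-level signature bits leak into
non-positive pairs that happen to contain a signature-carrying drug.
Random negative draws can therefore include pairs that look partially
or fully positive in feature space — which is precisely the mislabeling
hazard screened selection avoids, and why the random-negative baseline
trails the screened pipeline on this fixture.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `nsr` | 1 | negatives per positive, per ADR; 1 keeps classes balanced |
| `pcn` | 300 | PCA components; 300 suits the full-scale 14,388-dim pairs, small fixtures cap it at the training rank (effective value echoed) |
| `algo` | `"svm"` | per-ADR classifier: `svm`, `logreg`, `knn`, `rf` |
| `folds` | 5 | stratified CV folds |
| `min_positives` | 10 | ADRs below this are skipped — below ~2 positives per fold, per-fold estimates stop being meaningful |
| `seed` | 1 | top-level seed, fanned out to all sub-streams |

`grid_search()` sweeps `nsr × pcn` with a shared seed and marks failing
cells instead of aborting.

## Known limitations

* Scoring treats network edges as unweighted, certain associations;
  confidence scores and edge weights are ignored.
* Drugs absent from the association tables score 0 against everything
  and head the ranking; they are retained (with a coverage warning)
  because excluding them would silently shrink the candidate space.
* Per-ADR negative selection reuses the global ranking prefix, so
  different ADRs receive heavily overlapping negative sets. By default
  only the current ADR's positives are excluded — a pair can cause one
  reaction and not another, and the candidate list deliberately contains
  known-interacting pairs; `exclude_all_positives = TRUE` gives the
  stricter global exclusion.
* The macro average weights a 10-positive ADR equally with a
  1000-positive one; per-ADR rows are reported so other weightings can
  be computed.
* k-NN tie-breaking uses seeded randomisation from the stored model
  seed; predictions are reproducible but k-NN scores are coarse
  (multiples of 1/k).
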