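---
title: "Ranking candidate genes for missing enzymes by functional coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate genes for missing enzymes by functional coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzgap)
```

## The model

A reconstructed metabolic network contains *positions* — enzymes known to be
required by validated reactions — for some of which no gene is assigned
(local orphan reactions). The working assumption of this package is that the
missing gene resembles the genes standing at neighboring positions of the
enzyme–enzyme network (EEN): enzymes sharing metabolites tend to be
co-expressed, co-inherited and annotated with coherent functions. Ranking
candidates therefore reduces to (i) building the EEN, (ii) quantifying
pairwise resemblance between a candidate and each neighbor gene,
(iii) aggregating resemblance over the neighborhood, and (iv) fusing several
resemblance types into one probability.

### Network construction

Nodes are enzymes; reactions with no assigned gene contribute pseudo-enzyme
nodes (`RXN:<id>`) so that their metabolite connectivity is preserved. Two
nodes are joined when their reactions share a metabolite, and all enzymes of
one reaction form a clique. Currency metabolites (ATP, water, cofactor
pairs, etc. — see `default_abundant_metabolites()`) are removed before edge
formation because they connect essentially everything without functional
specificity. Compartment suffixes are not stripped from metabolite ids;
identity is exact string match.

### Pairwise scores

* `CAS` (gene co-annotation lift) and `PAS` (literature co-mention lift) use
  the same dimensionless ratio `N·n_ab/(n_a·n_b)` over different corpora.
  The ratio is scale-invariant — multiplying all counts by a constant leaves
  it unchanged — so only the co-occurrence *structure* matters. Self-pairs
  count every gene carrying the term (`pair(t,t) = single(t)`). Terms with
  zero frequency score 0 rather than erroring, so sparse corpora degrade
  gracefully.
* `funsim` scores term pairs by the Lin form over the most informative
  common ancestor, using annotation frequencies `p(c)` computed with
  true-path up-propagation. Per-category scores are plain all-pairs means,
  and the gene-level score averages the categories in which **both** genes
  carry annotations. Excluding (rather than zeroing) missing categories
  keeps `funsim(X, X) = 1` for partially annotated genes, which matters
  precisely in the under-annotation scenarios this method targets.
* `EXPR` is |Spearman| (direction of co-regulation is irrelevant), `PHYL`
  Pearson on presence/absence profiles. Undefined correlations (constant
  profiles) score 0 and are never propagated as NA.
* `PROFILE` compares a candidate's annotations against a GO profile of the
  position itself, treated as a pseudo-gene under `funsim`.

### Aggregation and weighting

`rel_score()` averages a pairwise score over the exact distance-*k*
neighbors of the position; neighbors without the relevant data (notably
pseudo-enzymes) are skipped and the denominator reduced. `gtom_rel_score()`
replaces the plain mean by a GTOM-weighted mean normalized by the sum of
weights. That normalization is a deliberate choice: the weighted form then
degenerates exactly to the unweighted one under uniform weights, which is
the property implicitly assumed whenever the two forms are compared. GTOM
weights are computed on the full network including pseudo-enzymes, since
they are genuine topology even without gene data.

### The combiner

Feature columns (default: the `GTOM1_N1` and `GTOM1_N2` form of each score
type, plus `PROFILE` when available; CAS/PAS after `log(score + 1e-6)`) feed
an L2-regularized logistic regression. Negative candidates carry observation
weight 0.001 to counter their overwhelming number. Two implementation
choices deserve note:

* the ridge penalty is parameterized as `lambda = 1/(C·n)` with `C = 1` by
  default, exposed to the user;
* features are standardized internally before fitting (coefficients are
  returned on the original scale). The log-converted association scores
  span roughly \[-14, 2\] while similarity scores live in \[0, 1\]; without
  standardization the penalty acts incomparably across columns and the fit
  measurably under-uses the bounded features.

Evaluation is leave-one-out over positions: for each held-out position the
combiner is trained on every other position's single positive and a seeded
sample of its negatives (1000 by default, scaled down in the test suite),
and the held-out pool is ranked by fitted probability. Reported metrics are
the mean reciprocal rank and the cumulative count of positions whose correct
gene falls within each rank threshold.

### Iterative filling

With a substantial fraction of positions simultaneously missing, neighbor
genes are themselves unknown. `iterative_fill()` starts from seeded-random
assignments (iteration 0, committed unconditionally), then repeatedly
re-scores every missing node's pool with the trained combiner. Only the
coherence scores (CAS, PAS, funsim) see provisionally assigned neighbor
genes; expression and phylogenetic scores use known nodes only, since a
provisional assignment is an annotation-level hypothesis, not a measurement.
Updates are synchronous (iteration *n* reads iteration *n − 1*'s
assignments), and a node commits a new assignment only when the top
probability exceeds the cutoff; otherwise it keeps its previous one,
including through oscillations. The cutoff defaults to 0.99, the stricter of
the two values the method's provenance suggests; the package's own fill
experiments use 0.9, which commits earlier without changing fixed points in
practice.

## The synthetic study conditions

`generate_fixture()` emits every input file from a single seed. Defaults
were chosen once as a desk-scale analogue of a small microbial
reconstruction and are not tuned per experiment:

* ontology of 3 namespaces, 6 levels, widths growing 3× per level capped at
  48 (≈ 410 terms), with 20% of terms getting a second parent (diamonds);
  genes annotate terms of the two deepest levels, 5 terms per gene split
  2 MF / 2 BP / 1 CC. Deep terms each annotate only a handful of genes, so
  information content discriminates; much smaller ontologies make every
  term pair look similar and flatten both funsim and CAS.
* 60 enzymes and 200 decoys; 90 reactions over 100 specific metabolites
  (2–3 per reaction) plus 5 abundant ones, 10% orphan reactions. This
  yields ≈ 70 nodes with mean degree ≈ 9 and every enzyme connected.
* expression over 20 conditions, phylogenetic profiles over 25 genomes,
  300 synthetic abstracts whose co-mentions follow gene co-annotation.

The planted effect with size *s*: the correct gene copies a fraction *s* of
**each** first-level neighbor's annotations, mixes its expression vector
with the normalized neighbor mean at weight √s, copies the neighbors'
majority presence bit with probability *s*, and the position profile draws a
fraction *s* of its terms from the correct gene's own annotations. At
*s* = 0 the correct gene is exchangeable with decoys and leave-one-out MRR
sits at the chance level (≈ 2/pool size); at *s* ≥ 0.8 the combiner
recovers essentially every position. The generator emulates the
*statistical* structure the method exploits — neighborhood coherence — and
none of the biology it does not: no stoichiometry, no realistic GO topic
structure, no homology between decoys. Passing tests on fixtures therefore
demonstrate correctness of the machinery and recoverability of planted
signal, not expected accuracy on any real genome.

The multi-missing (fill) experiments run under coarsened annotations
(`map_annotations()` to level 3 of the 6-level DAG) at moderate effect: at
full resolution and high effect every missing node resolves at rank 1 in one
iteration and the probability–rank relationship degenerates to a point. The
coarsened regime spreads ranks and shows the calibration property — nodes
assigned with high probability are the ones whose correct gene ranks well.

## Numerical choices and degenerate inputs

* Term levels are longest paths from the synthetic root `"all"`; because a
  level-L term always has a maximizing parent at L − 1, every deep term has
  an ancestor chain through all lower levels, and level mapping always finds
  ancestors exactly at the target level (a below-target fallback exists as
  defensive code only).
* Tie-breaking in ranking is the mean rank of the tied block — seed-free
  and deterministic, and an uninformative scorer yields the exact chance
  MRR.
* `log_transform` uses ε = 1e-6; any ε only shifts the CAS/PAS columns by a
  monotone reparameterization, and the combiner's standardization absorbs
  the scale.
* Zero-variance and missing-data cases (constant expression, all-zero
  profiles, unannotated genes, empty neighborhoods, all-zero GTOM weights)
  all resolve to a neutral 0 contribution rather than NA, so a ranking is
  always produced; the affected pairs are simply uninformative.
* All randomness (fixture generation, negative sampling, iteration-0
  assignment) flows from explicit seeds; reruns are byte-identical.

## Known limitations

* CAS/PAS use the lift ratio; other association variants differing by a
  global constant would produce identical rankings, but variants with
  different denominators (e.g. Jaccard-style) would not — the choice is
  fixed, not data-driven.
* All-pairs averaging (rather than best-match) in funsim and PROFILE
  dilutes exact term matches for heavily annotated genes; on the synthetic
  fixtures PROFILE is accordingly a weak single feature even though its
  profile terms literally come from the correct gene.
* The literature corpus is a frozen counts table; no live querying, MeSH
  expansion, or synonym handling is performed, and the tokenizer only
  removes the stop-words "and, or, not".
* The combiner is a plain ridge-logistic fit; probabilities are used for
  ranking and commit decisions, not as calibrated posteriors.
* The fill algorithm keeps the last committed assignment under oscillation;
  no convergence guarantee is claimed, matching its probe-style use.
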