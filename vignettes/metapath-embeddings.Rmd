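---
title: "Metapath embeddings of biomedical knowledge graphs: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapath embeddings of biomedical knowledge graphs: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biokg)
```

## The problem

Biomedical knowledge is scattered over hundreds of databases that describe
associations between heterogeneous entities: genes interact with genes,
compounds bind proteins, diseases associate with genes, cell lines respond
to drugs. `biokg` organizes such data as a typed knowledge graph and turns
selected *metapaths* — semantic routes such as
`DIS-ass-GEN-ass-DIS` ("diseases that associate with the same genes") —
into fixed-length vectors per entity. The vectors summarize the chosen
slice of the graph and can be consumed by any downstream statistical or
machine-learning method, while staying cheap to store and compare.

The pipeline is:

1. **Typed graph.** Entity types (metanodes, 3-letter uppercase tags) and
   typed relations (metaedges, `SRC-rel-TGT`) form the schema; each
   dataset is one named binary edge set bound to one metaedge. Datasets
   are never merged at ingestion, so any subset can back a metapath.
   Edges are unweighted by design: source-specific confidence scores
   mostly reflect annotation and detection biases rather than biological
   strength, and no common scale exists across 150-odd heterogeneous
   sources.
2. **Metapath collapse (DWPC).** A multi-step metapath is collapsed into
   one source-by-target matrix of degree-weighted path counts.
3. **Embedding.** The collapsed network is explored by weighted random
   walks, and a skip-gram model turns walk co-occurrence into vectors.
4. **Evaluation.** Embeddings must reconstruct the network they were
   trained on (AUROC against permuted node pairs); they are characterized
   against orthogonal reference networks and queried through co-rank
   statistics with permutation-based null models.

## Degree-weighted path counts

For each step of a metapath, the dataset's binary adjacency $A$ is damped
as $D_r^{w} A D_c^{w}$, where $D_r$, $D_c$ are diagonal matrices of row
and column degrees *within that dataset* and $w = -0.5$ by default.
Chaining the damped matrices by multiplication sums, over all paths
between a source and a target, the product of the degrees of every node
crossing damped by $w$ — the degree-weighted path count. Hubs therefore
contribute much less than specific intermediates. Setting $w = 0$
recovers raw path counts; the implementation is checked against an
explicit path-enumeration oracle at $10^{-9}$ tolerance.

Choices worth knowing:

* **Degrees are per dataset**, not on the merged graph, so a node's
  hubness in one source does not distort a path through another.
* **Universe alignment.** Consecutive steps are restricted to the node
  universe they share; a chain with an empty shared universe is an error
  ("disconnected metapath").
* **Self paths.** For homogeneous round trips (e.g.
  `DIS-ass-GEN-ass-DIS`) the diagonal collects each node's paths back to
  itself. Self-similarity is not an edge, and on these metapaths the
  diagonal is always the largest entry of its row, so it would otherwise
  consume a capping slot and distort the top-weight subsets; it is
  removed at construction.
* **Several datasets or `+`-combined relations per step** produce one
  DWPC matrix per single-dataset chain (cartesian product over steps),
  which are then summed. Mimicking/reversion compositions that exclude
  cross terms (e.g. `dwr-dwr` plus `upr-upr` but not `dwr-upr`) are
  expressed by computing the two chains separately and merging with
  `merge_networks(mode = "sum")`.
* **Directed homogeneous steps** (kinase-substrate, TF-target) are
  traversed along their direction by default; the `'_'` mark next to the
  source entity selects the orientation, and traversal against the
  direction uses the transpose.

## Controlling node degree

Even damped, longer metapaths connect almost everything to almost
everything with tiny weights, which makes the network dense and the walks
uninformative. Each node therefore keeps only its top
$k = \mathrm{clamp}(\mathrm{round}(0.05\,n_\text{possible}),\,3,\,250)$
neighbours by weight ($n_\text{possible}$ = size of the opposite side,
minus one for homogeneous networks). The cap is applied from both the row
and the column perspective and an edge survives if **either** endpoint
keeps it. The union was chosen over the intersection because the
intersection can disconnect low-degree nodes whose few neighbours are
themselves popular; the cost is that a node can end up with more than $k$
surviving edges when many partners elect it. Ties are broken by weight
then ascending neighbour id, which makes capping deterministic and
idempotent.

After capping, connected components covering less than 5% of the entities
are dropped; if less than half of the node universe survives, the
metapath is flagged REJECTED and not embedded.

## Random walks and skip-gram

The retained network is explored by 100 walks of length 100 per node,
with next-step probabilities proportional to the DWPC weights scaled per
node to sum to one (uniform for unweighted length-1 metapaths). With the
return and in-out parameters at $p = q = 1$ the walk is first-order
Markov, which is what the pipeline uses; a second-order walker is
available for other $p, q$. Bipartite networks are walked on their
two-layer graph, so walks alternate sides and both entity types are
embedded in the same space.

The skip-gram trainer is a from-scratch single-threaded implementation of
the word2vec negative-sampling objective (sigmoid lookup table,
unigram$^{0.75}$ negative table, dynamic window, linear learning-rate
decay). Defaults follow word2vec conventions where the pipeline itself
fixes none: window 5, 5 negatives, 5 epochs, initial learning rate 0.025,
128 dimensions. No frequent-token subsampling is applied: walk corpora
have much flatter token distributions than natural text, and skipping it
keeps training exactly reproducible token-for-token. Both the walker and
the trainer draw from their own deterministic RNG seeded by
`embed_config(seed = )`, so runs are bit-reproducible regardless of the
caller's R RNG state.

## Evaluation and statistics

**Reconstruction AUROC.** Every network edge is scored by the cosine
distance of its endpoint vectors and compared against 100 random node
pairs per edge (endpoints resampled within the correct entity side;
self-pairs and true edges rejected; rejecting true edges was an open
choice, and it only makes the bar slightly harder). The AUROC is the
Mann-Whitney rank statistic with ties
mid-ranked, so it is invariant to monotone transforms of the distance.
Embeddings below 0.8 are not retained. For weighted multi-step networks
the same exercise is repeated on subsets keeping each node's top 1%, 25%
and 50% neighbours by DWPC weight. An AUROC that cannot be computed
(one class empty, fewer than two shared nodes) is reported as missing,
never as 0.5.

**Co-rank P values.** For a node pair $(a, b)$, the rank of $b$ in $a$'s
ascending-distance list (1-based, self excluded, ties by id) is
normalized by the $n - 1$ other covered nodes, and symmetrically for
$a$; the empirical P value is the geometric mean of the two. Requiring
*both* directions to be small prevents broadly connected entities — which
are close to everything — from dominating; the quantity is an empirical
quantile, not a significance test. With the $n - 1$ denominator the
mutually-farthest pair scores exactly 1 and the statistic lies in
$(0, 1]$; under a random-vector embedding it is uniform to within
KS < 0.05 at 5,000 pairs.

**Permutation nulls.** Query networks are randomized by degree-preserving
double-edge swaps (10 attempted swaps per edge by default; on the order
of 1,000 permutations for a stable null). Homogeneous networks use
`igraph`'s degree-preserving rewiring; bipartite networks use a dedicated
swap routine because generic rewiring mixes the two sides. Fold change at
a P value cutoff is the real edge count over the mean null count, with
the null mean floored at one edge to keep the ratio finite. The
FDR-controlling cutoff is the largest value covering at most the nominal
fraction (default 5%) of null edges on average — the wording "minimum P
value needed to cover no more than 5%" admits two readings, so the
stricter first-crossing variant is available via `which = "smallest"`;
the default maximizes recall at the nominal FDR. Coverage is a step
function over the pooled null values; nothing is interpolated.

## Standardization of continuous inputs

**Expression signatures.** Duplicate genes/samples are collapsed by mean;
values are log2-transformed (data already on log scale skip this;
non-positive values are shifted by $1 - \min$ and the shift recorded);
samples are quantile-normalized (limma) so every sample shares one value
distribution; each gene is centred by its median and scaled by its IQR —
the conventional reading of a "quantile range", with zero-IQR genes
scaled by 1 under a warning; finally the top 250 most positive and most
negative genes per sample become its `upr`/`dwr` signature edges, with
rank-boundary ties broken by gene id for determinism. Quantile
normalization is performed across samples (making sample distributions
identical), the standard orientation for this pipeline.

**Drug sensitivity (waterfall).** Cell lines are ranked by ascending AUC
and the elbow of the ranked curve is found by exhaustive scan of the
perpendicular distances to the chord joining its endpoints. On the usual
concave profile the maximal distance sits where the resistant plateau
leaves the chord, but consecutive plateau order statistics produce
near-tied distances just past the corner, so the elbow is taken as the
earliest rank within 2% (`waterfall_elbow_tol`) of the maximum and the
sensitive set is the prefix before it; on a convex profile the knee below
the chord is included instead. Calls are clipped to 1–20% of the lines
and must have AUC < 0.9, so the set may be empty. Calling is monotone in
practice: making a sensitive line more sensitive never removes it.

**Ontologies.** Annotations are propagated to all ancestors before
cross-referencing; propagation is idempotent and monotone. The
information content $IC(t) = -\log_2(|entities(t)|/n_{corpus})$ (Resnik
style, base 2) flags overly general terms; terms below the bottom-5% IC
quantile are pruned by default; no universal cutoff exists across
ontologies, so the quantile is an explicit, configurable choice.

**Vocabulary mapping.** Terms are encoded as binary vectors over shared
cross-references, TF-IDF-reweighted and matched by cosine at a 0.5
cutoff. The TF-IDF variant matters for the cosines and is therefore fixed
and documented: smoothed idf $\ln((1+N)/(1+df)) + 1$ with L2-normalized
rows. Pathway vocabularies are clustered PathCards-style: pathways with
at least 20 genes merge into SuperPaths while any pair of clusters has an
overlap coefficient of at least 0.9 (greedy best-pair agglomeration, ties
by id), and pathway pairs whose SuperPath gene sets reach Jaccard 0.7
become similarity edges.

**Perturbation data** are reified: each experiment becomes a perturbagen
(PGN) node linked to its perturbed gene (`PGN-pdw-GEN` for
knockdown-like, `PGN-pup-GEN` for overexpression-like kinds) and to its
outcome, which untangles the perturbation from its effect.

## The synthetic universe

All tests run without any external download on seeded generators that
emulate the structure each stage assumes:

* `planted_partition_network()` — stochastic block model with true labels
  returned, the ground truth for silhouette and AUROC checks.
* `synthetic_kg()` — a small graph (defaults: GEN 200, DIS 120, CPD 80,
  PWY 40; 4 blocks; $p_{in} = 0.25$, $p_{out} = 0.02$) whose homogeneous
  and bipartite layers share one block structure, so multi-step metapaths
  carry signal.
* `synthetic_expression()` — log-normal baseline (per-gene log2 mean
  $\mathcal{N}(8, 1.5)$, sample noise $\mathcal{N}(0, 0.5)$) with 2% up-
  and 2% down-marker genes per sample group shifted by the effect size
  (default 2 log2 units).
* `synthetic_drug_response()` — bimodal AUC per drug: sensitive with
  probability `sens_frac` (default 0.05) at $\mathcal{N}(0.30, 0.05)$,
  resistant at $\mathcal{N}(0.92, 0.03)$, clipped to $[0, 1]$.

Generators are pure functions of their seed (byte-identical outputs).
Sizes were chosen once so that the full pipeline — graph, DWPC, capping,
walking, training, evaluation — runs in minutes on a single CPU: about
2,000 nodes and 50,000 edges at most, with the end-to-end checks using a
500-node planted partition and the default 100×100 walk budget.

What passing on these fixtures does *not* show: robustness to the heavy
degree skew, annotation sparsity, inter-source redundancy and vocabulary
noise of real biomedical databases. The fixtures have clean block signal
and near-homogeneous degrees; real metapaths can be rejected by the
component filter, retained with borderline AUROCs, or dominated by a few
hubs in ways the synthetic universe only caricatures.

## Numerical and degenerate-input conventions

* Sparse matrices throughout; multiplication never materializes zero
  entries, and symmetric storage classes are converted to general storage
  wherever triplets or row slices are read (one-triangle storage would
  silently hide half of the neighbourhoods).
* Zero-degree factors: $0^{w}$ with negative $w$ is treated as 0, so
  isolated nodes simply contribute no paths.
* Tie-breaks are always (value, then id), making every ranking
  deterministic.
* `round(0.05 n)` uses round-half-up, not banker's rounding.
* Isolated nodes are skipped by the walker with a warning; walk corpora
  on connected undirected graphs never stall because the walker can
  always step back.
* Empty sensitive sets, empty similarity outputs and zero-coverage
  recapitulations are valid results, not errors; undefined AUROCs are
  `NA`.

## Known limitations

* The greedy pathway agglomeration is quadratic in the number of
  pathways; it targets vocabulary-sized inputs (hundreds), not genome
  scale.
* The second-order ($p, q \neq 1$) walker is available but not exercised
  by the pipeline defaults, which fix $p = q = 1$.
* Multi-threaded skip-gram training is deliberately absent: determinism
  was preferred over speed at the fixture scales this package targets.
* Only binary edges are supported; weighted source evidence is discarded
  by design (see above), not aggregated.
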