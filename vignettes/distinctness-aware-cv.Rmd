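---
title: "Distinctness-aware cross-validation for expression prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinctness-aware cross-validation for expression prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Expression-to-expression models predict a gene's expression in a condition
(a sample) from the expression of all transcription factors (TFs) in that
same condition. Such models are routinely evaluated by K-fold
cross-validation with random fold assignment (RCV). When the conditions
cluster by biological context — cancer type, tissue, treatment — random
folds place test samples next to near-identical training samples, and the
CV estimate answers a question nobody asked: "how well do I predict samples
I have essentially already seen?" For applications whose real goal is to
learn generalizable TF–gene relationships (global gene-regulatory-network
inference above all), that estimate is systematically over-optimistic.

`distinctcv` makes the train/test relationship an explicit, measurable, and
controllable quantity.

## The distinctness score

For a test condition $i$ with TF-expression vector $E_i$ and a training set
$R$, the distinctness score is the harmonic mean of min-max-normalized
Euclidean distances:

$$\eta(E_i, R) = \frac{|R|}{\sum_{j \in R} 1 / D(E_i, E_j)},$$

where $D$ is the Euclidean distance between TF profiles rescaled to
$[0, 1]$ by the minimum and maximum over *all* pairs of conditions. The
harmonic mean is the point: it is dominated by the closest training
samples, so a single near-replicate of the test condition in the training
set collapses $\eta$ toward zero, exactly matching the intuition that such
a test sample is not distinct at all. A whole K-fold collection $P$ with
folds $S_1,\dots,S_K$ and complements $R_k = C \setminus S_k$ is scored by
averaging over every condition scored once as a test sample:

$$\eta(P) = \frac{1}{|C|} \sum_{k=1}^{K} \sum_{j \in S_k} \eta(E_j, R_k).$$

Numerical choices, all deliberate:

* **Global normalization.** $D_{\min}$ and $D_{\max}$ are computed once on
  the full condition set and reused for every partition. Per-partition
  renormalization would make $\eta$ incomparable across partitions, which
  would defeat the purpose of a partition-comparison score.
* **Zero distances.** The globally closest pair normalizes to exactly 0;
  when such a pair spans test and train, $1/D$ is undefined and the score
  is set to 0 — the mathematical limit of the harmonic mean, and the right
  answer scientifically (a test sample indistinguishable from a training
  sample has no distinctness). No epsilon is injected.
* **Diagonal exclusion.** Self-distances are excluded from the extremes;
  including them would pin $D_{\min}$ at 0 and shift every score.
* **Degenerate geometry.** If all pairs are equidistant
  ($D_{\min}=D_{\max}$) normalization is undefined and the package refuses
  the input rather than guessing.
* **Raw vs z-scored features.** Distances are computed on the matrix as
  given; `compute_pairwise_distances(..., zscore = TRUE)` opts into
  feature z-scoring. Whether distances should be taken on raw or
  standardized TF expression is genuinely open (standardization before
  *regression* is a separate, always-on step); raw is the default because
  it adds no hidden transformation.
* **Medians** of even-length score lists are the midpoint of the two
  central values (the `stats::median` convention).

`collection_distinctness()` is defined only for mutually exclusive,
exhaustive K-fold collections — the $|C|$ denominator presumes them. For
annealed partitions, which need not be exhaustive, per-partition summaries
(`partition_distinctness()`) are the honest quantity, and the package
refuses to invent a collection-level score for them.

## Partition generators

**RCV** (`random_kfold`): uniformly random folds, sizes differing by at
most one.

**CCV** (`clustered_kfold`): k-means clusters of the conditions become the
test folds, so every test fold is by construction distant from its
training complement. We use k-means++ seeding feeding the Hartigan–Wong
iterations (up to 300), with up to ten re-initializations if a cluster
comes back empty. The choice of k and seed are the caller's; the cost of
CCV is precisely that it inherits every property of the clustering.

**SACV** (`sacv_generate`): simulated annealing over fixed-size test sets
with the partition *mean* distinctness as the objective (the collection
formula does not apply to a single non-exhaustive partition). Moves swap
one uniformly chosen test condition with one uniformly chosen training
condition; acceptance follows the standard Metropolis rule — improvements
always, worsening moves with probability $\exp(\Delta\eta / T)$. The
temperature decays geometrically (`cooling_factor` per
`iters_per_temperature` proposals) from `t_initial` until it falls below
`t_min`. Every accepted state, including the random initial state, is
recorded; after discarding the first `burn_in` accepted states,
`n_select` states are drawn uniformly without replacement and returned in
acceptance order, so distinctness trends upward across the selection.

The defaults of `sa_config()` are the genome-scale protocol: $T_0 = 1$,
500 proposals per level, cooling 0.98 down to $10^{-14}$, burn-in 50000,
30 selected partitions. At genome scale the burn-in swallows the entire
high-temperature phase (in the protocol's original application it
discarded about two thirds of all accepted states), leaving the ordered
climb for sampling.

At the desk scale this package's tests and demos use (180 conditions, 50
features, test sets of 30), the geometry is harsher than at genome scale:
a single swap moves the 30-sample mean by $\sim 10^{-3}$, while the chain's
stationary fluctuation at high temperature has about the same magnitude as
the drift between consecutive sampled partitions. Three regimes are worth
naming: a high-temperature phase ($T \gg 10^{-3}$) where essentially every
proposal is accepted and the chain is an unbiased walk at the
random-partition level; a transition band ($T \approx 10^{-3}$) where the
chain climbs; and a frozen phase where only the few remaining improving
moves are accepted. Because geometric cooling spends proposals evenly per
unit $\log T$, the high-temperature phase always contributes the majority
of accepted states unless the schedule starts near the transition band.
The desk schedule used in the test suite
(`t_initial = 0.05`, cooling 0.95, 200 proposals per level,
`t_min = 10^{-5}`, burn-in 1000, 15 selections) sizes the walk phase at
roughly the burn-in, so the sampled range starts at the random level and
climbs; users who need a denser top of the spectrum should lengthen the
schedule and raise the burn-in together, which is exactly what the
genome-scale defaults do. A consequence worth stating plainly: with a
small test set the selected sequence is upward-trending but noisy —
strict non-decrease between consecutive selections should not be expected
at this scale, and the package exposes the full trace so users can see
the climb rather than trust a summary.

`sacv_generate` errors, reporting the accepted count, if the schedule
produced no more than `burn_in + n_select` accepted states.

## Regression methods

`fit_predict_partition()` implements three expression-to-expression
regressors behind one interface:

* `lars` — a least-angle-style sparse linear model fit on the lasso
  regularization path (`glmnet`, $\alpha = 1$), tuning the **number of
  active predictors** over $\{1, 2, 5, 10, 20, 50\}$ by inner 5-fold CV;
  the lasso-modified least-angle path and the lasso path coincide, and the
  active-set size is the natural complexity knob of that family.
* `elastic_net` — `glmnet` over mixing $\alpha \in \{0.1, 0.5, 0.9\}$ and
  a 20-point log-spaced penalty path per $\alpha$, chosen by inner 5-fold
  CV mean squared error. Ties resolve toward the stronger penalty, then
  the sparser mixing.
* `svr_rbf` — $\varepsilon$-SVR with Gaussian kernel (`e1071`) at fixed
  conventional settings (cost 1, $\gamma = 1/p$, $\varepsilon = 0.1$),
  overridable through the `grid` argument; no inner CV.

Features and target are z-scored with **training-fold statistics only**,
and predictions are inverse-transformed to the original scale. Fold-local
normalization is the only leakage-free reading of "the input was z-score
normalized", and the suite verifies the stronger property directly:
permuting test-fold target values leaves fitted predictions bit-identical.
Zero-variance features on a training fold are dropped with a warning; a
zero-variance target is an error (its z-transform does not exist); if
every feature is dropped the prediction falls back to the training mean.
Every (partition, gene) task is seeded independently from the spec's seed,
so results are identical under any execution order.

Accuracy is reported two ways, matching their different uses: pooled
out-of-fold Pearson correlation per gene for exhaustive collections (one
prediction per condition, pooled across folds), and per-partition test-set
PCC and RMSD for spectrum-resolved analyses. Undefined correlations
(constant vectors, test sets smaller than 3) are reported as `NA` with a
warning, never silently zeroed. `compare_methods()` subtracts per-gene
RMSDs partition by partition, and
`distinctness_accuracy_correlation()` computes per-gene Spearman rank
correlations (average ranks on ties) between partition distinctness and
accuracy.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the method is
built for, not the marginal distributions of RNA-seq:

* conditions fall into well-separated isotropic Gaussian clusters in TF
  space (centroids on a sphere scaled so pairwise spacing is
  `cluster_separation` within-cluster standard deviations — the clustered
  geometry real tumor transcriptomes show when represented by TF
  expression);
* each target gene is a sparse linear function of the TFs
  (`regulators_per_gene` nonzero standard-normal coefficients), with each
  cluster perturbing the nonzero coefficients by
  $\mathcal{N}(0, \texttt{context\_shift\_sd}^2)$ — contexts share most of
  the regulatory program but not all of it, which is what makes
  cross-context generalization nontrivial;
* optional near-replicates (`replicate_fraction`, jitter $0.01\sigma$)
  emulate biological replicates that make random CV trivially easy;
* `generate_heldout()` draws entirely fresh clusters that share each
  gene's *base* coefficients but get their own context perturbation —
  held-out accuracy therefore measures exactly cross-context
  generalization.

The reference configuration (6 clusters × 30 samples, 50 features,
separation 8, context shift 0.5, noise 0.5, 20 genes) is the scale at
which the whole pipeline runs in about a minute on one core.

What the generator does **not** model — count noise, library-size and
batch effects, correlated TF modules, a continuum of contexts — bounds
what green tests mean: they demonstrate the scoring and partitioning
machinery and the *direction* of the over-optimism and
distinctness-accuracy effects, not their magnitude on real transcriptomes.
Two honest caveats found while characterizing the generator. First,
because distances are globally min-max normalized, adding near-replicates
shrinks $D_{\min}$ and thereby *raises* every other normalized distance;
the collection-mean distinctness can increase even though the replicated
samples themselves score near zero — per-sample scores, not the
collection mean, carry the replicate signal. Second, context shift acts on
cluster-level coefficients, so prediction hardness is a per-cluster step
rather than a smooth function of distance; distinctness-accuracy rank
correlations at desk scale are correspondingly noisier than on real
heterogeneous data, where hardness varies continuously.

## Files and interfaces

Expression matrices are tab-separated text (conditions × features, id
column first; `transpose = TRUE` accepts the features × conditions dialect
of TCGA/Xena exports; gzip transparent). Partition collections are JSON
(`kind`, `folds` as condition-id lists, `seed`, `meta`), round-tripped
with full invariant re-validation. Missing values are rejected, not
imputed — every formula above assumes complete vectors.
`run_pipeline()` drives simulate → distances → partition → evaluate and
writes a manifest (seeds, parameters, versions) sufficient to reproduce
every output byte-identically; `inst/cli/distinctcv.R` is a thin Rscript
exposing the same stages as shell subcommands.

## Known limitations

* The annealer optimizes mean partition distinctness only; no stratified
  or multi-objective variants.
* The score is the harmonic mean of min-max-normalized Euclidean
  distances — alternative metrics (correlation distance, Mahalanobis) and
  alternative means are out of scope by design.
* Uniform-by-acceptance-index sampling concentrates where acceptance is
  dense; at desk scale the very top of the distinctness range is sparsely
  represented (see the annealing discussion above).
* The three regressors are the supported set; the harness is indifferent
  to the model family but no other fitters are wired in.
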