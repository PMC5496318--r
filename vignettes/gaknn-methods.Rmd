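---
title: "GA/KNN ensemble classification: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GA/KNN ensemble classification: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaknn)
```

## The model

`gaknn()` fits a wrapper feature-selection ensemble for multi-class
classification of expression profiles. The components, bottom up:

**Input scale.** All analysis operates on floor-log2 values: every raw
normalized expression value $v$ is replaced by $\log_2\max(v, 1)$
(`floor_log2()`). Values below 1 read-per-kilobase-per-million-scale units
are mostly noise, so flooring them at 1 (which maps to 0) removes spurious
variation among near-zero measurements while leaving the informative range
untouched. The transform is applied exactly once; the dataset object carries
a flag that makes re-application an error.

**Partitioning.** `stratified_split()` assigns
$\mathrm{round}(f \cdot n_c)$ samples of each class $c$ to training
(default $f = 0.75$), rounding half up and clamping to $[1, n_c - 1]$ so
both sides of the split retain every class. The clamp matters only for very
small classes; for a 9,096-sample cohort it reproduces the familiar
"~6,800 training / ~2,300 testing" sizes.

**The classifier.** `knn_predict()` uses Euclidean distance with $k = 5$
and a *strict majority* rule: a class must hold more than $k/2$ of the
neighbours to win, otherwise the sample is *unclassifiable* (a 2–2–1 vote
is a rejection, not a coin flip). Distances are computed on per-gene
standardized values (zero mean, unit variance, training-set statistics
only, frozen for test samples) so that highly expressed genes do not
dominate the metric. Genes constant in the training set standardize to all
zeros and contribute nothing. Neighbour order is the total order
(distance, training index); this canonical tie policy makes predictions
deterministic and invariant to training-sample permutation.

**The objective.** `knn_fitness()` scores a gene subset by leave-one-out
KNN accuracy *within the training set*, with the left-out sample excluded
from its own neighbour search. Resubstitution would be degenerate — each
sample would be its own nearest neighbour at distance zero — so
leave-one-out is the natural reading of "classifies the training samples
correctly". Rejections count as errors.

**The search.** `ga_evolve()` maintains a population (default 300) of
fixed-size distinct-gene subsets (default 20). Each generation applies
tournament selection (size 3), uniform union-repair crossover (rate 0.9),
per-position replacement mutation (rate 0.05) and elitism (2). Crossover
gives both children all genes the parents share and partitions the
remaining parental genes randomly between them, so children are always
valid subsets of the parental union; mutation replaces a position by a gene
not currently in the subset. The search stops as soon as the best
chromosome of the current generation — including generation 0, the random
initial population — reaches 90% training accuracy, or when the generation
budget (default 300) is exhausted; the best subset ever seen is returned as
the *near-optimal classifier*. Fitness values are cached within a run
keyed by the sorted gene tuple, since subsets recur.

**The ensemble.** `gaknn()` repeats the search `n_runs` times on one fixed
partition, classifying every test sample with each run's subset. Run $r$
is seeded `seed + r`, so runs are self-contained: executing them in any
order, or one at a time, reproduces the ensemble bit for bit (this is also
what makes parallel execution safe, although the implementation is serial).
From the runs-by-samples prediction matrix come the three result types:
per-sample profiles over all classes plus the reject category
(`prediction_profiles()`, summing to 1, with $\pi_{cc}$ the true-class
entry), modal accuracies (`modal_accuracy()`), and selection-frequency gene
ranks (`gene_frequencies()`, pooled over any number of fits). Modal ties
break deterministically: higher count, then class name, reject category
last; gene-rank ties break by gene id.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `chromosome_length` | 20 | genes per subset; the signature size |
| `population_size` | 300 | GA population |
| `max_generations` | 300 | GA budget per run |
| `stop_fitness` | 0.90 | early-stop training accuracy |
| `k_neighbors` | 5 | KNN neighbourhood |
| `n_runs` | 1000 | searches per partition |
| `train_fraction` | 0.75 | stratified split |
| mutation / crossover / elitism / tournament | 0.05 / 0.9 / 2 / 3 | variation operators |

The first six are the study design this package implements; the variation
operators are this package's own choices (the lineage method leaves them
open) and all ensemble-level properties — profile normalization, frequency
conservation, determinism, monotone best-ever fitness — are
operator-agnostic.

## The synthetic-data generator

`simulate_expression()` emulates the statistical structure the analysis
assumes, not the mechanics of RNA-seq: expression is Gaussian in log2 space
(`baseline_log_mean` 6, `noise_sd` 1 by default, i.e. raw values spanning a
few orders of magnitude), with `informative_per_class` genes per class
(disjoint across classes, up-shifts only) raised by `effect_size` log2
units in their class. Gender labels are drawn per class (default 60% male,
mirroring the imbalance of real pan-cancer cohorts), and a
`flagged_fraction` of genes (default 10%) stands in for a pseudogene
annotation, with half of each class's informative genes drawn from the
flagged set so that flag enrichment among top ranks is testable. The
defaults are the scaled-down study conditions used throughout the tests and
the acceptance script: 5 classes × 30 samples, 1,000 genes, 5 informative
genes per class at effect 2.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: count overdispersion and library-size effects (the
pipeline consumes normalized values, so no negative-binomial model is
attempted), correlated gene modules, batch effects, class-dependent noise,
down-regulated markers, or label noise. Recovery rates on planted signal
are an upper bound on what identically parameterized real data would give.

`simulate_cluster_dataset()` provides the subtype-discovery fixture: one
nominal class whose samples form `n_clusters` Gaussian clusters with
centroids a fixed Euclidean distance apart in log2 space.

## Numerical and design choices

- **Problem sizes.** The validation experiments run at desk scale: the
  planted-signal ensemble uses 50 runs of a (10-gene, population 50,
  ≤50 generations) search on a 150 × 1,000 dataset; the null-signal control
  uses 10 runs on 100 × 500. These sizes give stable pass/fail behaviour
  across seeds while keeping the whole suite in minutes.
- **Attainable fitness at small chromosomes.** Under the scaled-down
  conditions the 0.90 early-stop is rarely reached: with 10-gene subsets
  and five classes, even an oracle subset holding the two strongest planted
  genes per class achieves only ≈0.83 leave-one-out accuracy under the
  strict-majority reject rule (rejections count as errors). Runs therefore
  typically exhaust their generation budget around fitness 0.7–0.9 — and
  the *ensemble* still classifies ≥90% of held-out samples correctly by
  modal vote, which is the property that matters. This is a genuine feature
  of the method: individually mediocre near-optimal classifiers aggregate
  into an accurate and stable committee.
- **k-means.** `subtype_discovery()` uses `stats::kmeans` with 10 random
  restarts per candidate k (best within-cluster sum of squares kept) and
  selects k by *maximum* mean silhouette width on Euclidean distance in the
  filtered gene space. Ten random restarts serve the same robustness
  purpose as more elaborate seeding schemes, and the choice of initializer
  does not affect any tested property. Candidate k defaults to {2, 3}; the
  per-k scores are returned so any other selection rule can be applied by
  the user.
- **IQR filter.** Genes with zero interquartile range within the class are
  dropped before clustering; quartiles use R's default type-7 definition.
- **Exact rank-sum test.** `ranksum_test()` enumerates the null
  distribution over all $\binom{n_1+n_2}{n_1}$ assignments of the pooled
  (tied) ranks whenever both groups have ≤10 samples — unlike the usual
  shortcut, the exact branch handles ties — and reports
  $\min(1, 2\min(P(W \le w), P(W \ge w)))$. Larger groups use the normal
  approximation with tie and continuity corrections; the two branches agree
  to well under 0.01 at the crossover sizes.
- **Enrichment universe.** `hypergeom_enrichment()` takes the universe
  explicitly; the natural default in a pipeline is all genes in the
  dataset. Printed p-values from external studies depend on their
  (unstated) universes and are not comparable targets.
- **Rank comparisons** use full-table ranks for the difference column, so a
  gene outside one cohort's top-N (say rank 932) is still comparable to its
  rank in the other cohort.
- **Degenerate inputs.** Validation errors name the offending field, sample
  or class; a class with fewer than two samples cannot be split; a gene
  subset spanning the whole pool cannot be mutated and is returned
  unchanged; `max_generations = 0` returns the best of the initial
  population with `stopped_early = FALSE` (a stop at the final generation
  is by definition not early).

## Known limitations

- The GA offers no optimality guarantee — by design; the method's output is
  the *distribution* of near-optimal subsets, not a single optimum.
- Runtime scales as population × generations × runs × $n^2_{\text{train}}$;
  the compiled KNN kernel handles desk-scale data comfortably, but
  full-scale designs (300 × 300 × 1000 runs on ~7,000 training samples) are
  a cluster-scale computation.
- Profiles are frequencies over runs, not calibrated probabilities.
- The gender comparison utilities test expression differences gene by gene;
  they do not model confounding between gender and class composition —
  that is exactly what `matched_subsample()` is for, by equalizing class
  proportions before refitting.
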