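---
title: "Methods: graph-measure extraction, evolutionary subset search, and the LM-trained perceptron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-measure extraction, evolutionary subset search, and the LM-trained perceptron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

connselect implements a complete wrapper-selection pipeline for two-group
discrimination from resting-state functional-connectivity graph measures:
ROI time series are reduced to Fisher-z correlation matrices and binary
brain graphs, seven node-level graph measures become a high-dimensional
feature vector, and fixed-size feature subsets are searched by five
evolutionary algorithms (plus a Welch t-test filter baseline) with the
cross-validated accuracy of a small multilayer perceptron as the search
objective. This vignette documents the models, the conventions adopted at
every point where a convention had to be chosen, and what the synthetic
cohorts used in testing do and do not establish about real data.

## Connectivity model

For each subject we observe a $T \times N$ matrix of BOLD-like signals
(rows = timepoints, columns = ROIs). The pipeline steps are:

1. **Band-pass filtering** (`bandpass_filter()`): each ROI column is
   filtered to the canonical resting-state band 0.01–0.1 Hz and
   mean-centred. The filter is a 2nd-order Butterworth band-pass applied
   forward and backward (`signal::filtfilt`), i.e. zero-phase, so no
   lag is introduced into the correlation structure. Units: Hz, with the
   Nyquist frequency $1/(2\,\mathrm{dt})$ as the hard upper limit; the
   default sampling interval is $\mathrm{dt} = 3$ s (TR = 3000 ms).
2. **ROI-to-ROI correlation** (`roi_correlation()`): the Pearson
   correlation $r_{ij}$ between ROI columns. The diagonal is fixed at 0 —
   self-connectivity is meaningless downstream and a unit diagonal would
   otherwise dominate absolute thresholding.
3. **Fisher z-transform** (`fisher_z()`): $z = \tanh^{-1}(r)$, the
   variance-stabilising transform with standard error approximately
   $1/\sqrt{T-3}$. $|r|$ is clipped at $1 - 10^{-7}$ first, so perfectly
   correlated columns produce a large finite $z \approx 8.1$ rather than
   infinity; the distortion is negligible at any attainable sample size.
4. **Thresholding** (`threshold_adjacency()`): either an absolute rule
   ($A_{ij} = 1$ iff $z_{ij} > \theta$, one-sided on signed $z$ — e.g.
   $z > 0.5$) or a proportional rule that keeps exactly
   $\lceil d \cdot N(N-1)/2 \rceil$ strongest pairs (e.g. the highest
   10%). The default is proportional with density $d = 0.15$: a fixed
   edge budget makes graphs comparable across subjects regardless of
   overall correlation level, which is the property the downstream
   measures rely on. Ties are broken by $(i,j)$ lexicographic order so
   graphs are bit-reproducible. Negative correlations do not form edges
   under the signed rule; ranking by $|z|$ is available via `use_abs`.

## Graph measures

Seven node-level measures are computed on the binary undirected graph
(`compute_measure_set()`); shortest paths and betweenness come from
igraph, with the normalisations below applied by this package:

* degree centrality: $\deg(v)$, a count;
* betweenness centrality: $\sum_{s \ne t \ne v} \sigma_{st}(v)/\sigma_{st}$
  divided by $(N-1)(N-2)/2$, so it is the *proportion* of shortest paths
  through $v$, in $[0,1]$;
* average path length: the mean shortest-path distance from $v$ to the
  nodes *reachable* from it; an isolated node scores 0;
* clustering coefficient: the fraction of neighbour pairs of $v$ that are
  themselves adjacent; 0 when $\deg(v) < 2$;
* cost: $\deg(v)/(N-1)$, the node's share of its possible connections —
  the natural per-node restriction of network density, which is what a
  per-ROI feature requires;
* local efficiency: the global efficiency of the subgraph induced on the
  neighbours of $v$; 0 when $\deg(v) < 2$;
* global efficiency: $\frac{1}{N-1}\sum_{u \ne v} 1/d(v,u)$ with
  $1/\infty = 0$.

Unreachable pairs are handled without imputation: path-length means skip
them, efficiencies count them as 0. Every quantity is finite on every
graph, including the empty one. The test suite checks all seven measures
exactly against a from-scratch Floyd–Warshall / path-counting oracle on
all 64 labelled 4-node graphs and on random 5–8-node graphs across
densities — the regimes (isolates, disconnected components, degree < 2)
where the conventions actually bite.

## Feature assembly

`assemble_features()` concatenates, in order, the seven measures of every
atlas ROI node, of every brain-network node, and a global aggregate
defined as the per-measure arithmetic mean over the network nodes.
Feature names are `"<node>::<measure>"`. With the reference layout — 132
atlas ROIs, 32 network nodes in 8 networks, plus the global aggregate —
this yields $(132 + 32 + 1) \times 7 = 1155$ named features. One graph is
built over the union of the 164 nodes from a single connectivity matrix;
network-node measures are read from that shared topology rather than from
network-restricted subgraphs, keeping all features consistent with one
graph per subject. The alternative aggregate (mean over all 164 nodes) is
available via `global_over = "all"`.

## Classifier

The classifier (`init_mlp()`, `train_mlp()`) is a fixed small perceptron:
inputs → 10 tanh units → 10 tanh units → 1 logistic output. Targets are
coded 0/1, matching the bounded logistic output so the squared error is
bounded; predicted labels are 1 exactly when the score exceeds 0.5.

Training is Levenberg–Marquardt backpropagation on the summed squared
error $F(x) = e^\top e$, $e = y - a$: the error Jacobian
$J = \partial e / \partial x$ is assembled by propagating layer
sensitivities backward, and each step solves
$x \leftarrow x - (J^\top J + \mu I)^{-1} J^\top e$. The damping schedule
is the classical Marquardt recipe: $\mu_0 = 10^{-3}$, multiplied by 10
when a step fails to reduce $F$, divided by 10 on acceptance, capped at
$\mu_{\max} = 10^{10}$; training stops at 100 epochs, at gradient
infinity-norm $10^{-7}$, or when no acceptable step exists below
$\mu_{\max}$. Accepted steps never increase $F$, which the tests assert
on every recorded history. Weights initialise uniformly in $[-0.5, 0.5]$
from a seeded stream. The per-step linear algebra lives in C++
(RcppArmadillo); the Jacobian is verified against central finite
differences to $10^{-4}$ relative error in the tests.

## Wrapper fitness

`evaluate_fitness()` scores a candidate subset by restricting the feature
table to it, z-scoring each feature on the training portion only, and
running stratified cross-validation of the MLP (`cross_validate()`).
Folds preserve group proportions and the dealing pointer carries across
classes, so 140 subjects give ten folds of exactly 14; each fold is thus
a 90/10 train/validation split. Accuracy is reported in percent as the
fold mean (pooled accuracy is also recorded).

Two fitness modes exist. `mode = "split"` evaluates one stratified 90/10
split — cheap, but on cohorts of ~140 subjects a 14-subject validation
set quantises accuracy in steps of about 7 points and saturates at 100%
for many subsets, so it cannot rank good candidates. `mode = "cv"` runs
the full k-fold evaluation, and `repeats` averages over independently
drawn fold assignments. Because the search maximises a noisy estimate,
the selected subset's fitness is biased upward (winner's curse); the
experiment functions therefore re-evaluate the returned subset with an
independently seeded cross-validation. In our reference experiments the
search uses `mode = "cv", n_folds = 5, repeats = 2`: five folds with two
averaged assignments give 280 held-out predictions per evaluation at
half the training cost of repeated 10-fold, and averaging over
assignments roughly halves the selection noise, which measurably
improves how well the chosen subsets generalise. The fitness seed is
fixed per search run so that cached evaluations are consistent and
elitism is well defined.

## The subset searches

All searches use the published constants of each algorithm as defaults
(see `ea_config()`), operate on subsets of fixed cardinality $k$ via
repair operators, share a per-run evaluation cache, and are
bit-reproducible from `(seed, config, table)`. The iteration budget
defaults to 200 per run; independent restarts are exposed separately
(`accuracy_vs_k(repetitions = )`) rather than conflated with iterations.

* **GA** (`ga_select()`): population 20; Boltzmann roulette with
  selection probability $\propto \exp(\beta\, f_i / \max_j f_j)$ at
  pressure $\beta = 8$ — scaling by the best fitness keeps the pressure
  moderate and scale-free, where sharper normalisations (e.g. min–max)
  collapse the population onto the early best and measurably hurt the
  selected subsets' generalisation; 14 crossover offspring per
  generation from operators drawn uniformly among single-point,
  double-point and uniform mask crossover, repaired back to cardinality
  $k$; swap mutation (each selected bit exchanged with a random
  unselected bit with probability 0.1) applied to 30% of offspring;
  parents and offspring compete for the 20 survivor slots, so the best
  individual always survives.
* **NSGA-II** (`nsga2_select()`): objectives (maximise accuracy, minimise
  cardinality) with cardinality free in $[1, k_{\max}]$ — the pair of
  objectives that yields the accuracy-per-size front the per-k analyses
  need. Standard fast nondominated sorting, crowding-distance truncation
  and binary-tournament mating; population 25, mutation percentage 0.4 at
  per-bit rate 0.1.
* **ACO** (`aco_select()`): 10 ants sample $k$ features without
  replacement with probability $\propto \tau^\alpha \eta^\beta$
  ($\alpha = \beta = 1$); the heuristic information $\eta$ is the
  per-feature absolute Welch $t$ statistic — the pipeline's own filter
  baseline supplies the natural prior. Pheromone evaporates at 0.05 per
  iteration and the iteration-best ant deposits fitness-proportional
  pheromone.
* **SA** (`sa_select()`): neighbourhood = one selected/unselected swap;
  Metropolis acceptance $\exp(-\Delta/T)$ on accuracy-point losses;
  $T_0 = 10$ cooled by 0.99 per iteration; best-so-far returned.
* **PSO** (`pso_select()`): continuous positions over all features,
  inertia 0.72, cognitive and social coefficients 1.5; a particle's
  subset is its top-$k$ positions (ties by index) — a deterministic rank
  decoding that keeps cardinality exact without stochastic binarisation.
* **Statistical baseline** (`ttest_select()`): Welch t-test per feature,
  the $k$ smallest p-values win, ties by index; zero-variance features
  receive $p = 1$ and rank last.

On toy problems small enough to enumerate, each evolutionary search is
required (in tests across 10 seeds) to match the exhaustive optimum in at
least 80–90% of runs.

## Synthetic cohorts

`generate_feature_cohort()` plants `n_informative` features whose group-1
mean is shifted by `effect` standard deviations against Gaussian noise;
`generate_timeseries_cohort()` plants a block of ROIs whose within-block
correlation is $\rho_0$ in group 0 and $\rho_0 + \Delta\rho$ in group 1,
sampling each subject's $T \times N$ series from the corresponding
Gaussian. Default group sizes are 72 and 68 — a realistic two-arm
clinical cohort — with $T = 140$ timepoints at $\mathrm{dt} = 3$ s.

The generators emulate exactly what the downstream stages consume:
group-dependent mean shifts at the feature level, and group-dependent
covariance (hence connectivity, hence graph structure) at the time-series
level. They deliberately do not model haemodynamic spectra, motion or
physiological artefacts, scanner drift, or site effects. Passing tests on
these cohorts therefore establish that the machinery recovers known
structure at realistic sample sizes and noise levels — not that any
particular accuracy level will transfer to clinical data, where effect
sizes are smaller, features are correlated in more complicated ways, and
preprocessing quality dominates.

## Reference experiment scale

The packaged acceptance analysis (`scripts/acceptance.R`) uses a
feature-level cohort of 70 + 70 subjects with 10 informative features of
effect 1.5 among 200, runs the GA at its published constants for 50
generations with the 5-fold, 2-repeat `cv`-mode fitness, and re-scores the
returned 10-feature subset with an independently seeded stratified
10-fold cross-validation of the default-configuration MLP, averaging over
5 master seeds. These sizes were chosen so the full analysis is a
desk-scale computation; the same functions scale to the 1155-feature,
$k$ up to 500 setting by changing arguments.

The test suite exercises smaller instances of the same machinery
(cohorts of 24–140 subjects, 4–200 features, search budgets of 5–200
iterations) plus the exact oracle comparisons described above.

## Known limitations

* The LM step solves a dense $(p \times p)$ system; with the fixed 10-10
  architecture $p = 10\,n_{in} + 131$, fine for wrapper-scale subsets
  ($k \le$ a few hundred) but not for training on all 1155 features at
  once — which the wrapper design never does.
* Fitness caching keys on the subset only; it assumes the fitness seed is
  fixed within a run (enforced by the engines).
* The proportional threshold guarantees the edge *count*; on matrices
  with ties at the cut the deterministic tie-break selects a specific,
  reproducible set of edges rather than a random one.
* NSGA-II's archive reports the best subset per cardinality from the
  final population; it is not an any-time archive of every nondominated
  point ever visited.
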