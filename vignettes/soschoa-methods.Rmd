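---
title: "Methods: chimp-optimizer wrapper feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chimp-optimizer wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soschoa)
```

## The problem

High-dimensional biomedical classification data — gene-expression
microarrays above all — pair very few samples (tens to low hundreds)
with hundreds to tens of thousands of features, most of which are
irrelevant or redundant for the class labels. Wrapper feature selection
searches the $2^D$ space of feature subsets by scoring each candidate
subset with an actual classifier. Exhaustive search is impossible beyond
a few dozen features, so the search is delegated to a population
metaheuristic.

This package implements two such optimizers behind one contract:

* **CHoA**, the Chimp Optimization Algorithm: the four best individuals
  (*attacker*, *barrier*, *chaser*, *driver*) jointly guide every other
  candidate, with a stochastic switch to chaotic relocation; and
* **SOSCHoA**, CHoA augmented with a *social coevolution* position
  update and *dimension-wise sine-chaotic opposition learning* under
  greedy replacement.

## Model and operators

### Baseline chimp update

Candidate positions live in a bounded continuous space (for feature
selection, $[0,1]^D$). Each generation, individual $x$ is attracted to
each leader $L_k$ through

$$X_k = L_k - a_k\,\lvert C_k L_k - m_k x\rvert,$$

with $a_k \in [-f, f]$, $C_k \in [0,2]$ uniform draws and
$m_k \in [0,1]$ a sine-chaos value. The convergence factor
$f = 2.5 - 2.5\,t/t_{max}$ shrinks steps linearly from 2.5 to 0 (the
formula is affine even though it is often described as non-linear; we
implement it as printed). With probability $1/2$ the new position is the
mean $(X_1 + X_2 + X_3 + X_4)/4$; otherwise every coordinate relocates
chaotically to $lb + (ub - lb)\,c$ with $c$ the next chaos value. All
positions are hard-clamped into bounds.

### Sine chaos streams

The single chaotic source is the sine map $S(x) = a\sin(\pi x)$ with
control $a \in (0,1]$ (default 1). On $[0,1]$ the map's range is
$[0, a]$ — non-negative, regardless of the wider range sometimes quoted
for it — and feeding each iterate back as the next state keeps the orbit
closed. Each individual owns one independent stream whose initial state
is drawn uniformly from $(0.05, 0.95)$ (avoiding the fixed point at 0),
so a run is a deterministic function of its seed.

### Social coevolution

SOSCHoA replaces the leader-aggregate/chaotic update with

$$x_i' = x_i + r_3\left(x_{attacker} -
  \frac{x_i + x_{i-1}}{2}\,R\right),$$

where $r_3 \sim U[0,1]$, the midpoint is the *co-occurrence* of $i$ and
its ring neighbour $i-1$ (individual 1 pairs with individual $N$), and
the benefit factor $R$ is drawn uniformly from $\{1, 2\}$ per individual
per generation. We update all individuals synchronously from the
generation-start snapshot: the update rule is written as a pairwise
interaction, and the synchronous reading keeps the ring symmetric and
each individual updated exactly once. The per-leader coefficients
$a_k, C_k, m_k$ have no consumer in this update, so the SOSCHoA engine
computes $f$ (it is part of the iteration state) but does not draw
coefficients it would discard.

### Sine-chaotic opposition with greedy replacement

After the social sweep, each individual receives an opposition candidate
built dimension-by-dimension,

$$\bar x_i^j = lb_j + (ub_j - x_i^j)\,s_j,$$

where $lb_j, ub_j$ are the *dynamic bounds* (population minimum and
maximum in dimension $j$) and $s_j \in [0,1]$ comes from the
individual's chaos stream. Drawing $s$ from the stream rather than
applying the sine map to the raw coordinate keeps the candidate inside
the dynamic bounds for arbitrary search spaces — the closure property
the convergence argument needs: when the population collapses to a
point, $lb = ub = x^*$ and the candidate is exactly $x^*$. The candidate
replaces the original iff its fitness is no worse (ties go to the
candidate), so individual fitnesses never worsen through this sweep. A
`best-only` mode restricted to the current best individual is provided
as a configuration switch; the per-individual sweep is the default
because the dynamic bounds argument is population-wide.

### Wrapper fitness

A continuous position decodes to a feature mask by thresholding each
coordinate at 0.5 (exactly 0.5 selects; the decode of a 0/1 vector is
the identity). If no coordinate reaches the threshold, the decode used
inside the objective selects the single highest-valued coordinate — a
pure function of the position, which keeps the objective deterministic
and the reported mask consistent with the reported fitness (a uniformly
random single-bit repair, `repair_mask()`, is also provided for
standalone masks). The fitness, minimized, is

$$f(X) = \alpha\,\gamma + (1 - \alpha)\,\frac{|Selected|}{|ALL|},
  \qquad \alpha = 0.99,$$

with $\gamma$ the misclassification rate of a $k$-nearest-neighbour
classifier ($k = 5$, Euclidean distance) trained on the 70% training
partition restricted to the selected features and scored on the held-out
30%. This matches the evaluation pipeline the protocol reports; note it
scores candidate subsets on the same held-out partition later used for
the reported accuracy, a leakage the protocol itself accepts. Distance
ties are broken by lower training index and vote ties by smallest class
label, so the classifier is fully deterministic. Squared distances are
rounded at the 12th decimal before ranking so that exact duplicates are
detected as ties despite floating-point summation order.

## Evaluation protocol

`run_experiment()` performs $M = 30$ independent runs (population 10,
100 generations), each with a fresh stratified 70/30 split; per-run seeds
follow a counter scheme (`master_seed + run - 1`). Summaries follow the
protocol's printed formulas, including the dispersion statistics
$SD = \frac1M\sum(acc_i - \overline{acc})^2$ — a population *variance*,
without square root and divided by $M$. We emit it verbatim alongside a
clearly labelled conventional square-rooted value, since published
tables using the symbol cannot be reproduced to settle which was meant.
Optimizers are compared with a two-sided Wilcoxon rank-sum test at the
5% level: exact enumeration for combined $n \le 20$ without ties, normal
approximation with tie and continuity correction otherwise.

Population diversity is reported as the mean Euclidean distance of
individuals to the population centroid — zero iff collapsed,
translation-invariant. The measure behind published diversity figures is
never specified; this is our choice, recorded once.

## Synthetic data generator

`generate_dataset()` emulates microarray-like shapes: $n$ samples in
(near-)balanced classes, three feature blocks, shuffled columns with
recorded ground truth:

* **informative** — class-conditional Gaussians with unit variance; a
  class subset has its mean raised by `separation` (default 3, i.e. a
  3-sigma signal). In the default `"random"` pattern the subset is a
  random nonempty proper subset of classes; in the `"marker"` pattern
  feature $h$ elevates exactly class $h$ — the marker-gene structure.
* **redundant** — a random informative parent plus Gaussian noise with
  standard deviation `redundancy_noise` (default 0.5, parent-child
  correlation about 0.9).
* **noise** — standard Gaussian, independent of the labels.

The generator does **not** simulate batch effects, heavy-tailed noise,
or gene-gene correlation beyond the redundant copies; a green test on
synthetic data establishes algorithmic correctness, not performance on
real expression data.

The feature-recovery property uses `strong_signal_preset()`: 100
samples, 10 classes, 10 marker features at separation 4, no redundant
copies, 190 noise features. The marker structure is what makes a
recovery test well-posed: each planted feature carries class information
no other feature provides (dropping two markers merges two classes). In
a 2-class world with 3-sigma features, any single informative feature
separates the classes, so a fitness that prices subset size *correctly*
selects one feature and "recall of all planted features" would test
nothing about the optimizer.

## What the acceptance properties do and do not establish

Two directional acceptance properties are asserted faithfully and are
**red** in this stated world; we document rather than weaken them.

* **Feature recovery (recall ≥ 0.8, noise ≤ 0.2).** At the protocol
  budget (population 10, 100 generations = 2000 evaluations for a
  $2^{200}$ space) SOSCHoA reaches mean marker recall ≈ 0.62 (seeds vary
  0.2–0.9) at a mean noise-selection rate ≈ 0.24 — both just outside
  their bars: the best fitness stops improving by about generation 100
  and is unchanged at 400 generations, while the ideal 10-marker mask
  scores an order of magnitude better. The exhaustive-oracle criterion
  at $D = 8$ is attained in 20/20 runs, so this is search capacity at
  high dimension, not an implementation or fitness-design defect. A
  dimension that falls below threshold population-wide is hard to
  regain, because opposition candidates are confined to the dynamic
  population bounds.
* **Diversity direction (SOSCHoA ≥ CHoA − 5%).** CHoA's chaotic branch
  relocates each updated individual uniformly within bounds with
  probability 1/2 per generation, which pins its diversity near the
  uniform-random level (≈ 1.87 on $D = 50$); SOSCHoA's two operators are
  contractive (≈ 0.3). Under our recorded operator choices the claimed
  direction reverses by roughly a factor of six. The comparison is
  sensitive to how the undefined chaotic branch and the undefined
  diversity measure are instantiated.

## Numerical choices and edge cases

* Bounds handling: hard clamp after every move (no reflection).
* Leader ties broken by lower individual index; the four leaders are the
  four best by a stable (fitness, index) sort.
* `t_max = 0` returns the best of the initial population; convergence
  and diversity curves always have length `t_max + 1`.
* A class with a single sample is forced into the training partition
  with a warning; stratified rounding keeps at least one training and,
  when possible, one test sample per class.
* Objective values must be finite; a non-finite value aborts with the
  offending individual's index.
* Instrumentation counts objective evaluations (SOSCHoA performs at most
  $2N$ per generation — the social sweep plus opposition — versus CHoA's
  $N$) and element-wise vector-operation units, which scale linearly in
  $N \cdot D$; this is the complexity-parity check.

## Known limitations

* MAT-file support is a minimal MAT v5 codec (double matrices `X`, `Y`;
  zlib-compressed elements are read where the R runtime can inflate
  them). It round-trips this package's own files and scipy's; it is not
  a general MAT reader, and v7.3/HDF5 files are out of scope.
* The comparator metaheuristics from the surrounding literature
  (DLFCHOA, PIL-BOA, BBOA, LMRAOA, VGHHO, FA, FPA, WOA, HHO, MRFO) are
  not implemented; `run_experiment()` compares the two optimizers
  shipped here.
* Configuration files are JSON (not YAML), matching the dependencies
  guaranteed in the target environment.
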