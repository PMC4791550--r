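---
title: "Methods: CTBN network inference from time-course expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CTBN network inference from time-course expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctbnflow)
```

## The model

A continuous-time Bayesian network (CTBN) factors a joint continuous-time
Markov process over discrete variables. Here each variable is a gene in one
of three states — 0 (down-regulated relative to control), 1 (unchanged), 2
(up-regulated) — and its dynamics are governed by one conditional intensity
matrix (CIM) per joint configuration $u$ of its parent genes. A CIM row for
state $x$ has off-diagonal entries $q_{x \to x' \mid u} \ge 0$ in units of
1/h and diagonal $-q_{x \mid u}$ with $q_{x \mid u} = \sum_{x' \ne x}
q_{x \to x' \mid u}$: the gene dwells in $x$ for an Exponential($q_{x \mid
u}$) time, then jumps to $x'$ with probability $\theta_{x \to x' \mid u} =
q_{x \to x' \mid u} / q_{x \mid u}$.

Two modelling properties matter for expression time courses. First, time is
explicit, so unevenly spaced sampling designs need no imputation onto a
regular grid. Second, unlike static Bayesian networks, CTBN structures may
contain cycles (including feedback loops), because the score decomposes
over *families* (a variable plus its parent set) with no acyclicity
constraint.

## Evidence, sufficient statistics, and the family score

Fully observed trajectories enter the likelihood only through the
sufficient statistics of each family: dwell times $T[x; u]$ (hours spent in
state $x$ while the parents sat in configuration $u$) and transition counts
$M[x, x'; u]$, with row totals $M[x; u] = \sum_{x'} M[x, x'; u]$. A
transition is attributed to the parent configuration in force immediately
before it; dwell is stratified segment by segment, so a parent change mid-dwell
splits the dwell between configurations. Trajectories pool additively,
which is how replicates contribute.

With conjugate priors — each leave intensity $q_{x|u} \sim$
Gamma(shape $\alpha + 1$, rate $\tau$) and each jump row $\theta_{x|u}
\sim$ Dirichlet($\alpha, \ldots, \alpha$) over its $k - 1$ targets — the
parameters integrate out in closed form and the family log marginal
likelihood is

$$
\ln ML_q = \sum_{u,x} \Big[ \ln\Gamma(\alpha + M[x;u] + 1) - \ln\Gamma(\alpha + 1)
  + (\alpha + 1)\ln\tau - (\alpha + M[x;u] + 1)\ln(\tau + T[x;u]) \Big]
$$
$$
\ln ML_\theta = \sum_{u,x} \Big[ \ln\Gamma(\alpha(k-1)) - \ln\Gamma(\alpha(k-1) + M[x;u])
  + \sum_{x' \ne x} \big( \ln\Gamma(\alpha + M[x,x';u]) - \ln\Gamma(\alpha) \big) \Big].
$$

With no data every term cancels and the score is exactly 0. The test suite
verifies the closed form against Monte-Carlo integration of the likelihood
over the priors; because the tiny Dirichlet concentration ($\alpha = 0.01$)
makes naive prior sampling degenerate when a row has counts on more than
one target, the oracle uses a uniform importance proposal for those rows
(bounded weights) and prior sampling otherwise.

**Hyperparameter convention.** The reference settings are scalar $\alpha =
0.01$ and $\tau = 5$ h. Scalars under-determine the prior layout, so this
package applies $\alpha$ per dwell cell (Gamma shape $\alpha + 1$, rate
$\tau$) and per transition cell (Dirichlet pseudo-count $\alpha$, hence
row total $\alpha(k-1)$) — the uniform reading of scalar hyperparameters.
The convention is isolated in `learn_config()` and
`family_log_score()`; an equivalent-sample-size reading would change only
those two places.

## Structure search

Each variable's parent set is optimized independently. Greedy
hill-climbing starts from the empty set and repeatedly applies the single
add-or-remove-parent move with the largest strictly positive gain, stopping
at a local optimum or at the in-degree cap (`max_parents`, default 5).
Determinism is part of the contract: candidate moves are scanned additions
first, then removals, each in variable-index order, and only a strictly
larger gain displaces the incumbent, so ties resolve to the earliest
candidate. There are no random restarts; given the same trajectories and
configuration the learned structure is identical on every run.

`exhaustive_structure_search()` enumerates all parent sets up to the cap
and is the exact oracle used in testing; it refuses search spaces beyond a
configured number of candidate families. The structure prior is uniform
(omitted from the score). Posterior-mean parameters for any family are
$\hat q_{x|u} = (\alpha + M[x;u] + 1)/(\tau + T[x;u])$ and
$\hat\theta_{x \to x'|u} = (\alpha + M[x,x';u])/(\alpha(k-1) + M[x;u])$;
cells never visited fall back to the prior mean
($\hat q = (\alpha+1)/\tau = 0.202$/h at the defaults).

## From sparse observations to trajectories

Microarray sampling observes each replicate's state vector at grid times
only. The package uses the simplest convention consistent with
fully-observed CTBN learning: the state observed at $t_i$ is held on
$[t_i, t_{i+1})$; if the next observation differs, the transition is placed
at $t_{i+1}$; the final observation contributes zero dwell (absorbed by the
prior — no special-casing). Replicates become independent trajectories
whose sufficient statistics pool. This convention is load-bearing: it
shapes every dwell and count, and with 10 observations it can place
transitions tens of hours from their true instant, and simultaneous
multi-gene changes between consecutive observations are recorded at the
same timestamp. Partially-observed CTBN inference (EM or sampling over
hidden paths) would treat the grid correctly but is deliberately out of
scope.

## The synthetic generator

The generator emulates the target study design: a 10-point grid over 72 h
(default $\{0, 0.5, 1, 2, 4, 6, 12, 24, 48, 72\}$ h — the true design is
stated only as "unevenly distributed", so this default is a stand-in
chosen to be uneven, 10-point and 72 h-spanning, and is fully
configurable), three replicates, and case/control arms. Ground truth is a
random CTBN over `n_genes` 3-state genes with at most `max_true_parents`
parents each. Trajectories are simulated exactly (Gillespie): exponential
race over current leave intensities, one variable changes per jump.

Parameter choices, made once on domain grounds:

* `rate_scale = 0.25`/h — mean sojourn 4 h, so a 72 h course sees several
  regime changes per gene, comparable to expression kinetics that motivate
  dense early sampling.
* `parent_effect = 3` — each parent multiplies the child's leave rates by
  `parent_effect` raised to the parent's centered state ($-1, 0, +1$ for 3
  states), i.e. up to a 9-fold swing per parent. Arcs therefore modulate
  dwell-time distributions and are identifiable from the $ML_q$ part of the
  score. A per-gene, per-state jitter (uniform in $[0.7, 1.3]$) breaks
  symmetry. The jump distribution is uniform over the other states.
* `level_map = (-2, 0, +2)` — state centers two bin-widths apart, so
  discretization at $\pm 1$ is unambiguous at zero noise and the zero-noise
  round trip is exact.
* `noise_sd = 0.2` log2 units — typical replicate-level microarray noise.
* Initial state is the middle bin: at $t = 0$ case and control are the same
  cells, so fold change starts at 0.
* Case expression = per-gene baseline (uniform in $[7, 9]$ log2 units) +
  `level_map[state]` + Gaussian noise; control = baseline + noise. Null
  genes omit the state term in both arms; undetected probes get detection
  p-values from Uniform(0.5, 1) (all others Uniform(0, 0.01)).

What the generator does **not** emulate: probe-level physics (background,
hybridization), batch effects, dropout, probe-to-gene many-to-one mappings,
and regulation mechanisms other than dwell-rate modulation (e.g. purely
jump-directional control). Passing the synthetic validation therefore
demonstrates correctness of the machinery and identifiability under the
stated noise model, not performance on real arrays.

## Preprocessing decisions

* **Detection filter direction.** The source description reads as if
  probes with detection p < 0.05 were *discarded*, which would keep only
  background probes; standard Illumina practice keeps them. The default
  retains probes detected (p < `detection_p_max`) in at least half the
  samples; `literal_detection = TRUE` gives the literal reading.
* **Normalization.** "log2 normalized" is ambiguous; quantile
  normalization between arrays (via limma) is the common microarray choice
  and the `"quantile"` method. The generator emits data already on a
  comparable log2 scale, so the pipeline default is `"none"`; quantile
  normalization of zero-noise synthetic arrays would actually distort fold
  changes, since case arrays legitimately differ in distribution.
* **Differential expression.** A plain Welch two-sample t-test per gene per
  time point stands in for limma's moderated t-test; empirical-Bayes
  variance moderation is a declared non-goal. The substitution preserves
  the selection semantics (per-time significance + fold-change
  conjunction). Degenerate convention: both groups constant and equal
  gives p = 1; both constant and different gives p = 0.
* **BH scope.** Adjusted within each time point, matching per-time-point
  testing; `bh_scope = "global"` is available.
* **Fold change.** Each case replicate against the mean of control
  replicates at the matched time (per-replicate pairing is not defined by
  the design).
* **Replicates.** Kept as separate discretized series, becoming separate
  trajectories; pooling happens in the sufficient statistics, not by
  averaging profiles.
* **Bins.** State 0 iff FC $\le -1$, state 2 iff FC $\ge +1$ (both outer
  bins closed), state 1 between; NaN fold changes are hard errors naming
  the gene and time.

A consequence worth stating: at zero noise, a gene is selected exactly when
its replicates *unanimously* occupy a non-middle state at some time point —
a replicate-mean fold change above 1 with replicate disagreement leaves too
much within-group variance for a 3-vs-3 t-test. The acceptance suite
asserts this exact characterization.

## Network interpretation

`build_graph()` turns parent sets into a directed graph (self-loops
impossible by construction, duplicates collapsed with a warning).
"Hub" is formalized as out-degree rank (descending, ties by gene id);
"root" as out-degree $\ge 1$ with in-degree 0, "leaf" the reverse,
"intermediate" both, "isolated" neither. A node can be the top hub without
being a root; both facts are reported separately.
`extract_subnetwork()` implements the neighborhood reading of subnetwork
figures: the induced subgraph on seed genes plus all nodes within a given
arc radius in either direction, with attributes recomputed.
`evaluate_structure()` scores directed arcs (precision, recall, F1) with
explicit degenerate conventions: empty truth $\Rightarrow$ recall 1, empty
inference $\Rightarrow$ precision 1, F1 = 0 when undefined.

## Pipeline reproducibility

`run_pipeline()` derives one sub-seed per stage from the master seed, so
changing the generator's randomness does not perturb anything downstream
that draws its own. Manifests record the config hash, seed, derived
seeds and per-stage counts — never timestamps — so a fixed (config, seed)
pair reproduces every output file byte for byte. Stage failures abort with
the stage name. Counts of probes and genes removed per filter are logged at
each stage.

## Validation problem sizes

The test and acceptance suites size their problems to be decisive yet
quick: 20 random small-statistics instances at $10^6$ Monte-Carlo draws for
the score oracle; 30 random 4-node, 2-state datasets for greedy-vs-
exhaustive; an 8-node, 3-state, $\le 2$-parent ground truth with 200
fully-observed 72 h trajectories for structure recovery, subset to
$\{3, 25, 100, 200\}$ trajectories (paired, nested) for the data-scaling
check; 100 random p-vectors for the Benjamini–Hochberg cross-check; and a
10-gene end-to-end run executed twice for byte-level determinism.

## Known limitations

* The hold-forward observation convention biases transition times late and
  can merge fast successive transitions; with 10 observations per replicate
  the learner sees weak evidence, and arcs learned in that regime should be
  read as hypotheses for follow-up, not reconstructions.
* The Welch test with 3-vs-3 replicates is conservative relative to a
  moderated test; borderline genes that variance moderation would rescue
  are dropped.
* Greedy hill-climbing returns a local optimum; on small random instances
  it attains the exhaustive optimum in most but not all cases (the
  acceptance run reports the observed agreement rate).
* The score's prior-allocation convention for scalar $\alpha, \tau$ is one
  of several defensible readings; conclusions that hinge on absolute score
  values (rather than rankings under a fixed convention) should not be
  drawn.
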