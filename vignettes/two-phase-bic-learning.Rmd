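---
title: "Two-phase BIC structure learning: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase BIC structure learning: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twophasebn)
```

## The model

A Bayesian network over variables $X_1,\dots,X_p$ is a directed acyclic
graph (DAG) together with one conditional distribution per node, and the
joint density factorizes as
$P(X) = \prod_i P(X_i \mid \mathrm{pa}(X_i))$.
`twophasebn` supports three node families, which jointly cover continuous,
discrete and mixed networks:

* **linear-Gaussian** — a continuous child with continuous parents,
  $X_i = \beta_0 + \sum_j \beta_{ji} X_j + \varepsilon_i$,
  $\varepsilon_i \sim N(0,\sigma_i^2)$;
* **multinomial** — a discrete child with discrete parents, one
  probability row per parent configuration;
* **conditional-Gaussian** — a continuous child with at least one
  discrete parent: slopes on the continuous parents are shared while the
  intercept varies with the discrete-parent configuration, so the child is
  marginally a Gaussian mixture.

A discrete child never has a continuous parent (`typed_dag` enforces
this), the standard restriction that keeps mixed networks in the
conditional-Gaussian family.

## Scoring

Structures are ranked by the decomposable BIC in the *maximized-score*
convention,
$$\mathrm{bic}(i \mid \mathrm{pa}_i) = \hat\ell_i - \tfrac{k_i}{2}\log n,$$
summed over nodes.  One convention is used everywhere; mixing it with the
$-2\ell + k\log n$ form is the classic sign bug, and the identity
`bic == loglik - k/2 * log(n)` is asserted in the unit tests.  Free
parameters: $k = |\mathrm{pa}| + 2$ for Gaussian families (coefficients,
intercept, variance), $k = (L-1)\prod_j L_j$ for a CPT, and
$k = \#\text{continuous parents} + \#\text{observed configurations} + 1$
for conditional-Gaussian families.

Parameter estimation is MLE for Gaussian families and a symmetric
Dirichlet($\alpha$) posterior mean (default $\alpha = 1$) for CPT rows —
a prior-regularized estimate keeps rarely observed configurations from
producing $-\infty$ log-likelihoods at small $n$.  A Gaussian
coefficient prior would add a scale hyperparameter with no obvious
default, so it was deliberately left out; $\alpha$ is exposed.

Gaussian family scores are computed from the precomputed Gram matrix
$[1,X]^\top[1,X]$ of the continuous block, which makes one family score
$O(|\mathrm{pa}|^3)$ *independent of* $n$.  That is what makes exhaustive
parent-set enumeration affordable: at $p = 20$, `max_parents = 4`, the
5\,036 subsets per node all get scored in well under a second.

Degenerate families (zero residual variance, e.g. a child that is an
exact linear copy) are flagged and excluded from every candidate
ranking via a sentinel; the mandatory empty-parent family of a constant
column is floored at a tiny variance instead, so each node always has a
finite fallback family.

## The two-phase learner

**Phase 1** (`enumerate_families`) scores *every* type-admissible parent
subset up to `max_parents` per node — no heuristic pruning — and keeps
the `candidates_per_node` best (default 20), ranked by BIC with ties
broken by smaller parent set, then lexicographic parent names.  The
empty family is always retained, which guarantees the assembler can
break any cycle.  When $\binom{p-1}{\le m}$ exceeds `subset_budget`, a
staged scheme scores all subsets of size $\le 2$ and then extends only
the current top families one parent at a time; the result is flagged
`staged` and exactness is no longer claimed.

**Phase 2** combines one family per node into an acyclic graph
maximizing the global BIC.  Two assemblers are provided:

* `exact_dp` — the classic subset dynamic program over node sets,
  $\mathrm{best}(S) = \max_{v \in S}\,\mathrm{best}(S\setminus v) +
  g_v(S \setminus v)$, with $g_v(A)$ (the best family of $v$ inside
  $A$) computed for all $A$ by a subset zeta transform in compiled code.
  This is exact but exponential; it is limited to $p \le 20$
  (about 160 MB of tables and a few seconds at $p = 20$).
* `greedy_repair` — starts from each node's top family and repairs
  directed cycles by the cheapest demotion: within the first cycle
  found, the node whose next-ranked family dropping the offending
  parent costs the least global BIC is demoted (ties by node name).
  Repair alone turned out to discard large amounts of score — ranked
  lists are dominated by families full of children and Markov-blanket
  spouses, so demotions cascade — and is therefore followed by a
  monotone ascent on the full table of families scored in phase 1:
  node re-selection sweeps (each node takes its best family among its
  non-descendants), edge-reversal sweeps (a paired two-family change),
  and an iterated local search over topological orders (greedy adjacent
  transpositions, restarted from seeded perturbations of the incumbent
  order, `restarts` = 50 by default).  Every accepted move strictly
  increases the global BIC, so the ascent terminates.

The default `assembler = "auto"` uses the exact program up to 20 nodes
and the greedy heuristic beyond.  On 6-node instances the greedy
assembler matches the exact optimum in well over 80% of cases and can
never exceed it, which the test suite checks explicitly.

`learn()` reports edge weights: the fitted regression coefficient for a
continuous parent of a continuous child, and the family's BIC gain over
the empty family for edges involving discrete variables.

A classic hill-climbing learner over single-edge moves
(`hill_climb_baseline`) is included as the in-package baseline for
benchmark comparisons.

## The simulator

`simulate_instance()` reproduces the linear structural equation model
design the benchmarking protocol prescribes:

| parameter | default | meaning |
|---|---|---|
| `mean_parents` | 1.5 | expected in-degree of the random topology |
| `beta_mean`, `beta_sd` | 2, 0.8 | $|\beta| \sim N(2, 0.8)$, per structural coefficient |
| `sign_prob` | 0.5 | probability a coefficient is positive (Bernoulli sign) |
| `sigma2_mean`, `sigma2_sd` | 1, 0.01 | residual variance $\sim N(1, 0.01)$, truncated at $10^{-3}$ |
| `levels_set` | \{2, 3\} | discrete level counts, drawn uniformly per node |
| `max_discrete_parents` | 3 | in-degree cap for discrete children |
| `shuffle_columns` | on | seeded permutation of the dataset's column order |

Design notes, in order of how often they matter:

* The spread arguments are read as **standard deviations** by default;
  `second_arg = "var"` switches the interpretation, since distribution
  notation of the form $N(a, b)$ is ambiguous.
* The sign is applied to $|\beta|$, so `sign_prob` is *exactly* the
  probability of a positive coefficient.
* Truncating $\sigma^2$ at $10^{-3}$ turns positivity from an event of
  probability $\approx 1 - 10^{-23}$ into an invariant.
* Random topology: a uniformly random order over the nodes, each forward
  pair included with probability $2m/(p-1)$.  This hits the expected
  in-degree $m$ exactly, but in-degrees are heterogeneous — a node late
  in the order has $\mathrm{Binomial}(p-1, 2m/(p-1))$ parents, so at
  $p = 20$, $m = 1.5$ roughly a quarter of instances contain a node
  with five or more true parents.  See *Limitations*.
* Scale-free topology grows by preferential attachment with edges
  oriented old→new (acyclic by construction) and is restricted to
  continuous networks: a hub's unbounded in-degree would blow up a
  discrete child's CPT.
* CPT rows are Dirichlet(1) draws, re-drawn one offending row at a time
  until every pair of configurations differing in a single parent level
  is at total-variation distance $\ge 0.1$ — the operational meaning of
  "every parent genuinely moves the child".  Whole-table rejection was
  rejected: for three ternary parents its acceptance probability is
  about $0.8^{81}$, while row-wise repair converges in a handful of
  draws.
* Purely continuous families have intercept 0 (the structural equation
  has no intercept term); conditional-Gaussian children draw one
  intercept per discrete configuration from the same signed-magnitude
  law as $\beta$.
* Column shuffling exists because some learners are sensitive to the
  variable order on disk; the stored permutation lets tests verify the
  learned structure is identical after name alignment.

What the simulator does **not** emulate: nonlinear or non-Gaussian
mechanisms, interventions, missing data, measurement error,
hidden confounders.  A green test suite therefore says the learner
recovers *linear-SEM* structure under these noise levels — nothing about
robustness to model misspecification on real data.

## Evaluation protocol

`compare_structures` uses the strict directed convention: a learned edge
is a true positive only with matching direction; a reversed true edge is
a false positive *and* leaves its true counterpart a false negative.  The
false-positive rate divides by all ordered non-true pairs,
$p(p-1) - |E_{\mathrm{true}}|$ (the "nondirected relations"
denominator is stated here so results are interpretable either way).
`run_benchmark` records per-replicate metrics, per-setting medians and
IQRs, and a paired two-sided $t$-test matrix between learners; raw
p-values are reported (matching the protocol) with a Holm-adjusted
column alongside.  `paired_t_test` flags zero-variance difference
vectors instead of erroring.

## Numerical and determinism choices

* Node names sort lexicographically everywhere determinism is promised;
  the scoring context reorders columns by name on entry, so every result
  is exactly invariant to the column order of the input file.
* Ranking ties: higher BIC, then fewer parents, then lexicographic
  parent names.  Ascent moves require an improvement of more than
  $10^{-9}$, so exact ties never cause churn.
* All randomness flows through integer seeds; one user seed is split
  into independent streams (topology, parameters, sampling, shuffle,
  assembler restarts) by a deterministic mixing function
  (`derive_seed`), and the same seed reproduces any artifact
  bit-identically.
* Rank-deficient Gaussian designs fall back to a pseudoinverse fit and
  are flagged; conditional-Gaussian configurations with fewer rows than
  continuous parents + 1 are merged into a pooled intercept group and
  flagged.

## Problem sizes used by the test and acceptance suites

The packaged tests run the full pipeline at $p \le 20$, $n \le 10\,000$:
the headline protocol (10 replicates of $p = 20$, $n = 1000$ continuous
random networks), brute-force cross-checks on all 543 labeled 4-node
DAGs and all $25^2$ 3-node truth/learned pairs, and Monte-Carlo checks
with 40–400 replicates elsewhere.  These sizes keep the whole suite in
the minutes range on a single core while leaving every claim
computation-backed.

## Limitations

* **Score equivalence.** With MLE-fit Gaussian families, Markov
  equivalent DAGs score *identically*; edge directions inside an
  equivalence class are exact ties, so only compelled edges (those
  fixed by v-structures) are reliably oriented.  Directed-edge metrics
  therefore have a model-intrinsic ceiling below 1 even with unlimited
  data.
* **Parent-cap misspecification.** With `max_parents = 4` and the
  heterogeneous in-degrees of the random topology, instances containing
  a node with more true parents than the cap make the BIC optimum
  provably different from the generating graph — the learner finds
  structures that *out-score* the cap-restricted truth.  Raising
  `max_parents` trades enumeration cost for fidelity.
* `exact_dp` is exponential and refuses $p > 20$; beyond that the
  greedy assembler's ascent is a heuristic with seeded restarts, and
  recovering the exact optimum is not guaranteed.
* Staged enumeration (very large $p$) is explicitly approximate.
* Missing data are rejected, not imputed.
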