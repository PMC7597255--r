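---
title: "Non-uniform embedding for conditional transfer entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-uniform embedding for conditional transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuecte)
```

## Scientific problem

Given simultaneous recordings of $L$ stochastic processes
$Y_1, \dots, Y_L$, we want the directed-dependency network: which process'
past helps predict which other process' present, beyond what the target's
own past and all remaining processes already explain. The
information-theoretic quantity behind this Wiener/Granger-type question is
the **conditional transfer entropy**

$$\mathrm{CTE}(X \to Y \mid Z) \;=\; I\!\left(Y_n;\, X_n^- \mid Y_n^-,
Z_n^-\right),$$

the mutual information between the present of the target and the past of
the source, conditioned on the past of the target and of every other
process. Conditioning on $Z$ suppresses indirect routes and common
drivers, which plain transfer entropy confounds.

The pasts $X_n^-, Y_n^-, Z_n^-$ are infinite-dimensional. Estimating CTE
therefore requires an embedding — a finite set of lagged variables that
stands in for the past. A *uniform* embedding takes every lag
$m, 2m, \dots, dm$ of every process and quickly produces conditioning sets
too high-dimensional for any nearest-neighbor estimator at realistic $N$.
This package implements the alternative: **non-uniform embedding (NUE)**,
a greedy search that picks only the most informative lagged variables,
across all processes, one at a time.

## The greedy embedding search

The candidate pool is $C = \{Y_{l, n-jm} : l = 1..L,\ j = 1..d\}$ —
`build_candidate_set()` enumerates it process-major, lag-minor. Starting
from an empty embedding $S^{0}$, iteration $k$

1. **ranks** every remaining candidate $W$ by a criterion measuring what
   $W$ adds about the target's present $Y_n$ given $S^{k-1}$,
2. takes the maximizer $W^{k}$, and
3. applies a **termination test**: if $W^{k}$ passes, it joins the
   embedding and the loop continues; the first failure ends the search.

`run_nue()` implements four variants of this loop, differing in the
ranking criterion and the termination rule (argument `variant` of
`nue_config()`):

| variant | ranking | termination |
|---|---|---|
| `msr` | $(1-\lambda)\, I(W; Y_n \mid S) - \lambda\, \mathrm{MSR}(Y_n \mid [W, S])$ | MSR must improve by more than $\gamma$ |
| `bootstrap` | $I(W; Y_n \mid S)$ | criterion $> I_{95}$ of a shuffle null |
| `la` | low-dimensional approximation of the CMI | full CMI $> I_{95}$ of an LA-statistic shuffle null |
| `aic` | $I(W; Y_n \mid S)$ | AIC of a kernel regression of $Y_n$ on $[W, S]$ |

**MSR** is the mean squared residual of a leave-one-out nearest-neighbor
prediction (`nn_predict()`): each $y_n(i)$ is predicted as the average of
$y_n$ over the $T$ nearest rows of the embedding matrix (Euclidean
metric, self excluded). On standardized channels the MSR lives in
$[0, \operatorname{var}(y)] = [0, 1]$, so the mixing weight
$\lambda \in [0,1]$ and the improvement threshold $\gamma \in [0, 1]$ are
unit-free and commensurable with the CMI term. The first winner is always
accepted (there is no previous MSR to improve on); from the second
iteration the candidate must lower the embedding's MSR by more than
$\gamma$. Raising $\gamma$ demands more predictive payoff per accepted
variable and thus trades sensitivity for specificity — the practical
lever against instantaneous-coupling confounds (below).

The **bootstrap** rule estimates a critical value by shuffling: $B = 100$
times, the candidate column and the target column are independently row
permuted (the conditioning block stays intact), the criterion is
re-estimated, and the observed value must exceed the 95th percentile of
this null (`bootstrap_threshold()`).

The **LA** (low-dimensional approximation) criterion replaces the
increasingly high-dimensional CMI with sums of bivariate quantities,

$$I(W; Y_n) - \tfrac{2}{|S|}\textstyle\sum_{W_j \in S} I(W; W_j) +
\tfrac{2}{|S|}\sum_{W_j \in S} I(W; W_j \mid Y_n),$$

i.e. relevance minus redundancy plus conditional redundancy. The LA
statistic does the ranking and feeds the shuffle null that estimates the
critical value $I_{95}$; the termination test itself compares the winning
candidate's *full* CMI $I(W; Y_n \mid S)$ against that critical value.
(Comparing the LA statistic itself against its own null makes the
threshold shrink with $|S|$ faster than the criterion and leads to severe
over-selection.)

The **AIC** rule predicts $Y_n$ from $[W, S]$ by Nadaraya–Watson kernel
regression (`kde_predict()`: Gaussian kernel on Mahalanobis-whitened
coordinates, Gaussian-reference bandwidth) and computes
$\mathrm{AIC}_k = N \log(\mathrm{MSE}) + 2p$ with the effective parameter
count $p = \sum_i K_{ii} / \sum_j K_{ij}$. A candidate is kept while the
AIC keeps *increasing* (`aic_accept = "increase"`). This direction looks
inverted but is the published rule and the one that reproduces the
benchmark: as embedding dimension $k$ grows, the reference bandwidth
$h = (4/(k+2))^{1/(k+4)} N^{-1/(k+4)}$ widens, the kernel rows flatten,
and $p$ *falls* toward 1 — so for informative candidates the complexity
term drops faster than the fit term, raising the AIC, while uninformative
candidates let the AIC fall. The classical direction is available as
`aic_accept = "decrease"`.

## Estimators

All information quantities use the Kraskov–Stögbauer–Grassberger
(algorithm 1) $k$-nearest-neighbor estimator
(`ksg_mutual_information()`, `ksg_conditional_mutual_information()`):
the distance to the $T$-th neighbor in the joint space under the max-norm
sets a radius per point; strictly-inside range counts in the marginal
spaces enter a digamma formula. Estimates are in nats and can be slightly
negative at finite $N$; no non-negativity is assumed anywhere.

Numerical choices that matter for reproducibility:

* **Tie breaking.** Strict-inequality range counts are ill-defined on
  duplicated coordinates (common after mixing integer-ish data or in
  deterministic maps). Every realization matrix gets a seeded uniform
  jitter of amplitude $10^{-10} \times$ column-sd before any neighbor
  search; the seed lives in `neighbor_config()`/`nue_config()`, draws are
  column-major so a leading block's jitter does not depend on what
  follows it, and `run_nue()` jitters once per run so all iterations see
  one noise realization. Nearest-neighbor regression breaks remaining
  exact ties by (distance, index).
* **Alignment.** All lagged blocks share one time support: the first
  $d \cdot m$ rows are dropped everywhere, so every estimate in a run
  uses the same $N_{\mathrm{eff}} = N - d\,m$ realizations.
* **Standardization.** Channels are centered and scaled by the population
  standard deviation (divide by $N$). `run_nue()` standardizes its input
  if it is not already standardized.
* **Theiler window.** Neighbor searches can exclude temporally adjacent
  samples (`theiler`); the benchmark default is 0 (only the point itself
  is excluded).

## Benchmark systems

Two 5-channel systems with known ground truth (`ground_truth()`) are
included, with defaults chosen to match the published study conditions:

* `simulate_henon()`: five coupled Hénon maps; the outer nodes are
  autonomous, inner node $l$ is driven by both neighbors through a convex
  combination with coupling strength $Q$. Six true edges. Initial states
  are uniform on $[0, 0.5]$, 1000 burn-in samples are discarded, and
  diverging trajectories are redrawn.
* `simulate_ar()`: a linear-stochastic AR core (channel 1) driving
  channels 2–4 linearly and quadratically, with a 4 → 5 chain. Five true
  edges. Innovations are standard normal; an `innovations` hook makes the
  recursion exactly testable.

`mix_instantaneous()` post-multiplies by
$A = (1-\alpha) I + \alpha (J - I)$, the zero-lag mixing used to emulate
volume-conduction-like instantaneous couplings ($\alpha \le 0.3$). Mixing
creates spurious zero-lag dependencies between all channels; the $\gamma$
threshold of the `msr` variant is the intended counter-measure.

## From embeddings to networks

`detect_network()` runs the embedding once per target and declares edge
$i \to j$ exactly when some lag of channel $i$ survives in target $j$'s
embedding; under this rule the embedding's termination test doubles as
the significance test of the CTE (`estimate_cte()` returns exactly 0,
flagged `no_source_lag`, when no source lag was selected).
`score_detection()` computes TP/TN/FP/FN over the 20 ordered off-diagonal
pairs and the percentage metrics ACC/TPR/TNR. `run_experiment()` wraps
simulation → mixing → standardization → detection → scoring over a
seeded parameter grid and reports per-realization averages plus the
iteration counts of the greedy loop (the number of accepted candidates,
summed over targets; the final rejected test is not counted).

```{r example, eval = FALSE}
cfg <- nue_config(variant = "msr", lambda = 0.5, gamma = 0.04, seed = 1)
res <- run_experiment("ar", N = 512, alpha = 0.1, R = 100, cfg = cfg)
res[, c("alpha", "gamma", "acc", "tpr", "tnr", "iterations")]
```

Problem sizes: the package's own benchmark settings are $L = 5$ channels,
$N = 512$ samples, $d = 5$ lags per channel ($|C| = 25$ candidates),
$T = 10$ neighbors, $B = 100$ shuffles — each `run_nue()` call then takes
of the order of 0.1–1 s (`msr`, `aic`) on one CPU core. Costs scale as
$O(N^2)$ per estimate and linearly in the candidate count per iteration;
the `la` variant additionally scales with the square of the selection
size and is by far the slowest, consistent with its published execution
times.

## Limitations

* KSG estimates assume continuous-valued data; heavily quantized inputs
  survive only thanks to the tie-breaking jitter and lose information.
* The greedy search is sequential: a candidate rejected at iteration $k$
  is only reconsidered implicitly (it stays in the pool), and the loop
  stops at the *first* rejection, so a single unlucky test ends the
  embedding.
* $\gamma$ is data-dependent and must be scanned; the benchmark values
  (0.04–0.12) apply to standardized channels at these lengths.
* The `bootstrap` (and to a lesser degree `la`) variants over-select
  under strong instantaneous mixing (their shuffle nulls do not model
  zero-lag leakage), which is the motivation for the MSR rule with
  $\gamma > 0$.
* All routines are serial; Monte-Carlo replications parallelize trivially
  outside the package if needed.
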