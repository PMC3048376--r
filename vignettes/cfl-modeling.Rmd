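---
title: "Constrained fuzzy logic modeling of signaling networks with cflnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained fuzzy logic modeling of signaling networks with cflnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cflnet)
```

## The modeling problem

Immediate-early signaling responses — phosphorylation states measured
shortly after a cell is exposed to ligands, with or without kinase
inhibitors — are graded: a node is often at 20–40 % of its maximal
activity, not simply on or off. Boolean logic (BL) models of a signaling
network cannot represent such intermediate states, and when forced to fit
them they systematically mis-estimate network topology: a link that drives
a node to 30 % activity costs a Boolean model more error when present
(predicting 1 against an observation of 0.3) than when deleted (predicting
0). Constrained fuzzy logic (cFL) keeps the interpretability of a logic
model but replaces the binary input–output map of each interaction with a
quantitative transfer function, so node activities live in $[0,1]$.

`cflnet` implements the complete cFL workflow: it takes a signed directed
*prior knowledge network* (PKN) and a normalized perturbation–response
dataset, and returns a *family* of trained, simplified quantitative logic
models together with ensemble summaries (gate frequencies, sensitivities,
prediction uncertainty).

## The model

**Transfer functions.** Each gate input carries a transfer function. The
workhorse is the normalized Hill function

$$f(x) = \frac{x^n\,(1+k^n)}{x^n + k^n},$$

rescaled so that $f(0)=0$ and $f(1)=1$; $n \ge 1$ sets the sharpness and
$k > 0$ is the EC50-like midpoint. Edges leaving a *stimulus* node instead
use a zero-intercept linear map $f(x) = \mathit{slope}\cdot x$: stimuli are
applied at saturating (0/1) levels, and a normalized Hill transfer of a 0/1
input is again 0/1, so graded activity downstream of a stimulus is only
reachable through a linear first edge. Inhibitory edges invert the
transfer, $1 - f(x)$.

**Gates.** A gate AND-combines its transferred inputs (minimum by default;
a product variant is available), and a node OR-combines its active gates
(maximum by default; capped sum in the product variant), i.e. models are in
disjunctive normal form. A `boolean` operator mode — inputs thresholded at
0.5, logical AND/OR — gives the BL reference point used for comparisons.

**Simulation.** Stimulus nodes are clamped to their design values,
inhibited nodes with flag 1 are clamped to 0, all other nodes start at 0
(no basal activity) and are updated synchronously until the maximum change
falls below a tolerance. Fit is the mean squared error (MSE) over all
non-missing signal × condition cells.

## The training workflow

1. **Compression.** Nodes that are neither measured, perturbed, nor
   necessary for the logic are spliced out: an intermediate with one
   incoming or one outgoing edge is bypassed, the bypass sign being the
   product of the two edge signs. Nodes with ≥ 2 in- and ≥ 2 out-edges are
   retained, as are nodes on cycles and multi-input nodes feeding a single
   inhibitory edge — in both of the latter cases the splice would (or
   could) change the input–output logic, so the package keeps them. The
   property test guarding this rule checks Boolean input–output truth-table
   equivalence on random acyclic networks.
2. **Expansion.** Every node's incoming edges are expanded into candidate
   gates: all single edges plus all two-input AND gates (`all_pairs`), or —
   the variant that avoids "output active because the input is absent"
   hypotheses — standalone gates only for activating edges plus
   AND-NOT gates pairing each activator with each inhibitor
   (`inhibitory_only`). Each (gate, input) pair owns one discrete
   transfer-function *slot*.
3. **Discrete training.** Each slot takes one of 8 states: absent, or one
   of 7 library members (Hill: a near-linear curve $n=1.01$, $k=68.5098$
   plus sigmoids $n=3$, $k \in \{0.2,\dots,0.7\}$; linear: slopes
   $0.2,\dots,0.8$). With $h$ slots the search space is $8^h$. A
   generational genetic algorithm (elitism, tournament selection, uniform
   crossover, per-locus mutation) minimizes the MSE; independent seeded
   runs yield a model family. Logically redundant AND gates (subsumed by a
   simpler gate on the same output) are removed.
4. **Reduction.** Each model is greedily simplified — deactivate a gate,
   or replace a 2-input AND by one of its 1-input sub-gates — accepting at
   each step the alteration with the smallest resulting MSE as long as it
   stays within a *reduction threshold* of the unprocessed model's MSE.
5. **Refinement.** With the topology fixed, all active transfer-function
   parameters are optimized continuously (bounded local search; Hill
   $k \in [0.01, 2]$, $n \in [1, 5]$, slopes in $[0,1]$).
6. **Filtering.** Per model, the fewest-parameter reduced–refined variant
   whose MSE stays within the *selection threshold* (default
   $5\times10^{-3}$) of the model's best refined MSE is selected; the
   collection is the *filtered* family analysed downstream.

```{r workflow, eval = FALSE}
pkn <- read_sif(system.file("extdata", "toy_pkn.sif", package = "cflnet"))
data <- read_midas(system.file("extdata", "toy_data.csv", package = "cflnet"))
fit <- cfl_fit(pkn, data, expand_mode = "inhibitory_only",
               n_runs = 20, seed = 1)
summary(fit)
plot(fit, type = "profile")
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `expand_mode` | `all_pairs` | candidate-gate vocabulary (see above) |
| `sim$tol` | `1e-4` | fixed-point convergence tolerance (activity units) |
| `sim$max_iter` | `10 × nodes` | iteration cap; non-convergence is penalized, not fatal |
| `ga$population_size` / `max_generations` / `stall_generations` | 50 / 500 / 100 | GA budget; defaults sized for $h$ up to a few hundred slots |
| `ga$mutation_rate` | `1/h` | per-locus mutation probability |
| `reduction_grid` | `0 … 5e-2` (9 points) | thresholds at which each model is simplified |
| `selection_threshold` | `5e-3` | allowed MSE increase when picking each model's final form |

The reduction-threshold grid spans the decades over which trained models
show their characteristic jump in refined MSE (the *filter point*); the
profile plot makes that jump visible per model.

## Numerical and design choices

* **Update scheme.** Synchronous fixed-point iteration with tolerance
  `1e-4`. cFL updates are continuous and, on the acyclic networks the
  package targets, contract to a fixed point in a few sweeps. Conditions
  that fail to converge within the cap are flagged and their predictions
  treated as undefined; each undefined prediction contributes a squared
  error of 1.0 to the MSE so oscillating models are selected against.
* **Inhibitor semantics.** An inhibited node's *activity* is clamped to 0.
  Whether the measured phospho-level of an inhibited kinase should instead
  be compared against its computed (but catalytically silenced) value is a
  genuinely open modeling question; the package adopts the simpler clamp.
* **Boolean mode with graded stimuli.** Boolean evaluation thresholds
  inputs at 0.5. Designs in the package's benchmarks apply stimuli at 0/1,
  where the threshold is irrelevant.
* **Reduction bookkeeping.** The degradation cap is measured against the
  *unprocessed* model's MSE (an absolute cap per threshold), which is what
  makes the filter-point semantics well defined. Along the ascending grid,
  reduction continues from the previous threshold's topology, so parameter
  counts are nonincreasing in the threshold by construction. Ties between
  alterations break deterministically by (output, gate index, kind).
* **Refinement.** A bounded quasi-Newton local search (L-BFGS-B) over all
  active slots' parameters, started from their current values; if the
  optimizer fails or worsens the fit the incoming model is kept. Both $n$
  and $k$ are refined; bounds cover the discrete library with margin.
* **Baseline for filtering.** A model's baseline is its minimum refined
  MSE across the grid (not the threshold-0 MSE); the two differ only when
  refinement landscapes are rugged.
* **Significance testing.** Families trained on randomized data/networks
  provide null MSE distributions. The null is first checked for normality
  with a Jarque–Bera test at $\alpha = 0.001$: normal-looking nulls use a
  one-sided z-score p-value, otherwise the p-value is the empirical
  fraction of null models at or below the real model's MSE, reported as an
  upper bound $1/|\mathrm{null}|$ when that count is zero.
* **Holdout eligibility.** A (signal, stimulus) holdout is only attempted
  when the signal reaches at least 0.1 (the package's reading of "at least
  partially activated") under the held-out stimulus and under some other
  stimulus.
* **Consensus topologies.** Family topologies are compared through edges
  present in more than 25 % of models, projected onto designated nodes by
  re-compressing the consensus graph.

## What the synthetic-data generator emulates

`make_toy_pkn()` draws random signed DAGs with designated roles (stimuli
as sources, every measured node reachable); `make_ground_truth_model()`
selects one generating gate per output and assigns library (or off-grid)
transfer functions; `simulate_dataset()` produces noise-free or
truncated-Gaussian-noised observations over a full-factorial stimulus ×
inhibitor design. `toy_signaling_example()` is a fixed, hand-authored
15-node growth-factor/cytokine network (2 stimuli, 2 inhibited kinases, 6
measured phosphoproteins) whose ground truth drives one branch to ~0.38
and ~0.21 — deliberately inside the regime where BL and cFL disagree. It
is inspired by classic toy networks in the logic-modeling literature but
transcribes no published network.

Null controls mirror the standard randomizations: pairwise exchange of
data values, source/target permutations of the edge list, wholesale
exchange of nodes' input sets, fully random networks with matched node and
edge counts, and random removal or addition of a fraction of PKN edges.

What passing these benchmarks does *not* show: real phosphoproteomic data
carry measurement noise (~10 % in typical bead-based assays; the generator
exposes `noise_sd = 0.1` for realism experiments but the benchmarks are
noise-free), normalization artifacts, unmodeled crosstalk, and feedback on
time scales the steady-state abstraction ignores. Success on in-space
synthetic data demonstrates the estimator and workflow, not biological
fidelity of any particular PKN.

## Benchmark problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU: the 15-node toy network
(11 slots after compression and expansion), GA populations of 25–40 with
80–150 generations, families of 3–10 models, 20 null replicates, and
10-seed replications of the qualitative BL-vs-cFL comparison. The same
code paths scale to the hundred-slot hypothesis spaces of real studies by
raising the GA budget and family size in `cfl_ga_config()`.

## Known limitations

* Compression is deliberately conservative on cycles; cyclic PKNs are
  legal inputs but intermediates on cycles are never spliced out.
* Expansion stops at 2-input AND gates, matching standard practice;
  higher-arity gates would require extending `expand_pkn()`.
* The greedy reduction is a non-exhaustive heuristic: it can miss a
  smaller equally-fitting topology that is only reachable through a
  temporarily worse alteration.
* No ordinary-differential-equation translation and no asynchronous update
  schemes are provided; the model is a steady-state abstraction.
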