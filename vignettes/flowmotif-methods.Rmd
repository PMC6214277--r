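---
title: "Methods: information-flow motifs in directed phase-coupling networks"
author: "flowmotif developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-flow motifs in directed phase-coupling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowmotif)
```

## Overview

`flowmotif` analyzes directed effective-connectivity networks built from
multichannel instantaneous-phase recordings (e.g. source-projected MEG
parcellated into cortical regions). The pipeline has five stages:

1. **Phase transfer entropy (PTE).** For regions $X$ and $Y$ with binned
   instantaneous phases,
   $$\mathrm{PTE}_{XY}(h) = \sum \Pr[x_{t+h}, x_t, y_t]\,
     \log\frac{\Pr[x_{t+h} \mid x_t, y_t]}{\Pr[x_{t+h} \mid x_t]},$$
   a conditional mutual information: the gain in predicting $X$'s phase
   $h$ samples ahead from $Y$'s present phase beyond $X$'s own. All
   probabilities are plug-in estimates from joint histograms over one
   epoch; pairwise values are averaged over all subject–epoch units to
   remove individual measurement bias. The prediction delay is
   $h = N_s N_{ROI} / N_\pm$, where $N_\pm$ counts sign changes of
   consecutive phase values pooled over time and regions in the epoch.
2. **Network construction.** Strict thresholding (`PTE > τ`) turns the
   complete weighted digraph into a binary directed network $G(\tau)$. A
   principled interval $[\tau_{\min}, \tau_{\max}]$ is used instead of a
   single threshold: $\tau_{\min}$ is the nearest-rank 30th percentile of
   the off-diagonal PTE distribution (retaining the top 70% of links) and
   $\tau_{\max}$ the largest threshold whose network is still weakly
   connected with no isolated nodes.
3. **Motif census and null model.** Every weakly connected induced 3-node
   subgraph is classified by a canonical id — the 9-bit row-major reading
   of its adjacency matrix minimized over the six relabelings; there are
   exactly 13 connected classes. Observed counts are compared against
   networks randomized by an edge-switching algorithm that preserves each
   node's in- and out-degree and the number of bi-directional links
   (mutual dyads and single links swap within their own class). A motif is
   *overexpressed* when (i) the empirical probability that a rewired
   network matches or exceeds the observed count is below 0.01, (ii) the
   motif occurs at least 4 times with distinct node sets, and (iii)
   observed/null-mean count ratio is at least 1.1. Magnitude is the
   z-score $(J - \mu)/\sigma$ over the null ensemble.
4. **Apex statistics.** Motif 78 is the bi-directional two-hop path: a
   centre (*apex*) bidirectionally linked to two otherwise unlinked
   nodes. A node's apex-ratio is the fraction of its motif-78
   participations in which it is the apex; hubs are nodes whose total
   degree is at least the mean plus one (population) standard deviation.
5. **Motif-conductance clustering.** The motif adjacency matrix $W_M$
   counts node-disjoint motif instances shared by each node pair; with
   motif degrees $d_{ii} = \sum_j w_{ij}$, the motif conductance of a
   bipartition is $\phi = \mathrm{cut}/\min(\mathrm{vol}_1,
   \mathrm{vol}_2)$. The spectral sweep orders participating nodes by the
   $D^{-1/2}$-scaled eigenvector of the second smallest eigenvalue of
   $\mathcal{L} = I - D^{-1/2} W D^{-1/2}$ and returns the minimum-
   conductance prefix split, guaranteed within $4\sqrt{\phi^*}$ of the
   optimum. Rather than fixing one threshold, motif adjacency matrices are
   aggregated over the *link-resolved* threshold set T — all values in
   $(\tau_{\min}, \tau_{\max}]$ at which exactly one link drops, i.e. the
   weights of the removed links — so motifs made of strong links count in
   more summands. Nodes in no motif instance form a third,
   non-participating group.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `n_bins` | `round(exp(0.626 + 0.4 log(N_s − 1)))` (52 at $N_s = 4096$) | histogram bins over $(-\pi,\pi]$; the binning rule of the PTE literature. The reference analysis leaves the bin count unstated, so this documented default is configurable. |
| `h` | per-epoch sign-change estimate | Rounding of the generally non-integer ratio is half-away-from-zero, clamped to $\ge 1$; a fixed `h` can be supplied. |
| `log_base` | $e$ | PTE values are compared, never interpreted in bits; the base only rescales. |
| `percentile` | 0.30 | nearest-rank convention; with 6006 distinct values this retains exactly 4204 directed links. |
| `n_random`, `switch_factor` | 1000, 100 | null ensemble size and attempted swaps per directed link. "100 switches" is read as 100 × (number of links) attempted swaps, the standard switching-algorithm convention; the original tool's exact semantics are not recoverable, so the factor is configurable. |
| `delta` | 0.005 | step for the equally spaced threshold sweep used in per-threshold overexpression reports (clustering itself uses the link-resolved set T, which is bias-free). |
| `motif` | 78 | the clustering motif; only 78 has a distinguished apex position. |

Statistical conventions: standard deviations in the z-score and the hub
rule are population (divide-by-$N$) — the 1000 nulls are a fixed
descriptive ensemble, not a sample; exceedance probabilities use the weak
inequality, so a motif absent everywhere has $p = 1$; a zero null mean
with a positive observed count passes the ratio criterion and is flagged.

## The synthetic world

The MEG recordings underlying the reference analysis are not
distributable, so the
package ships a generative stand-in with known ground truth.

**Coupled phase oscillators** (`generate_coupled_phases`): per subject and
epoch, each region's phase performs a wrapped random walk
$$x_i(t+1) = \mathrm{wrap}\!\left(x_i(t) + \omega_i +
  \sum_j c_{ji} \sin(x_j(t - \ell) - x_i(t)) + \varepsilon\right),
  \qquad \varepsilon \sim \mathcal{N}(0, \sigma^2),$$
initialized uniformly on $(-\pi, \pi]$. The sine coupling is the minimal
(Kuramoto-style) form producing genuine directed information flow
detectable by the transfer-entropy estimator. Epochs are re-initialized
rather than sliced from one long run, matching their treatment as
exchangeable averaged units. Defaults mirror the reference data's structure
(67 subjects × 20 epochs × 78 regions × 4096 samples; intrinsic increments
0.050–0.065 rad/sample correspond to a 10–13 Hz rhythm at 1250 Hz
sampling). The model is *not* an MEG forward model: no volume conduction,
no band-pass filtering, no amplitude dynamics — a green recovery test
establishes that the estimator chain detects planted directed coupling,
not that it reproduces MEG physics.

The directionality-recovery tests run a scaled-down world calibrated once
and frozen: 2 regions, $\omega = (0.53, 0.47)$, one-way coupling 0.8, lag
1, noise 0.3, five 512-sample epochs. The faster intrinsic frequencies
keep the sign-change delay estimate small at 512 samples.

**Planted weight matrices** (`generate_planted_weight_matrix`): two
clusters, designated apex hubs; within-cluster ordered pairs incident to a
hub are drawn around `w_in` (both directions), everything else around
`w_out`, plus Gaussian jitter *reflected at zero* — reflection rather than
clamping keeps all off-diagonal entries distinct with probability 1, which
the one-link-per-threshold construction of T requires. An optional
directional offset plants sender/receiver asymmetry in the background.

## Numerical and design choices

- **Zero-probability histogram cells** contribute 0 (standard entropy
  convention); the PTE sum is clamped at 0 against round-off, as the
  population quantity is nonnegative.
- **Eigenproblem**: dense symmetric `eigen()` (the target scale is
  $N = 78$); the eigenvector sign is irrelevant because every prefix split
  of the ordering and its complement are both evaluated. Both the
  $D^{-1/2}$-scaled and the raw eigenvector orderings are swept and the
  better split returned, covering both conventions of the cited
  algorithm.
- **Disconnected motif graphs**: the sweep runs globally on all
  participating nodes. Under the scaled ordering the zero eigenspace of
  $\mathcal{L}$ makes components contiguous, so a zero-conductance split
  across components is found directly; the component count is reported.
  (A largest-component-only treatment would be unable to return the
  planted split for two motif-disconnected blocks.)
- **Ties**: tied PTE values inside the threshold interval violate the
  one-link-per-step guarantee and raise an error by default; a grouped
  mode (`ties = "group"`) drops tied links together. Ties in eigenvector
  entries break by node index; ties in minimum conductance by smaller
  first cluster, then lexicographically — all for determinism.
- **Degenerate inputs**: constant-sign phases (no sign changes) are a
  delay-estimation error; all-equal weight matrices have no percentile
  threshold; networks admitting no legal swap are returned unchanged and
  flagged; a motif graph with fewer than 3 participating nodes refuses
  partitioning with an informative report instead of erroring inside the
  pipeline.
- **Reproducibility**: every stochastic stage takes an explicit seed; the
  null ensemble fans a single seed out to per-draw substreams so results
  do not depend on draw order; `run_full_pipeline` refuses configurations
  without a seed and reproduces byte-identical artifacts.

## What a green test does and does not establish

The census is verified against a brute-force all-subsets oracle, the
switching null against per-draw degree/mutuality invariants, the sweep
against exhaustive minimum conductance on small graphs (within the stated
$4\sqrt{\phi^*}$ bound), and the threshold arithmetic against the reference
78-node counts (6006 ordered pairs, 4204 links at the 30th percentile,
average degrees recomputed from the reference uni/bi link counts). None of
this certifies neuroscientific conclusions: the reference subject-derived
quantities (exact $\tau$ intervals, z-score magnitudes, cluster
memberships) depend on recordings that are not available and are replaced
here by internal-consistency and synthetic-recovery checks.

Two structural caveats surfaced by the synthetic world are worth knowing:

- Under the class-preserving null, every node's *mutual* degree is
  invariant, so a graph whose two-hop-path count is forced by its degree
  sequence (e.g. pure bidirectional stars) is never called overexpressed;
  overexpression requires uni-directional links sitting in non-spoiling
  positions relative to chance.
- The end-to-end aggregated clustering is an approximation: on jittered
  planted matrices the sweep occasionally returns a split whose
  conductance is slightly above the planted split's (within the
  guarantee). Exact recovery on every random instance is therefore not a
  contract; the noiseless planted world is recovered exactly at any fixed
  threshold between the background and hub weight levels.

## Limitations

- Inputs must already be instantaneous phases; no Hilbert transform,
  band-pass filtering, or source reconstruction is provided.
- Only 3-node motifs; only a single 2-way split (plus non-participants) —
  no recursive k-way partitioning.
- The apex-ratio is defined for motif 78 only.
- PTE estimation is O(pairs × samples) per epoch in plain R; at the
  reference scale (78 regions, 1340 subject-epochs) a full matrix is an
  overnight batch job, not an interactive call. All other stages are fast
  at that scale.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
ps <- planted_structure(rep(c(1, 2), each = 8), apex_nodes = c(1, 9))
W <- generate_planted_weight_matrix(16, ps, w_in = 1, w_out = 0.25,
                                    jitter_sd = 0.02, seed = 1)
part <- cluster_pipeline(W, motif = 78)
part
```
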