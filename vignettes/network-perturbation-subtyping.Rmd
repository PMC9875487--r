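---
title: "Network perturbation subtyping: model, design choices, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network perturbation subtyping: model, design choices, and what the synthetic benchmark shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netperturb)
```

## The model

The pipeline treats disease heterogeneity as heterogeneity in *network
deregulation*. A reference population defines normal co-regulation: we model
the (normalized, approximately Gaussian) expression of each gene as a linear
function of a small set of network neighbors. A disease sample is then
described not by its expression but by how far each gene deviates from the
value the reference network predicts from that same sample's neighborhood —
a per-gene, per-sample nonnegative deregulation score. Samples cluster on
these scores, so two samples belong to the same subtype when the *same part
of the network* is perturbed in both, regardless of the direction or
absolute magnitude of expression changes.

Formally, reference expression is assumed to follow a linear-Gaussian
structural equation model. Structure is learned by greedy penalized-BIC
search over DAGs: the forward phase adds, among all edges whose addition
keeps the graph acyclic, the one with the largest gain in

$$\mathrm{score}(g \mid \mathrm{Pa}) = -\tfrac{n}{2}\log\hat\sigma^2(g \mid \mathrm{Pa}) - \lambda\,\tfrac{|\mathrm{Pa}|+1}{2}\log n,$$

stopping when no gain is positive; the backward phase deletes edges the same
way. All conditional variances come from the reference covariance matrix, so
the search is exactly invariant to sample order, and gain ties are broken
lexicographically by gene ID so the output is fully deterministic. The DAG
is converted to its CPDAG (v-structures plus Meek rules R1–R3), because only
the equivalence class is identified from observational data. Markov blankets
are read off the CPDAG: neighbors plus co-parents, where co-parents are
collected from compelled (directed) edges only — in an undirected chain no
member DAG forces a spouse relationship, so undirected neighbors of a child
do not enter the blanket.

Per-gene reference regressions (ordinary least squares of each gene on its
blanket, residual SD with denominator $n-p-1$, floored at $10^{-6}$) turn
the graph into a scoring machine: $d_g = |y_g - \hat y_g| / \hat\sigma_g$.
For a sample drawn from the reference distribution, $d_g$ is approximately
$|Z|$ for standard normal $Z$, so its expectation $\sqrt{2/\pi} \approx
0.798$ is a sharp closed-form calibration point that the test suite checks
on held-out reference samples.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| BIC penalty multiplier $\lambda$ | 1.0 | standard BIC; larger values give sparser graphs when reference cohorts are small |
| minimum reference samples | 20 | below this the covariance estimate is too unstable to learn any structure |
| blanket cap | $\min(n/5, 20)$ | keeps the per-gene regressions well-conditioned at realistic reference sizes (~128); enforced by a largest-\|coefficient\| screen |
| PCA components | 6 | the number used in the motivating analysis; `n_pcs = "auto"` applies a reproducible elbow rule (first relative eigenvalue drop below 0.02) |
| SNN neighborhood `k` | 20 | dense enough that clusters of ~70 samples stay internally connected |
| resolution grid | 0.4–1.2 by 0.1 | brackets the stable window observed in practice (0.6–0.9) |
| kNN `k` for projection | 3 | smallest odd `k` at which assignments stabilize; `k_stability_scan()` verifies per cohort |
| FDR threshold | q < 0.05 | conventional; applied jointly across all scanned variables |

Normalization centers and scales each gene using **reference-sample
statistics only**; case samples never contribute to any statistic used in
training (a leakage guard the tests enforce by perturbing case values and
checking that reference-derived means/SDs are unchanged). CPM/log2
transformation is applied only when the input looks like integer counts.

## Batch handling

Batch structure is detected with guided PCA: the statistic is the variance
of the data along the first right singular vector of the batch-mean matrix,
divided by the variance along the first unguided principal component —
a ratio in [0, 1] — with significance from label permutations (+1
smoothing). Correction is per-gene location-scale adjustment of each batch
to the pooled mean/SD. This removes purely additive offsets exactly and is
deliberately simpler than empirical-Bayes alternatives; it is sufficient for
additive batch structure and is isolated behind `correct_batch()` so a
heavier method can be swapped in.

## The synthetic cohort generator

`simulate_study()` emulates the study conditions the pipeline was designed
for, at desk scale:

* a random DAG over 200 genes (expected degree 2), edge weights uniform on
  $\pm[0.5, 1.5]$ — the near-zero band is excluded because such edges are
  statistically invisible at $n \approx 10^3$ and would make structure
  recovery untestable;
* 128 reference samples and four case subtypes of 181/156/79/73 samples
  (the cluster sizes reported in the motivating COPD analysis);
* each subtype perturbs 12 disjoint genes, interleaved across the
  topological order, with an additive mean shift of 3 structural-noise SDs
  injected into those genes' equations (propagating to descendants);
* subtype-linked clinical variables whose means mirror the published
  cluster summaries (a lung-function-like continuous variable, an ordinal
  symptom score, a binary medication flag), exponential survival with
  per-subtype hazards 0.08/0.10/0.30/0.12 per year — the third subtype is
  the high-mortality one — and independent uniform censoring on
  $[0, 3/\mathrm{median\ hazard}]$, giving roughly 30–50% censoring without
  informative censoring;
* two sequencing batches with additive per-gene offsets (SD 1), and
  two-visit spirometry/emphysema fields constructed so that the designated
  reference samples pass all selection criteria and every case fails at
  least one (obstruction, preserved-ratio impairment, rapid decline, or
  emphysema), mimicking a realistic case-group composition.

Validation cohorts are drawn from the *same* generating network and subtype
specifications with fresh samples (`simulate_study(network =, specs =)`),
which is what cross-cohort validation means for this design.

What the generator does **not** emulate: count overdispersion (expression is
simulated post-normalization on the Gaussian scale), read-level artifacts,
non-linear regulatory effects, correlated censoring, population structure,
or clinical missingness patterns. Passing tests therefore demonstrate that
the machinery is correct and well-calibrated under the model's own
assumptions — not that real cohorts satisfy those assumptions.

## Numerical choices and degenerate inputs

* Conditional variances are floored at $10^{-12}$ during search and residual
  SDs at $10^{-6}$ during scoring, so collinear blankets cannot produce
  infinite deregulation.
* kNN distance ties are broken by training-sample order; vote ties by the
  single nearest neighbor's label; an even `k` draws a warning.
* Louvain labels are relabeled 0..K−1 by decreasing cluster size (ties by
  first member index) under a fixed seed, so repeated runs are identical.
* If no resolution window of length ≥ 2 is stable, selection falls back to
  the modal cluster count with a warning; a single dense clique collapses to
  one cluster rather than erroring.
* Constant features are dropped (with a warning) before PCA; genes absent
  from a new cohort are dropped from the frozen model when overlap is at
  least 90%, otherwise scoring refuses.
* All-equal values give Kruskal–Wallis (0, 1); empty contingency margins are
  an error; NA p-values are excluded from the BH family size.

## Design decisions that were genuinely open

* **Search algorithm.** An exact fast greedy equivalence search (FGES) over
  CPDAGs was not required: a DAG-space hill-climb followed by CPDAG
  conversion satisfies the same contract (scored greedy forward/backward
  phases, deterministic, monotone forward score) and is much simpler to
  audit. The score trace is stored so monotonicity is testable.
* **Deregulation feature.** The standardized absolute residual was chosen
  as the scale-free, nonnegative deviation measure that is zero iff a gene
  is perfectly predicted; squared-residual or log-ratio variants would
  order samples nearly identically and can be added behind the same
  interface.
* **Cross-cohort scoring.** For projection, structure is frozen but
  regressions are re-fit on the new cohort's own reference group. Refitting
  absorbs cohort-wide location/scale shifts (a held-out reference cohort
  scored after a global 2x scale change still averages $\sqrt{2/\pi}$).
  The cost is a mild scale contraction relative to discovery — the
  discovery residual SDs are slightly optimistic because structure was
  selected on the same reference samples — which is why projection accuracy
  is validated at the full default design size rather than on miniature
  cohorts.
* **Reference definition.** "Normal spirometry" is operationalized as
  FEV1/FVC ≥ 0.70 and FEV1 ≥ 80% predicted at both visits; the emphysema
  and decline thresholds are strict inequalities with the decline threshold
  configurable (5% default, 3% for the stricter variant), and samples with
  missing spirometry can be routed to the case group, matching the
  selection rules of the cohorts this design mirrors.

## Problem sizes used in validation

The shipped tests and the acceptance script use: 50-gene/degree-2 networks
at $n = 1000$ (10 seeds) for Markov-blanket recovery, where median F1
exceeds 0.8; 500 held-out reference samples for the $\sqrt{2/\pi}$
calibration; the full default design (128 reference, 489 cases, 200 genes,
10 seeds) for end-to-end subtype recovery and cross-cohort projection; and
200 replicates for the guided-PCA and FDR calibration checks. These sizes
were chosen as the smallest designs at which the corresponding properties
are statistically sharp.

## Known limitations

* The linear-Gaussian assumption is load-bearing: strongly non-linear or
  discrete regulatory relationships will be scored as deregulation even in
  reference samples.
* Structure learning at reference sizes near the minimum (a few dozen
  samples) produces dense, partially spurious graphs; the blanket cap keeps
  scoring stable but blankets should then be interpreted as predictive
  neighborhoods, not causal claims.
* The log-rank test and the association scan are unadjusted for covariates;
  confounding between subtype and, e.g., age must be assessed separately.
* t-SNE-style visualization of the subtype space is intentionally out of
  scope; the PCA coordinates are the canonical embedding.
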