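# netperturb

Disease subtyping from bulk gene expression by **single-sample network
perturbation scoring**, with chronic obstructive pulmonary disease (COPD)
blood RNA-seq as the motivating application. The package is aimed at
computational biologists who want to discover molecular subtypes that are
*not* dictated by the clinical variables used to evaluate them: clustering
runs entirely on gene-expression deregulation, and clinical phenotypes are
held out for downstream association testing.

## The method

1. **Reference network.** From control samples (for COPD: former smokers
   with stable normal spirometry and < 5% CT emphysema), learn a Gaussian
   graphical network over genes with a greedy score-based search: the
   forward phase repeatedly adds the directed edge with the largest gain in
   penalized BIC,
   `score(g | Pa) = -n/2 * log(sigma^2_hat(g | Pa)) - lambda * (|Pa|+1)/2 * log(n)`,
   the backward phase deletes edges likewise, and the result is reported as
   a completed partially directed graph (CPDAG).
2. **Deregulation features.** For every gene `g`, fit the reference
   regression of `g` on its Markov blanket (parents, children, co-parents).
   A sample's deregulation of `g` is the standardized absolute residual
   `d_g = |y_g - yhat_g| / sigma_g` — zero iff the sample obeys the
   reference network exactly; `E[d_g] = sqrt(2/pi)` for a sample drawn from
   the reference population.
3. **Subtype discovery.** PCA on the samples-by-genes deregulation matrix
   (6 components by default), a shared-nearest-neighbor graph (Jaccard
   weights, `k = 20`), and Louvain community detection across a resolution
   grid; the cluster count is chosen as the longest resolution window over
   which memberships are constant (adjusted Rand index 1 between adjacent
   resolutions).
4. **Cohort projection.** New cohorts are never re-clustered: the network
   structure is frozen, regressions are re-fit on the new cohort's own
   reference group, samples are scored, projected into the stored PCA
   space, and assigned to subtypes by kNN majority vote (`k = 3`).
5. **Clinical read-out.** Kruskal–Wallis (continuous/ordinal) and
   chi-squared (binary) scans across subtypes with joint Benjamini–Hochberg
   FDR, unadjusted pairwise Wilcoxon comparisons, and Kaplan–Meier curves
   with the K-group log-rank test.

Because the cohorts that motivated the method are controlled-access, the
package ships a linear-Gaussian structural-equation simulator
(`simulate_study()`) that generates a reference population plus four case
subtypes, each perturbing a distinct gene set, with subtype-linked clinical
covariates, exponential survival with uniform censoring, and additive batch
structure — so the whole pipeline is testable end to end against known
ground truth.

## Worked example

```r
library(netperturb)

sim  <- simulate_study(seed = 1)                       # 128 reference + 489 cases
disc <- run_discover(sim$expr, sim$phenotypes, default_config(seed = 1))
disc$subtypes
#> <subtype_model> 489 samples, 4 clusters at resolution 0.80 (6 PCs, snn k=20)
#> cluster
#>   0   1   2   3
#> 181 156  79  73

mclust::adjustedRandIndex(disc$subtypes$labels,
                          sim$truth$labels[names(disc$subtypes$labels)])
#> [1] 1

ph <- sim$phenotypes[names(disc$subtypes$labels), ]
km_logrank(ph$surv_time, ph$event, disc$subtypes$labels)
#> <survival_result> 4 groups, log-rank chi^2 = 101.812 (df 3), p = 6.34e-22

association_scan(ph, disc$subtypes$labels, core_variable_manifest())[,
  c("variable", "test_name", "q", "significant")]
#>        variable      test_name        q significant
#> 1 lung_function kruskal-wallis 9.49e-16        TRUE
#> 2 symptom_score kruskal-wallis 5.58e-04        TRUE
#> 3    medication    chi-squared 5.17e-03        TRUE
```

The four recovered clusters match the four planted subtypes exactly (ARI
1), the subtype-linked survival hazards produce a strongly significant
log-rank separation, and every subtype-linked clinical variable clears the
5% FDR threshold. `run_project()` then assigns a fresh cohort simulated
from the same generating network to these clusters without re-clustering.

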