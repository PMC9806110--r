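# ossubtype

Molecular subtyping of osteosarcoma expression cohorts from
differentiation-branch marker panels.

Single-cell profiling resolves the malignant compartment of osteosarcoma
into a stem-like (CSC) cluster and three differentiation branches whose
terminal clusters — OS-A2, OS-B2, OS-C2 — carry largely non-overlapping
marker genes. `ossubtype` turns that observation into a classification
pipeline:

* **Marker discovery.** For each terminal cluster, a one-vs-rest
  two-sided Wilcoxon rank-sum test per gene, with effect size
  $\log\{(\bar{e}_{\text{in}}+1)/(\bar{e}_{\text{out}}+1)\}$ on
  de-logged means, Benjamini–Hochberg adjustment, and detection
  fractions. Genes passing the screen
  ($q \le 0.05$, effect $\ge \log 1.5$, $\mathrm{pct_{in}} \ge 0.25$,
  $\mathrm{pct_{out}} \le 0.25$) for two or more clusters are removed
  from *all* panels, so the A/B/C panels are exclusive by construction.
* **Cohort subtyping.** Resampling consensus clustering of bulk samples
  on the panel genes: repeated 80% subsamples, k-means on z-scored
  expression at each candidate $k$, consensus matrix
  $M_{ij} = \#\text{co-clustered} / \#\text{co-drawn}$, final labels by
  average-linkage hierarchical clustering of $1 - M$, and $k$ selected
  by minimum PAC, $\mathrm{CDF}(0.9) - \mathrm{CDF}(0.1)$ of the
  off-diagonal consensus entries. Clusters are named A/B/C by the panel
  they over-express.
* **Single-sample assignment.** Panel-mean or strongest-marker argmax
  scores after per-gene cohort standardization, including the six-marker
  IHC rule (A: ALKBH5, TOM1L2; B: CDK4, LMO7; C: COL6A3, THBS2).
* **Survival.** Kaplan–Meier product-limit curves
  $S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ and the g-sample log-rank
  test, implemented from first principles and cross-checked against the
  `survival` package in the test suite.
* **Synthetic data.** A negative-binomial single-cell generator
  (CSC + three two-cluster branches + stroma, exclusive planted
  markers), a purity-mixture bulk cohort with exponential survival
  (worst hazard in the B-like subtype), and an IHC score table — all
  with ground truth, so the whole pipeline is testable offline.

The intended users are computational biologists who want a transparent,
fully deterministic re-implementation of this subtyping scheme, or a
harness for studying its statistical behavior under controlled
conditions.

## Worked example

```r
library(ossubtype)

cfg <- sim_config(seed = 1)                  # default study conditions
sim <- simulate_single_cell(cfg)             # 2000 cells x 2000 genes
norm <- lognormalize(sim$counts)

stats <- lapply(c(A = "OS-A2", B = "OS-B2", C = "OS-C2"),
                function(cl) wilcoxon_one_vs_rest(norm, sim$truth$cell_labels, cl))
panel <- select_specific_panel(stats)
panel
#> Marker panel: 60 genes (A: 21, B: 21, C: 18)
#>   A: G0043, G0059, G0049, G0042, G0044, G0056, G0048, G0045
#>   B: G0088, G0087, G0090, G0091, G0097, G0083, G0096, G0082
#>   C: G0131, G0122, G0132, G0135, G0123, G0126, G0134, G0136

cohort <- simulate_bulk_cohort(cfg)          # 90 samples + survival
cc <- consensus_cluster(cohort$expr, panel = panel, k_range = 2:6,
                        n_resamples = 100, seed = 2)
cc
#> Consensus clustering of 90 samples (100 resamples, frac 0.80)
#>   PAC per k: k=2: 0.449, k=3: 0.000, k=4: 0.076, k=5: 0.184, k=6: 0.222
#>   chosen k (min PAC): 3

groups <- assign_from_consensus(cc, 3, cohort$expr, panel)
adjusted_rand_index(groups, cohort$truth$bulk_group)
#> [1] 1

surv <- cohort$survival
surv$group <- as.character(groups[surv$sample_id])
logrank_test(surv)
#> Log-rank test: chi-square = 4.370 on 2 df, p = 0.1125
#>           A     B     C
#> observed 21 18.00 22.00
#> expected 23 11.91 26.09
```

Reading the output: the exclusivity screen recovers disjoint panels of
21/21/18 genes (the generator plants 20 exclusive markers per terminal
cluster); PAC is minimized at k = 3, the planted number of subtypes, and
the consensus labels agree perfectly with the simulated truth
(ARI = 1). The log-rank test compares the three recovered groups'
survival — group B shows an event excess (18 observed vs 11.9 expected
deaths), consistent with its doubled simulated hazard, though a single
90-sample cohort at hazard ratio 2 is not always significant at the 5%
level.

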