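# phosnet

Directed regulatory-network inference for phosphorus metabolism from
**short balanced panel time series**: a handful of subjects, each sampled a
handful of times per diet condition, across the eight analytes that govern
phosphate homeostasis (serum phosphate, corrected calcium, PTH, FGF23,
α-Klotho, 1,25-dihydroxyvitamin D, BALP, urinary Pi/Cr). It is written for
physiologists and biostatisticians who have panel data shaped like a
crossover diet intervention (typically 6 subjects × 9 time points × 8
variables × 3 conditions) and want the full chain from raw panel to
centrality tables, with every statistical step testable against synthetic
ground truth.

## What it computes

Per diet condition:

1. **Stationarity screen** — a Levin–Lin–Chu-type pooled panel unit-root
   test. Per subject, the ADF-orthogonalized pairs `(e, v)` are pooled into
   `e = delta * v + err`; the t-statistic of `delta` is recentred/rescaled
   with adjustment moments `mu*, sigma*` *calibrated by simulation at the
   exact (N, T) in hand* (published moment tables do not reach T = 9), and
   referred to the left normal tail. Variables failing the screen are
   within-subject differenced and retested (`ensure_stationary()`), with a
   log of what was done.
2. **Pairwise panel Granger tests** — for each ordered pair (x, y), the
   fixed-effects regression
   `y_it = alpha_i + sum_l rho_l y_{i,t-l} + sum_l beta_l x_{i,t-l} + eps_it`
   is estimated by pooled within-OLS, bias-corrected with the half-panel
   jackknife `2*theta_full - (theta_first + theta_second)/2`, and the
   cross-lag block `beta` is Wald-tested with a delete-one-subject
   jackknife (cluster-robust) variance; a subject-resampling bootstrap
   p-value is available for very small N.
3. **Network construction and graph metrics** — significant pairs (default
   per-pair alpha = 0.05; BH optional) enter a weighted adjacency matrix
   (Wald weight by default, "larger = stronger"), summarized by in/out
   degree centralities (counts / (n−1)), directed shortest-path
   betweenness (normalized by (n−1)(n−2)), density (edges / n(n−1)), and a
   hub report with ties reported as ties.

A panel-VAR **synthetic generator** with known causal ground truth
(`simulate_panel_var()`, `diet_study_preset()`) replaces the non-public
clinical measurements and drives the validation suite, including
end-to-end edge-recovery F1. Companion statistics used alongside the
networks — repeated-measures correlation (ANCOVA common slope) and
Kruskal–Wallis with explicit Bonferroni family — are included.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 1
simulates the three diet-condition panels from presets whose ground-truth
graphs realize each condition's reference degree structure; steps 2–3 run
the screen and the 56 pairwise tests per condition; step 4 checks the
reported network summaries for internal consistency; step 5 is a quick
validation Monte-Carlo. For example:

```sh
$ Rscript analysis/01_simulate_study.R
regular : wrote results/synthetic/panel_regular.csv (6 x 9 x 8) and results/synthetic/truth_regular.tsv (26 true edges, companion radius 0.88)
low     : wrote results/synthetic/panel_low.csv (6 x 9 x 8) and results/synthetic/truth_low.tsv (27 true edges, companion radius 0.89)
high    : wrote results/synthetic/panel_high.csv (6 x 9 x 8) and results/synthetic/truth_high.tsv (13 true edges, companion radius 0.75)

$ Rscript analysis/04_reported_network_consistency.R
regular : 26 edges, density 0.46; most regulated: U_PiCr (0.71 in), strongest regulator: S_Ca (0.71 out)
low     : 27 edges, density 0.48; most regulated: 1_25D (0.86 in), strongest regulator: S_Pi (0.71 out)
high    : 13 edges, density 0.23; most regulated: 1_25D (0.43 in), strongest regulator: FGF23 (0.57 out)
```

Reading step 4's output: multiplying each condition's degree centralities
by the 7 possible counterpart nodes yields integer degree sequences; the
package realizes each as a simple digraph (max-flow construction) and
recomputes the metrics, recovering the densities 0.46 / 0.48 / 0.23 and
the extreme centralities — the most-regulated and most-regulating analytes
per diet — from the degree tables alone.

Step 3 on the synthetic panels shows the flip side honestly: with only 6
subjects the pairwise test recovers few of the true edges (recall
0.08–0.23 in the run above; precision stays high). The method validation
(step 5, reduced replicates) prints, e.g.:

```
Granger size (null VAR, N=50 T=9, 150 reps): 0.080 (nominal 0.05)
Granger power (beta = 0.8, N=50 T=9, 150 reps): 1.000
Unit-root test size (random walks, N=20 T=50, 150 reps): 0.013 (nominal 0.05)
Edge-recovery F1 (sparse truth, N=30 T=9, 15 seeds): mean 0.835
```

In code, the same pipeline is one call:

```r
library(phosnet)
cfg <- pipeline_config(preset = "high", seed = 1, out_dir = "results/demo")
res <- run_pipeline(cfg)
res[["high"]]$report     # betweenness / outdegree / indegree / density table
res[["high"]]$hubs       # top node per metric, ties joined
```

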