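# timedrift

Sampling-time artifacts in single-cell transcriptomics: simulation,
detection, classification, correction, and mixing diagnostics.

## The problem

When blood samples wait hours between draw and cryopreservation, cells
respond: transcription shuts down globally, a small cold-shock module
(CIRBP/RBM3) switches on, and library sizes shrink — all increasing
with time at room temperature. Cells processed > 2 h after extraction
form a distinct technical class, and in cohort or biobank studies with
heterogeneous logistics this *sampling-time artifact* can dwarf the
biology of interest.

`timedrift` is for analysts of scRNA-seq cohort data who need to (a)
decide whether their dataset carries a sampling-time signal, (b)
quantify it against other variance sources, and (c) remove it while
preserving cell-type structure — plus a ground-truthed simulator to
validate every step.

## What it computes

* **Simulator** — gamma–Poisson counts with planted structure: for gene
  *g*, cell *c* at sampling time *t*,
  `mu_gc = mu_g * exp(r_g t) * marker * donor * batch * libsize(t)`,
  NB-distributed with gene-level dispersion; full per-gene/per-cell
  ground truth. HTO (cell-hashing) counts with doublets and negatives.
* **Demultiplexing** — CLR normalization per hashtag
  (`clr[i,c] = ln(x+1) − mean_c ln(x+1)`), k-medoids clustering with
  *k* = number of conditions, per-hashtag background thresholds at the
  0.99 quantile after trimming the top 0.5% as outliers; strict
  exceedance calls singlets, multiplets (≥ 2), negatives (0).
* **QC / normalization** — explicit threshold filters (including a
  full-length preset: 75,000–1,000,000 counts, ≥ 435 genes, ≤ 20%
  mitochondrial, gene mean ≥ 1), size factors `sf_c = N_c / mean(N)`,
  values `ln(1 + x/sf)`.
* **Signature** — per-gene two-sided Mann–Whitney rank-sum test of
  biased (> 2 h) vs unbiased (≤ 2 h) cells (tie-corrected normal
  approximation; exact enumeration for tiny groups), filtered at
  |logFC| ≥ 0.25 and adjusted p < 0.001; hypergeometric gene-set
  enrichment (term size in [3, 600), p < 0.05, odds ratio > 2);
  signature overlap with top-N harmonization.
* **Time score & classifier** — expression-bin-matched module score
  (25 bins, 100 controls/gene), unregularized logistic regression,
  rank-based AUC with a random-gene control signature.
* **Correction** — per-gene OLS of expression on the score, z-scored
  residuals (optionally per cell type); bootstrap silhouette across
  10–90% affected-cell fractions (300 cells × 25 replicates).
* **Diagnostics** — kBET acceptance rate (χ² test of local vs global
  label composition among k nearest neighbors; acceptance = % tested
  cells with p > 0.05), pairwise proportionality
  `rho_p = 2 cov / (var + var)`, per-gene ANOVA r², PC-weighted
  variance fractions.

## Worked example

```r
library(timedrift)
report <- run_pipeline(default_run_config(seed = 1))
print(report)
```

```
RunReport (seed 1 )
  simulated: 2000 genes x 1000 cells
  demux: singlet accuracy 0.966, doublet recall 1.000
  signature: 247 genes (13 up, 234 down)
  AUC: train 1.000, test 1.000 (random-gene control 0.567)
  silhouette 0.292 -> 0.006; kBET acceptance 0.0% -> 36.3%
```

Reading this: on a simulated 0 h vs 24 h experiment (two donors, 30% of
genes decaying at 0.05/h), hashed-pool demultiplexing recovered 96.6%
of singlets and flagged every doublet; differential expression on
donor 1 found a 247-gene signature dominated by downregulation (as the
planted artifact is); the module-score classifier transferred perfectly
to donor 2 while a same-size random-gene signature stayed near chance
(0.567); and regressing the score out collapsed the affected/unaffected
separation (average silhouette width 0.292 → 0.006) while improving
mixing across time points (kBET acceptance 0% → 36.3%). Cell-type
silhouette is essentially untouched by the correction (see
`report$stages$correct`).

Stage functions are usable à la carte — e.g.

```r
sim  <- simulate_counts(sim_config(seed = 1))
norm <- size_factor_normalize(filter_genes(sim$matrix, 10))
dea  <- wilcoxon_dea(norm, attr(norm, "cell_data")$affected)
sig  <- define_signature(dea)
```

A thin command-line wrapper lives at `inst/cli/timedrift.R`
(`run`, `simulate`, `demux` subcommands); YAML configuration is read
with `read_run_config()`.

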