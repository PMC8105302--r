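# tuftdyn

Statistical toolkit for dual-fluorescence reporter studies of intestinal
tuft-cell maturation. In this experimental design, rare chemosensory tuft
cells are tracked through their maturation along the crypt–villus axis with
two promoter-driven fluorophores — GFP under *Trpm5* (all tuft cells) and
mCherry under *Gpr64* (mature tuft cells) — and profiled three ways:

* **bulk RNA-seq of sorted populations** (non-tuft background, young tuft
  G+R−, mature tuft G+R+) from the same mice, a paired three-population
  design;
* **organoid time-lapse imaging**, recording when each reporter switches on
  in each cell;
* **a receptor qPCR array** comparing sorted mCherry-positive and -negative
  cells.

tuftdyn implements the corresponding analyses for anyone running this kind
of dual-reporter maturation study, plus a seeded synthetic-data generator
with planted ground truth so the whole pipeline is testable end to end.

## What it computes

**Paired NB differential expression.** Per gene, a negative-binomial
log-link GLM with design `~ mouse + population` and offset
log *s*<sub>j</sub> (median-of-ratios size factors):

  log μ<sub>gj</sub> = log s<sub>j</sub> + β<sub>g0</sub> + β<sub>g,mouse(j)</sub> + β<sub>g,pop(j)</sub>,  Var = μ + αμ²

fit by batched IRLS with per-gene moment dispersions; Wald tests
(β̂/SE, normal reference, two-sided) for the three pairwise population
contrasts; BH adjustment; strict selection at padj < 0.05 and
|log₂FC| > 1; top-50 lists per direction at p < 0.01; and
log₂(x+1)-normalized marker-panel matrices.

**Signed-score MWW geneset enrichment.** Genes are scored
s<sub>g</sub> = −log₁₀(p<sub>g</sub>)·sign(log₂FC<sub>g</sub>); each geneset
(GMT, filtered to 10–500 members in the scored universe) is tested by a
two-sided Mann–Whitney–Wilcoxon rank test of members vs non-members
(mid-ranks, tie correction, continuity correction; exact U distribution for
small tie-free cases), Bonferroni-flagged at α/M. Volcano coordinates per
set: x = the members' log₂FC weighted by −log₁₀ p, y = −log₁₀ p<sub>enrich</sub>.

**Reporter dynamics.** Track classification into transition (G+R− → G+R+),
GFP-only, both-throughout, mCherry-only; onset = first persistent on-frame;
lag = mCherry onset − GFP onset with left-censoring handling; mean ± SEM
lag summaries; crypt/villus double-positive fractions per animal with
region means ± SEM.

**ΔΔCt.** Relative expression 2^(−ΔCt) and fold enrichment 2^(−ΔΔCt)
against a housekeeping gene, with an annotated positive-vs-negative scatter
table.

## Worked example

```r
library(tuftdyn)

sim <- simulate_counts(sim_config(n_genes = 5000, n_de_genes = 300,
                                  de_lfc = 2, library_size_mean = 5e5,
                                  seed = 1))
sim$cm
#> count_matrix: 5000 genes x 15 samples
#> populations: 5/5/5  mice: 5

sf   <- size_factors(sim$cm)
disp <- estimate_dispersion(sim$cm, sf)
de   <- fit_paired_nb_wald(sim$cm, sf, disp,
                           contrast = c("mature_tuft", "young_tuft"))
sel  <- select_de(de)
nrow(sel)
#> [1] 276     # of 300 planted genes, at padj < 0.05 and |log2FC| > 1
head(sel[order(sel$padj), c("gene_id", "base_mean", "log2fc", "se", "padj")], 3)
#>       gene_id  base_mean   log2fc         se         padj
#> 4   gene00004  594.32271 1.993000 0.09613296 8.947730e-92
#> 292 gene00292   73.19042 2.036917 0.13398919 8.543301e-49
#> 160 gene00160 1178.86278 2.175254 0.15593011 5.218414e-41

scores <- signed_scores(de)
gs  <- simulate_genesets(scores$gene_id, n_sets = 200,
                         size_range = c(10, 200), n_planted = 5,
                         de_genes = sim$truth$gene_id[sim$truth$planted],
                         seed = 2)
enr <- enrich_collection(scores, gs$sets)
sum(enr$bonferroni_significant)
#> [1] 5        # exactly the five planted sets, at alpha/M = 2.5e-04
head(enr[order(enr$p_enrich), c("set_name", "n_in", "z", "p_enrich", "x_volcano")], 3)
#>   set_name n_in        z      p_enrich x_volcano
#> 3  set0003  169 21.34675 4.180272e-101  1.981480
#> 4  set0004  145 19.61900  1.064301e-85  1.985697
#> 1  set0001   94 15.89929  6.409043e-57  2.010664

tr  <- simulate_tracks(track_sim_config(seed = 3))   # 119-cell cohort
lag <- summarize_lags(classify_tracks(tr$tracks))
sprintf("onset lag: %.1f h +/- %.1f SEM (n = %d)", lag$mean_h, lag$sem_h, lag$n)
#> [1] "onset lag: 11.1 h +/- 0.4 SEM (n = 61)"
```

The planted log₂ fold change of 2 is recovered (estimates ≈ 1.99–2.18 for
the top genes, weighted-mean set log₂FC ≈ 1.98–2.01), all five planted
genesets clear the Bonferroni threshold, and the estimated reporter-onset
lag lands within half a frame interval of the generator's 10.8-h mean.

`run_pipeline(default_run_config(seed = 1, out_dir = "run"))` chains all
stages (simulate → DE → enrichment → panels → time-lapse → qPCR) and writes
every table plus a `manifest.json` with md5 checksums; reruns with the same
seed are byte-identical. A thin CLI over the same functions lives at
`inst/scripts/tuftdyn-cli.R` (subcommands `simulate`, `de`, `enrich`,
`panels`, `timelapse`, `qpcr`, `run-all`).

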