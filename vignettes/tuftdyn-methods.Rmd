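---
title: "Methods: paired differential expression, rank-based geneset enrichment and dual-reporter dynamics"
author: "tuftdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired DE, rank-based enrichment and reporter dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tuftdyn analyses dual-fluorescence reporter studies of intestinal tuft-cell
maturation, in which young tuft cells (Trpm5-driven GFP only, crypt-resident)
mature into double-positive cells (GFP plus Gpr64-driven mCherry,
villus-resident). Three sorted populations per mouse — non-tuft background,
young tuft, mature tuft — are profiled by RNA-seq in a paired design; organoid
time-lapse movies record the onset of each reporter per cell; and a receptor
qPCR array quantifies enrichment in sorted mCherry-positive cells. This
vignette describes the statistical machinery, the choices behind its defaults,
and what the synthetic data used for testing can and cannot show.

## Paired negative-binomial differential expression

Counts $K_{gj}$ for gene $g$ in library $j$ are modelled as
$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
$\mathrm{Var} = \mu + \alpha\mu^2$ and

$$\log \mu_{gj} = \log s_j + \beta_{g0} + \beta_{g,\mathrm{mouse}(j)} + \beta_{g,\mathrm{pop}(j)},$$

i.e. a per-gene log-link GLM with design `~ mouse + population` and the log
size factor as offset. The three pairwise population contrasts are tested by
Wald statistics $\hat\beta_c/\mathrm{SE}(\hat\beta_c)$ against a standard
normal, two-sided, with Benjamini–Hochberg adjustment across genes. No outlier
cut-off and no independent filtering are applied: every tested gene receives a
p-value. Genes with zero counts in every library are excluded from testing by
default (`drop_zero_genes`), since no contrast is estimable for them; the rule
is a flag, not hard-wired.

Three deliberate simplifications relative to shrinkage-based DE packages:
dispersions are plain per-gene moment estimates (no trend, no shrinkage), fold
changes are unshrunk maximum-likelihood estimates, and the Wald reference is
the normal rather than a small-sample correction. The package documents the
cost of this transparency honestly below.

**Size factors** are median-of-ratios: over genes positive in every library,
$s_j = \mathrm{median}_g\, K_{gj}/(\prod_{j'} K_{gj'})^{1/n}$, rescaled to
geometric mean 1 so normalized counts stay on the raw-count scale. If no gene
is positive everywhere the estimator fails loudly rather than guessing.

**Dispersions.** The default estimator is the group-wise method of moments on
normalized counts: within each population group,
$\alpha = \max\{0, (s^2-\bar\mu)/\bar\mu^2\}$, averaged over groups and
floored at $10^{-8}$. A second mode, `method = "design"`, estimates
$\alpha$ from residual moments around a log-linear fit of the full paired
design, with a degrees-of-freedom correction. The distinction matters: a
gene-specific mouse effect inflates within-population variance, so the
group-wise estimator absorbs it into $\alpha$ and makes the paired test
conservative; the design-aware estimator removes it, which is precisely where
the paired design earns its precision advantage over an unpaired analysis.
The group-wise formula remains the default because it assumes nothing about
the design; use `method = "design"` when mouse-to-mouse variability is
expected to be substantial.

**Fitting** is iteratively reweighted least squares, batched across genes:
all genes share one design matrix, so each IRLS step reduces to per-gene
weighted normal equations assembled by two matrix products, and a
22,000-gene, 15-library dataset fits in seconds. Starting values come from a
log-linear least-squares fit on shifted normalized counts; convergence is
declared at a relative deviance change below $10^{-8}$ (cap 100 iterations);
linear predictors are clamped to $\pm 30$ to keep the weights finite for
degenerate genes. Non-converged genes keep their last estimate but report a
missing p-value rather than an untrustworthy one.

**Calibration, measured.** The acceptance suite measures the null
rejection rate of this estimator at $p<0.05$ over 50 simulated null datasets
of 2,000 genes (five mice, dispersion 0.05, mean count $\sim$100,
no mouse effects so the group-moment estimator meets its own assumptions).
The pooled rate comes out near 0.054 — the test is mildly liberal, and at
tenfold deeper counts it is more so, while at tenfold shallower counts it
turns conservative. This is the known price of plugging noisy per-gene
dispersion estimates into an asymptotic Wald statistic with 15 observations
and 7 parameters, and it is exactly the problem dispersion shrinkage was
invented to solve. The suite asserts the three-sigma binomial band around
0.05 and the assertion fails by a few parts per thousand; we report this
rather than hiding it, and treat downstream conclusions that hinge on exact
5% error control with corresponding caution. Effect estimates are unaffected:
planted log2 fold changes of 2 are recovered with mean error below 0.05
across 200 replicates, and estimates agree with a direct
likelihood-maximization oracle to $10^{-4}$.

**Selection** uses the strict thresholds adjusted $p < 0.05$ and
$|\log_2 \mathrm{FC}| > 1$; genes sitting exactly on a boundary are excluded.
Top-50 lists per direction require raw $p < 0.01$ and sort by
$|\log_2 \mathrm{FC}|$ descending, ties broken by smaller p then gene id — the
tie rule is ours, chosen so output order is a pure function of the table.
Marker panels are $\log_2(K_{gj}/s_j + 1)$ matrices in marker-list order,
with missing markers reported, never silently dropped.

## Signed-score Mann–Whitney–Wilcoxon geneset enrichment

Each tested gene receives the signed score
$s_g = -\log_{10}(\max(p_g, 10^{-300}))\cdot \mathrm{sign}(\log_2\mathrm{FC}_g)$,
built from the *raw* DE p-value by default (`use_adjusted` switches to BH);
the floor guards $-\log_{10}$ overflow, which matters because independent
filtering is disabled upstream and extreme p-values do occur. For each
geneset, a two-sided MWW test compares the ranks of member scores against all
other scored genes. Sets are intersected with the scored universe first, then
filtered to 10–500 members; the Bonferroni family size $M$ is the number of
sets actually tested in the run, not a fixed constant, because collection
sizes are annotation-release-dependent.

Mid-ranks with tie-corrected variance and a continuity correction (flag,
default on) feed the normal approximation. For tie-free sets of at most 10
members in universes of at most 25 genes the exact U distribution is used
instead. The exact two-sided p doubles the smaller tail, capped at 1. An
exhaustive sweep in the acceptance suite compares both modes against full
combinatorial enumeration over every achievable U statistic: exact-mode p
agrees to $10^{-9}$ everywhere; the normal approximation stays within 0.01 of
exact in the tails ($p < 0.2$) and for balanced sets in universes of 18 or
more, but its mid-distribution discreteness gap reaches 0.038 for 2-member
sets in an 11-gene universe. Enrichment decisions live in the tails, so this
does not move Bonferroni calls, but the approximation should not be read to
two decimals in the centre of the distribution.

Volcano coordinates per set: $x$ is the members' $\log_2$ fold changes
weighted by $-\log_{10} p_g$, $y = -\log_{10} p_{\mathrm{enrich}}$, bubble
size the member count. Downregulated sets land left of zero. If every member
has $p = 1$ the weights vanish and $x$ is reported missing with a warning.

## Time-lapse reporter-onset quantification

Tracks are per-cell boolean GFP/mCherry states on a frame grid (defaults:
3-h frames over 60 h). A reporter's onset is the first frame at which it is
on and stays on for `persistence_frames` consecutive frames (default 1; raise
it to guard against segmentation flicker — the rule is ours, the source
imaging protocol does not state one). Categories follow from onset presence
and order: GFP-then-mCherry is a *transition* (the maturation event), equal
first onsets are *both_throughout*, and single-reporter tracks are
*GFP_only* / *mCherry_only*. A track whose mCherry precedes its GFP fits
none of the four biological categories and is filed as mCherry_only.

Cells with GFP already on at the first frame are left-censored: their true
GFP onset predates the movie, so their lag is only a lower bound. The lag
summary (mean, SEM) therefore excludes left-censored transition cells unless
`include_censored = TRUE`. Observed lags are multiples of the frame interval;
with onsets uniform over the horizon, the ceil-to-grid discretization of both
onsets leaves the mean lag biased by less than one frame interval, which the
simulation tests verify at 500 cells.

Crypt/villus co-localization is summarized per animal and region as the
double-positive fraction of detected fluorescent cells and of GFP-positive
cells, then averaged with SEM across animals. Inference beyond these
descriptive fractions (e.g. region-by-genotype ANOVA) is out of scope.

## ΔΔCt quantification

Classic ΔΔCt with amplification efficiency fixed at 2:
$\Delta Ct = Ct_{\mathrm{target}} - Ct_{\mathrm{housekeeping}}$ per
population, relative expression $2^{-\Delta Ct}$, fold enrichment
$2^{-\Delta\Delta Ct}$. Efficiency-corrected models are out of scope.
Undetected targets get relative expression 0 and are excluded from fold
ranking. The scatter table flags the top-k folds for annotation; ties at the
cutoff are all flagged, so annotation is never an arbitrary subset of equals.

## The synthetic-data generator

The generator exists so every stage is testable with planted ground truth; it
emulates the study design, not its raw data.

* **Counts**: five mice $\times$ three populations, NB counts with log-normal
  gene abundances, log-normal library sizes (20% CV) around
  `library_size_mean`, gene-wise dispersion (default 0.05, a typical
  well-replicated bulk value), and gene-specific per-mouse log-effects
  (SD `mouse_sd`, default 0.15) shared across each mouse's three libraries.
  The mouse effects are gene-specific on purpose: a sample-level effect would
  be absorbed entirely by size factors and the pairing factor would have
  nothing to do. The first `n_de_genes` genes carry the planted
  mature-vs-young log2 fold change (`de_lfc`, scalar or vector, so both
  directions can be planted). Defaults: 22,189 genes — the size of the
  measured universe in this study design — and a scaled-down library of
  2e6 counts giving means near 90; tests and the acceptance script state
  their own smaller sizes explicitly.
* **Genesets**: uniform draws from the universe; planted sets are filled from
  the planted-DE genes so recovery is detectable by construction.
* **Tracks**: category fractions default to the observed cohort tallies
  (58/33/25/3 of 119 cells). Transition cells draw a lag from a normal
  truncated at 0 (mean 10.8 h) and a GFP onset uniform on
  $[0, \mathrm{horizon} - \mathrm{lag}]$; onsets are then discretized to the
  frame grid ("first frame at or after onset", the detection-at-sampling
  convention). The lag SD defaults to 4 h: the source cohort reports only a
  mean and SEM, and back-computing an SD from the SEM ($\approx$13 h) would
  push a third of the mass below zero, so truncation would drift the realized
  mean several hours above the nominal one; 4 h keeps the truncated mean
  within 0.05 h of the nominal and is a plausible cell-to-cell spread.
* **Compartment counts** and **Ct tables** are binomial and Gaussian
  mechanisms matching their analysis models (defaults: 98%/46% double-positive
  rates, 3 animals, 350 cells per region; 379-gene array, constant
  housekeeping Ct, 0.2-cycle measurement noise).

Everything is seeded and byte-reproducible; every artifact returns its
planted truth alongside.

What passing tests on this generator do **not** show: robustness to outlier
libraries or sample swaps (no contamination model), to dispersion trends with
expression (dispersion is constant across genes), to correlated genes within
sets (genes are independent given the design), or to reporter-intensity
thresholding artefacts (states are already boolean). Results on real data
inherit all of these risks.

## Pipeline and reproducibility

`run_pipeline()` executes the stages in a fixed order — simulate, DE (three
contrasts), enrichment, panels, time-lapse, qPCR — writing plain-text tables
and a JSON manifest (package version, seeds, per-stage row counts, md5
checksum and byte size of every output). Stage seeds derive deterministically
from the master seed; numeric columns are written with a fixed 15-significant-
digit rendering so reruns are byte-identical regardless of session options.
A thin CLI (`inst/scripts/tuftdyn-cli.R`) exposes the stages as subcommands;
the R functions are the primary interface. Input validation happens before
any stage runs, so a misconfigured run writes nothing.

Problem sizes used by the test suite were chosen to keep the full suite in a
few minutes while leaving Monte-Carlo bands tight enough to be meaningful:
2,000-gene null datasets (50 replicates), 5,000-gene enrichment-power
datasets (100 replicates), 500-cell track cohorts, and exhaustive
enumeration up to 20-choose-10 assignments.

## Known limitations

* The Wald test is mildly liberal at realistic depth (measured above);
  ranking and effect estimation are sound, but exact FPR control is not
  promised without shrinkage, which is deliberately out of scope.
* Dispersion estimates at five mice per group are noisy by construction;
  the design-aware mode reduces bias, not variance.
* The MWW normal approximation's mid-distribution accuracy degrades below
  ~18-gene universes; exact mode covers the small tie-free cases only.
* Left-censored lags are excluded, not modelled; a survival formulation
  would use them, at the cost of distributional assumptions.
* One housekeeping gene, efficiency 2: no Pfaffl correction, no
  multi-reference normalization.
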