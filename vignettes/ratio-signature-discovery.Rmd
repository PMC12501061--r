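---
title: "Discovering prognostic gene-ratio signatures from co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering prognostic gene-ratio signatures from co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

In bulk tumour transcriptomics, survival-associated expression signal is
rarely carried by single genes. Co-expression network analysis groups genes
into modules whose shared pattern is summarized by the module eigengene
(ME, the first principal component of the standardized module members
across samples). In lung adenocarcinoma, two strongly anti-correlated
modules — one whose expression rises with stage and mortality, one that
falls — frame a natural prognostic contrast.

`ratiosig` implements a discovery pipeline built on that contrast:

1. **Preprocess** FPKM-like expression: drop transcripts with \(\ge\) 50%
   zeros, log2-transform with a pseudocount of 1, remove connectivity
   outlier samples, drop samples with incomplete staging/age/sex
   annotation, and regress age and sex out of each gene (residual plus the
   gene mean, so the scale is preserved).
2. **Fit the network**: biweight midcorrelation (bicor), soft-thresholded
   adjacency, topological overlap, average-linkage clustering, a static
   cut, module merging by ME correlation, and a kME membership cleanup.
   Modules are correlated to numerically encoded clinical traits with
   pairwise-complete bicor and Student p-values.
3. **Stage differential expression**: per-gene one-way ANOVA and Tukey HSD
   across stages, Welch t for two-group contrasts, Benjamini–Hochberg FDR,
   and DEG calls at FDR < 0.05 with |log2 fold change| strictly > 0.5.
4. **Nominate candidates** as the differentially expressed hubs (top 10% of
   module members by kME) of the most anti-correlated module pair, the
   numerator side coming from the module whose ME correlates negatively
   with death.
5. **Enumerate and rank ratio signatures**. For candidate sets \(N\) (high
   expression, good prognosis) and \(D\) (high expression, poor prognosis)
   every equal-sided combination \(k:k\), \(k \le 4\), defines a per-sample
   score
   \[
     s_j \;=\; \frac{\sum_{g \in N'} x_{gj}}{\sum_{g \in D'} x_{gj}},
     \qquad N' \subseteq N,\; D' \subseteq D,
   \]
   on normalized abundances. At each survival horizon \(t \in\)
   {12 mo, 18 mo, 3 y, 5 y, 10 y} the outcome is binarized (dead by
   \(t\); censored-before-\(t\) samples excluded), a logistic model is
   fitted, and the ROC AUC with a DeLong confidence interval and
   Youden-threshold confusion metrics is recorded. Combinations are ranked
   by mean AUC over a horizon subset; gene frequency among the top 100 is
   reported for the next nomination round.
6. **Survival analysis** of any score: median split (ties to the low tier),
   Kaplan–Meier curves, and a univariate Cox fit (Breslow ties) with Wald
   p and 95% CI.
7. **Signature comparison**: arbitrary signatures are scored with the same
   ratio, correlated to MEs and to observed survival times (uncensored
   samples), cross-correlated by Pearson, and compared pairwise with the
   paired DeLong placement-value test.

## A worked run

```{r, eval = FALSE}
library(ratiosig)
run <- run_full_pipeline(run_config(sim = sim_params(seed = 1)))
print(run)
summary(run$search)
```

## Normalization for ratio scoring

The scoring matrix uses a three-step normalization: `log2(x + 1)`,
per-sample median centring, and per-sample scale normalization (each
sample divided by its root mean square). The third step harmonizes dynamic
range across samples and platforms. Per-gene median centring is
deliberately **not** applied before ratio scoring: it would centre every
gene at zero, so the signature sums in numerator and denominator would
cross zero sample by sample and the ratio's sign — hence its ranking —
would be meaningless. In our experiments a gene-centred matrix reduces the
correlation between the ratio score and the underlying prognostic factor
to approximately zero. `cluster3_normalize(center_genes = TRUE)` remains
available for correlation-based analyses where gene centring is harmless.

Sample-level centring and scaling cancel within a ratio of same-sample
sums; what matters for score stability is that signature genes be well
expressed relative to the per-sample median, which holds for the
well-expressed hub genes the nomination step selects. A denominator-sum
guard (|sum| < 1e-9) nulls the score for degenerate samples and logs the
exclusion.

## Network construction choices

**Adjacency.** The default is the *signed hybrid* adjacency
\(a_{ij} = \max(r_{ij}, 0)^\beta\). An unsigned network
(\(|r|^\beta\)) connects anti-correlated genes: in data with two opposing
modules whose strongest members correlate at \(|r| \approx 0.8\) across
modules, unsigned topological overlap bridges the two modules into one.
The signed hybrid keeps anti-correlated modules apart while rejecting
uncorrelated background as sharply as an unsigned network (the fully
signed \(((1+r)/2)^\beta\) compresses that contrast and lets background
genes attach to modules). Both alternatives remain available through
`network_config(signed = )`.

**Power.** \(\beta = 6\), the conventional choice for unsigned-type
adjacencies; `beta = NULL` scans a candidate grid for the smallest power
whose connectivity distribution reaches a signed scale-free fit
\(R^2 \ge 0.8\) (occupancy-binned regression of \(\log_{10} p(k)\) on
\(\log_{10} k\), sign taken from the slope).

**Cut height.** A fixed fraction-of-maximum cut cannot track how strongly
\(\beta\) and the correlation level compress topological-overlap
distances toward 1: a cut that separates modules at one density merges or
shreds them at another. The default is therefore an adaptive static cut:
over a grid of merge heights, choose the height that maximizes the number
of clusters with at least `min_module_size` genes (clusters holding more
than half the network are the unclustered remainder and are not counted);
ties resolve to the highest such height. The rule is deterministic, and a
fixed `cut_height` fraction can still be supplied.

**Membership cleanup.** After cutting and merging, members whose
own-module kME falls below 0.3 are reassigned to the unassigned pool and
the minimum size is re-applied — the usual guard against loosely attached
background genes inflating modules.

**Merging.** Modules whose MEs correlate above 0.75 are merged, iterated
to a fixpoint; labels are renumbered by decreasing size (M1 largest).

## What the generator emulates

`generate_dataset()` plants the structure the pipeline is designed to
find, with ground truth for recovery testing. Defaults are the package's
study conditions:

* **Two anti-correlated blocks** of 150 genes over 1700 background genes,
  300 samples. The block factors \(f_1\) (protective) and \(f_2\)
  (adverse) are bivariate normal with correlation \(-0.85\).
* **A planted 4+4 signature.** Four genes per block load purely on the
  block factor with loading 2; the remaining block genes load
  U(0.3, 0.6) on the mixture \(0.85 f_b + \sqrt{1-0.85^2}\, u_b\), where
  \(u_b\) is a shared, non-prognostic within-block nuisance factor. This
  purity structure reflects cohorts in which a module tracks outcome but
  only a core of members carries the outcome signal — and it is what
  makes a specific gene core identifiable at all: if every block gene
  were an equally pure factor proxy, any four-gene sum would be
  statistically equivalent and top-of-ranking membership would be a
  lottery among tens of thousands of near-ties.
* **Noise** is set so mean within-block pairwise correlation is 0.5,
  typical of real co-expression modules.
* **Baselines**: planted genes draw log2 baselines in 7–9, other block
  genes 5–9, background genes a right-skewed gamma(1.5, 1.5). After
  exponentiation this yields an FPKM-like right-skewed dynamic range in
  which well-expressed signature genes sit far above the per-sample
  median (a requirement for stable ratio scores, see above). The lowest
  20% of the FPKM matrix is thresholded to zero, reproducing the input
  regime of the \(\ge\) 50%-zero filter.
* **Stage** follows a cumulative-logit model shifted by the standardized
  disease contrast \((f_2 - f_1)\) with effect 1.5 per step and baseline
  stage marginals of roughly 53/25/17/5%, so both blocks show
  early-stage differential expression of opposite sign with the planted
  genes well past the |L2FC| > 0.5 cutoff (about 1.3) and ordinary
  members mostly below it (about 0.3).
* **Survival** is exponential with log-hazard
  \(\log(5\times10^{-4}) - f_1 + f_2\) per day (median survival around
  1400 days at the factor origin), with independent exponential censoring
  (rate \(3\times10^{-4}\)) capped at 10 years — roughly a 60% event
  fraction.

What the generator does *not* emulate: batch structure, library-size or
GC biases, gene-length effects, count noise (values are log-normal, not
negative-binomial), more than two signal modules, and any correlation
between clinical covariates (age, sex) and expression. Passing recovery
tests therefore demonstrates the pipeline's statistical machinery, not
robustness to those real-data artefacts.

## Numerical and procedural details

* **bicor** uses median/MAD standardization with Tukey biweights
  \((1-u^2)^2\) inside \(|u|<1\), \(u = (x-\mathrm{med})/(9\,\mathrm{MAD})\);
  zero-MAD vectors fall back to Pearson standardization with a warning.
* **Outlier removal** standardizes per-sample connectivity
  \(k_i = \sum_{j \ne i} r_{ij}\) (Pearson on log2 values) and removes
  \(|z| > 3\) in a single pass; `upper_only` gives the literal one-sided
  reading.
* **AUC** is the Mann–Whitney concordance (ties count half). During
  exhaustive enumeration only the AUC is computed, oriented as
  \(\max(a, 1-a)\) — identical to the in-sample AUC of fitted
  probabilities from a single-covariate logistic model, by monotone
  invariance — which keeps 60k-combination searches tractable; the
  top-ranked block is re-evaluated with the actual logistic fit, DeLong
  CI/p and Youden-threshold confusion metrics.
* **Ranking** defaults to the mean AUC excluding the 5- and 10-year
  horizons (`no5y10y`), where long-horizon binarized outcomes rest on few
  long-term survivors; `all` and `no10y` subsets are available. Ties break
  by the all-horizon mean, then signature name, so rankings are
  reproducible bit for bit.
* **Candidate pools** are capped at 8 per side (twice the maximal side
  size), keeping the enumeration at the scale of a first-round pool; when
  the hub/DEG intersection is degenerate (< 2 genes) the top 4 hubs by
  kME stand in, the smallest pool that still supports 4:4 ratios.
* **Cox fits** use Breslow tie handling and Wald inference (matching the
  reported statistic class); monotone-likelihood fits are flagged with
  infinite CI markers rather than dropped.
* **Fixed-horizon binarization** excludes samples censored before the
  horizon; `binarize_outcome` documents the rule (dead-by-t = 1,
  survived-past-t = 0, censored-before-t = excluded).
* **Enrichment** is an upper-tail hypergeometric test of module gene
  lists against GMT collections, intersected with the analysis universe
  (the genes surviving preprocessing, not the genome), BH-adjusted per
  module.

## Known limitations

At realistic cohort sizes (n = 300), the AUC difference between a
top-ranked combination and near-miss combinations sharing most of its
genes is of the same order as single-gene selection noise (~0.01–0.03
AUC), so the exact membership of the top 10 is not fully stable across
replicates even when the nominated pools contain the full planted core.
Recovery assessments should therefore be read at the gene-overlap level
(how many planted genes appear in a top signature), as the package's
validation suite does, rather than expecting the exact planted
combination at rank 1. Aggregation over the top 100 (gene frequency) is
the more stable statistic and drives the refinement round.

The exhaustive search is in-sample: reported AUCs of top-ranked
combinations are optimistically biased by selection, as any ranked search
is. External validation — scoring frozen signatures on an independent
cohort via `score_signatures()` and `evaluate_signature()` — is the
intended guard; the package implements the harmonized scoring path but
ships no external cohort data.

Problem sizes used by the validation suite: unit tests run on reduced
instances (120–150 samples, 400–600 genes, 60-gene blocks); the
recovery and calibration checks use the full default conditions
(300 samples, 2000 genes), 10 seeded discovery runs, 500-replicate
DeLong calibration and 1000-replicate CI coverage.
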