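---
title: "Methods behind dyadomics: validated chemometrics for a longitudinal dyad design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind dyadomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadomics)
```

## The analytical problem

A single mother–infant dyad sampled densely from day 103 to day 268 after
birth yields three linked tables: stool metabolite concentrations (32
samples over five sets of consecutive days), stool 16S OTU relative
abundances (25 of those samples), and paired breast-milk profiles over the
lactation window (days 103–175). Diet defines three periods — exclusive
breastfeeding (BM, day blocks 103–108 and 145–147), breastfeeding plus a
fruit snack (FBM, 165–175), and weaning (W, 219–228 and 262–268). The
questions are classification-shaped (do fecal profiles discriminate diet
periods, and which variables drive that), integration-shaped (what
covaries between metabolome and microbiota), and trend-shaped (how does
milk composition evolve with lactation day).

With so few samples and 49–97 variables, naive fitting overstates
everything. The package therefore couples every supervised model to
repeated double cross-validation and permutation nulls, and treats the
marker list as a stability statement (rank products) rather than a single
fit's coefficients.

## Data model

All stages consume a `feature_table` — a numeric samples × variables matrix
with unique, case-sensitive ids and an optional per-variable class label —
plus a `sample_metadata` table (day after birth, day block, diet period;
the period is a deterministic function of the block). Missing or
non-finite cells are a hard loader error, not imputed: the workflow assumes
fully quantified tables, and silent imputation at n = 32 would distort
every downstream variance estimate. Multi-block models require an aligned
`block_set`: all blocks restricted to the intersection of sample ids, in
the first block's order.

## The synthetic dyad generator

No concentration tables are publicly deposited for this design, so the
package ships a generator whose defaults *are* the study conditions: 32
stool samples allocated (6, 3, 10, 8, 5) across the five day blocks (9 BM,
10 FBM, 13 W), 49 metabolites, 48 OTUs, 16S data for 25 of 32 samples
(the last 7 sample ids are dropped deterministically, since nothing
specifies which samples lacked sequencing), and paired start/end-of-suction
milk rows on the 19 lactation-window days.

Concentrations are log-normal with a detection floor at `1e-3`: period
effects enter as additive shifts on the log scale, and `effect_size` (default
2.0) is that shift in units of the within-period log-scale standard
deviation (`noise_sd`, default 1.0). The structured variables are:

* 8 HMO-class oligosaccharides — high in BM, reduced in FBM, and fixed at
  the detection floor in W (fucosylated milk sugars disappear from stool
  after weaning);
* 3 SCFA-class and 6 amino-acid-class variables — shifted up in W;
* 2 variables elevated *only* in FBM (1,2-propanediol-like and
  formate-like), mimicking fruit-fermentation intermediates;
* the remaining 30 are nulls.

Within-period correlation comes from `n_factor` latent factors per period
with N(0, 0.3²) loadings — metabolite panels are never independent, and the
correlation-network stage needs correlated structure to find. The OTU table
is logistic-normal (softmax of a Gaussian field, rows closed to 100), which
unlike a Dirichlet allows factor-induced correlation between taxa:
Firmicutes/Proteobacteria/Actinobacteria dominate, all
Bacteroidetes-phylum genera are parameterized below 1% total mean
abundance, a Bifidobacterium-like genus has high mean and high variance
independent of period, and Ruminococcus-like/Lachnospiraceae-like genera
shift up in W. Milk variables carry linear-in-day log-scale trends (one
increasing 3′FL-like, five decreasing) and an end-of-suction lactate shift
of `0.3 × effect_size` log units.

Ground truth (marker ids, trend signs, factor loadings) is returned with
every table. The generator emulates the *statistical* structure the
analysis assumes — it does not emulate NMR peak overlap, sequencing depth,
count noise, or compositional artifacts of read normalization, so passing
recovery tests show the machinery works under the assumed model, not that
the model captures everything in real dyad data.

## Preprocessing rules

* **Autoscaling** uses the n−1 sample standard deviation. A zero-variance
  variable is an error naming the variable — silently dropping columns
  inside a fitted pipeline is how variables disappear unnoticed.
* **OTU inclusion** keeps OTUs strictly exceeding 1% relative abundance in
  at least one sample. "Exceeds 1%" is ambiguous between per-sample, mean
  and any-sample readings; any-sample is the most inclusive and the
  alternative (`mode = "mean"`) is a flag away. Rows are *not* re-closed
  after filtering: retained abundances stay as measured.
* **Block scaling** divides a block by its Frobenius norm so each block
  enters fusion with equal total variance.

## PLS-DA and its validation

The core fit is NIPALS PLS1 with y-deflation on a ±1 class encoding
(threshold 0; an exact 0 goes to the first-listed class,
deterministically). The ±1 encoding makes the DQ² clipping bounds the
labels themselves: residuals are zeroed when a prediction overshoots its
own label in the correct direction, so DQ² never punishes confident correct
answers and always dominates the classical Q² on the same predictions.

Repeated double cross-validation: per repetition, a stratified 5-fold outer
split; per outer fold, a stratified 5-fold inner CV on the outer-training
set picks the LV count (1..10) minimizing mean inner NMC, ties going to
fewer LVs; the outer model is then refit on the full outer-training set —
with autoscaling re-estimated inside the fold, so the held-out fold never
touches scaling, LV selection, or fitting — and predicts the held-out fold.
Five folds are the practical ceiling: the smallest class in the BM-vs-FBM
comparison has 9 members. Each outer fit contributes a coefficient ranking
(|B|, largest = rank 1, exact ties broken by variable order so each ranking
is a true permutation); the rank product is the geometric mean over all
repetitions × folds, computed in log space, and the marker rule is RP
strictly below the arithmetic mean RP.

Permutation tests shuffle labels once per randomization and run a *single*
double-CV pass per shuffle; the observed statistic is the repetition mean
of each figure of merit. Running all 50 repetitions for each of 1000
shuffles would multiply cost 50-fold without changing the null being
estimated. p-values use the add-one convention, so the smallest attainable
p is 1/(n_perm + 1) — with 1000 randomizations, p below 1e-3 cannot be
claimed.

## ComDim and MB-PLSDA

ComDim (CCSWA) iterates, per component, the dominant eigenvector of the
salience-weighted sum of association matrices Σⱼ λⱼ XⱼXⱼ′, updating
λᵢⱼ = t′XⱼXⱼ′t until the saliences move < 1e-10 (max 100 iterations, both
configurable; the method converges in a handful of iterations at these
sizes). Working on the n × n association matrices rather than variable
space keeps every fit trivial at n ≤ 32. Scores are kept unit-norm so the
saliences carry the block-variance magnitude; with a single block the
procedure reduces to PCA component by component, which the tests verify.
Component signs everywhere follow one convention: the largest-|loading|
element is made positive. The default of two common components matches how
such score plots are read (a 2-D map); more are available via `K`.

MB-PLSDA concatenates the autoscaled, Frobenius-scaled blocks row-wise and
delegates to the same rDCV/permutation machinery. Inside cross-validation
the preprocessing must be re-estimated per training fold; after
autoscaling, a block's Frobenius norm is exactly √(p_block·(n−1)), and the
common (n−1) factor cannot change PLS predictions, so within-fold block
equalization reduces to constant per-variable weights 1/√p_block — applied
after the fold's autoscaling. This makes fold-honest block scaling exact
rather than approximate.

## Networks and trends

Pearson correlations get two-tailed p-values from
t = r√((n−2)/(1−r²)) on n−2 df, and the display mask is |r| > 0.6 AND
p < 0.05 — deliberately the plain thresholding rule, with
Benjamini–Hochberg available behind a flag but off by default. Networks
between two tables (metabolite–OTU) are bipartite: only cross-table pairs
are masked. Variables constant within a diet window (HMOs at the detection
floor during weaning) have no defined correlation and are excluded from
that window's network by the pipeline.

The milk trend model regresses autoscaled metabolites on centered
lactation day by PLS, choosing the LV count that maximizes cross-validated
Q²Y; coefficient intervals come from 500 percentile bootstrap resamples
(2.5–97.5%), and a variable is called trending only when its interval
excludes zero. The bootstrap was chosen because no distributional form for
PLS coefficients is assumed anywhere else; at n = 19 the percentile
interval is slightly liberal (≈8% of flat variables get called per run,
measured over seeds), which is acceptable for a screening call but should
not be read as a calibrated 5% test. Paired start/end-of-suction
comparisons use the classical paired t on log concentrations (the
generator's effects are multiplicative); an exact constant shift (zero
difference variance) is reported as t = ∞, p = 0 with a flag rather than an
error in disguise.

## Pipeline and reproducibility

`run_pipeline()` drives all stages from one config and one global seed,
fanned out to per-stage seeds through a fixed stage-name derivation so any
stage can be reproduced in isolation. Every stage writes flat CSV bundles
plus a JSON manifest (parameters, seed, package version); identical
seed + config gives byte-identical numeric outputs, which the test suite
asserts. Figures (`make_figures()`) are rendered from the bundles, not from
in-memory state, so a run directory is self-contained.

Test problem sizes are chosen to exercise the study shape at desk scale:
the full 32 × 49 / 25 × 48 design with 50 repetitions where the check is
about the study configuration, reduced repetition counts (2–10) where the
check is structural, 199 permutations for calibration sweeps and 1000 only
in the acceptance script.

## Known limitations

* The RP < mean-RP marker rule is deliberately simple and, at n = 32, is
  liberal: when a strong contrast pushes the inner loop to one latent
  variable, the coefficient ordering equals the in-sample |correlation|
  ordering, which is stable across resampled folds — so variables with
  large *spurious* sample correlations (|r| of order 1/√n) enter the marker
  set persistently. Expect the marker list to contain roughly the
  above-average-ranked half of the variables, not a calibrated
  false-discovery set; there is intentionally no FDR control on rank
  products.
* Only binary comparisons are supported (every contrast in the target
  design is two-group); no PLS2 multi-class, OPLS, or kernel variants.
* Compositionality of OTU tables is handled by closure and plain Pearson
  correlation, matching the target analysis; no CLR/SparCC-style
  compositional correction is attempted.
* Single-dyad (n-of-1) designs estimate within-subject structure only;
  nothing here licenses population-level claims, and the generator's
  ground truth encodes exactly that within-subject model.
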