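---
title: "Staging muscle injury healing from expression profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging muscle injury healing from expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healstage)
```

## The problem and the model

Skeletal muscle responds to a traumatic injury with a stereotyped
transcriptional program: inflammatory and stress-response genes surge within
hours, regeneration and matrix-remodeling programs dominate the following
days, and expression relaxes back toward the uninjured baseline over weeks.
`healstage` treats the post-injury time axis as a set of discrete classes —
nine sampled time points (3, 10, 24, 48, 72, 168, 336, 504, 672 h) plus
"uninjured control" — and asks: given the FPKM profile of one unlabeled
sample, which stage does it come from?

All methods work from the same primitive, the per-gene signed log fold
change against the paired control,

$$ f_g(t) = \log_2\frac{x_g(t) + \varepsilon}{c_g(t) + \varepsilon}, $$

thresholded into calls (*up* when $f_g(t) \ge 1$, *down* when
$f_g(t) \le -1$, *none* otherwise — the two-fold rule). The underlying
assumptions are those of the source study design: each injured time point has
a contemporaneous contralateral control, abundance is already
within-sample-normalized (FPKM), and replicate scatter is multiplicative and
modest relative to the between-gene dynamic range.

## The four classifiers

**Time point-specific signatures.** A gene called *up* at $k$ time points
carries up-weight $1/k$ (down-weight analogously, counted separately): a gene
responding at a single stage is maximally informative about that stage, one
responding at seven stages barely informative. Scoring a test profile against
a candidate stage sums the directional weight wherever the test call equals
the training call, plus a fixed 0.5 for a shared no-change. The candidate
with the highest match score wins; the margin to the runner-up maps to
confidence (over 100: high; 50–100: medium; else low). The 0.5 no-change
increment is exposed as `none_increment` but deliberately not re-optimized
here; it is treated as a fixed constant of the method.

**Time point-weighted signatures.** Weights instead encode effect size:
$w_g(t) = |f_g(t)| / \max_t |f_g(t)|$, so a match at the gene's peak stage
counts 1 and elsewhere proportionally less. Because a "fraction of the
maximum fold change" is only well defined on magnitudes when up- and
down-regulation coexist, the sign is carried separately as the expected call
and the weight kept in $[0, 1]$. An all-zero row is inert (weight 0
everywhere) rather than an error. The same 0.5 no-change increment is used as
in the specific method, so the two scores stay on a comparable scale.
A companion *score-matrix* variant restricts to genes significant at exactly
one training stage, codes them $-1/0/+1$ per stage, thresholds the test
profile the same way, and classifies by minimal element-wise L1 distance,
with an all-zero column representing the control class.

**One-vs-one SVM voting.** One linear-kernel soft-margin SVM (cost 1) is
trained per unordered pair of the ten classes — 45 models — on z-scored
replicate-level profiles. Each model votes for its predicted side with weight
equal to the test sample's perpendicular distance from that model's
hyperplane, $R = |w \cdot x + b| / \lVert w \rVert$; weighting by the test
sample's own distance (rather than a fixed margin width) is what makes the
per-class vote totals informative as bar heights — confident models dominate
the tally. The contrasting one-vs-all cascade first separates control from
injured, then repeatedly trains each remaining stage against the rest and
eliminates the stage whose one-vs-rest classifier pushes the sample hardest
toward "rest", until one survives.

**PCA nearest sample.** Training profiles are z-scored per gene
(zero-variance genes dropped first — they carry no information and make the
z-score undefined), decomposed with `stats::prcomp`, and a test sample —
z-scored with the *training* means and standard deviations and projected post
hoc, never included in the fit, to avoid leakage — takes the label of the
nearest training sample in Euclidean distance over the first $N$ components.
$N$ defaults to all components, in which case the call provably equals
nearest-neighbor in the original z-scored space; $N = 2$ reproduces the usual
two-component scatter view. Genes are ranked by
$\sum_c |\mathrm{loading}_{g,c}| \, \lambda_c$ — absolute loadings, so
opposite-signed contributions do not cancel.

## Pathway level

A pathway's activation in a column is the mean FPKM of its member genes
present in the table; members absent from a filtered table are dropped from
the mean rather than treated as zero, since absence after filtering does not
mean absence of expression. Activation Z-scores standardize each pathway
across the nine injured time points, $Z_t = (s_t - \bar s)/\mathrm{sd}(s)$,
with $|Z| > 2$ flagged (the two-sided normal 5% tail). This within-pathway
standardization is one of two defensible readings of a "test across the nine
time points"; the per-time-point injured-vs-control t-statistic reading is
structurally different (it needs replicate-level data) and is not what the
$|Z|>2 \leftrightarrow p<0.05$ equivalence suggests, so standardization is
the implemented default. Significant pathways must additionally show a
two-fold change (injured vs control pathway score) at one or more time
points. Every classifier runs unchanged at pathway resolution by substituting
the pathway-score matrix for the gene matrix, and calls are also mapped to a
coarse period: early (3–24 h), middle (48–168 h), late (336–672 h).

## Replicate quality control: the outlier rule

The replicate filter computes all pairwise Pearson correlations within each
(time point, condition) group and excludes a replicate only when its squared
correlation falls below the threshold (default $R^2 \ge 0.95$, raw-FPKM
scale; a log-scale option is exposed via `log_space`) against *every* other
replicate of a group of at least three. The naive alternative — exclude on
any failing pair — is self-defeating: a failing pair flags both of its ends,
so any group of two discordant replicates (and the study design contains
2-replicate groups) would always empty itself, and in a group of three one
outlier would drag down both good replicates. With three or more replicates
the outlier is identifiable as the one at odds with everyone; a discordant
pair has no internal evidence for which member is wrong, so both are kept and
a warning raised — mirroring how a real 2-replicate time point with
correlation ~0.90 remains usable, just flagged. The pass is simultaneous (one
round), which makes it idempotent: a replicate survives because it agrees
with at least one other survivor.

Aggregation then merges each group per gene: 0 if the replicate median is 0,
otherwise the mean — the median-zero rule guards against a single spurious
non-zero read-through inflating an otherwise silent gene.

## Significance filtering

`filter_spec()` carries the thresholds: minimum aggregate FPKM (1 for
discovery-style filtering, 0.5 for the classification filter — the default
here), optional q-value cutoff 0.05 (q-values are consumed, never computed:
they come from upstream differential testing, or from the generator), and the
two-fold rule. `all_significant_*` modes keep genes passing all clauses at
one or more time points; `single_tp_*` modes additionally require exactly one
called time point, the subset the score-matrix classifier is built on. A
stated "log fold change greater than 2" for the signature methods conflicts
with the two-fold criterion used everywhere else; the package resolves the
conflict as $|f| \ge 1$ (two-fold) uniformly, with `min_fold` configurable
for anyone wanting the stricter reading.

## Numerical and tie-breaking choices

* Pseudocount $\varepsilon = 0.5$ in the fold-change ratio, so $0/0$ maps to
  fold change 0 rather than an undefined value.
* Ties in any classifier resolve toward the earlier class (control counts as
  earliest) and are flagged on the result; determinism beats optimism.
* The control candidate in signature scoring expects *none* at every gene —
  controls have no fold change against themselves by construction.
* `fit_pca` refuses inputs whose every feature has zero variance (e.g. two
  identical samples): after dropping degenerate features nothing would
  remain to decompose.
* libsvm orients its decision values by the class it encounters first in the
  data, not by factor level order; the stored hyperplanes normalize this so
  that `positive`/`negative` labels are always correct.

## What the generator emulates — and what it does not

`generator_config()` defaults encode the emulated study design: nine
post-injury time points; injured replicate counts per time point of
(2, 5, 4, 3, 4, 2, 3, 3, 4), matching the per-time-point enumeration of the
training design (30 injured samples); four control replicates per time point
(36 controls; per-time-point control counts were never specified, only the
~37 total). Baseline abundance is log-normal (`meanlog = log 8`,
`sdlog = 1.2`), giving the heavy-tailed FPKM distribution on which raw-scale
Pearson correlations are dominated by abundant genes. Replicate noise is
mean-one multiplicative log-normal with CV 0.1 — chosen so that replicate
pairs typically correlate at $R^2 \ge 0.95$ (at this CV the expected
correlation is ≈0.97 with the baseline spread above) and the QC filter
rarely fires on clean data. The optional transition regime triples the
log-scale noise variance of injured replicates at one time point (168 h by
convention), dropping its expected replicate correlation to roughly 0.90 —
the empirically reported signature of the regenerative transition, where
tissue heterogeneity peaks.

Responding genes split into a single-time-point fraction (0.15) and a
multi-time-point fraction (0.25) active over a contiguous window of 2–4 time
points with a peaked magnitude profile (neighbors at 70% of the peak), which
is what makes adjacent stages share signature genes and misclassifications
land on temporal neighbors. Peak effects draw from `effect_log2fc_range`
(default $[1, 4]$ log2 units; the recovery benchmarks use $[2, 4]$).
Per-time-point q-values come from a vectorized Welch t-test on
$\log_2(\mathrm{FPKM} + 0.5)$ with Benjamini–Hochberg correction across
genes, giving downstream filters the q column they expect.

Deliberately not emulated: read-level noise (no FASTQ/alignment), isoform
structure and splicing, batch effects, library-size artifacts,
between-animal biological covariates, and any return-to-baseline correlation
between late time points and controls beyond what the effect windows imply.
Passing tests on this generator therefore demonstrate the *algorithms*
recover planted structure under realistic abundance and noise models — not
that real tissue data is this clean.

Blinded test sets share the training study's feature-effect model (a
deterministic function of the generator seed) but draw independent replicate
noise from their own seed, and their true labels travel in a separate sealed
record; the default composition is six controls plus two samples each at 3,
10 and 168 h, the held-out design the benchmarks mirror.

## Problem sizes used by the test suite

The suite favors many small randomized fixtures over few big ones: oracle
equivalence runs 100 randomized trials per scoring rule on 20–60-feature
fixtures; recovery benchmarks run 20 seeds per regime at the full default
design (2000 genes, 66 training samples, 12 blinded samples); structural
checks (self-classification, error adjacency, one-vs-one vs one-vs-all) use
300–800-gene studies. These sizes were chosen as the smallest at which the
statistical properties under test are stable.

## Known limitations

* The signature methods assume the test sample's control reference is
  comparable to the training controls; `control_reference()` pools the
  per-time-point control aggregates, which is the only option when the test
  sample's own paired control is unknown.
* The one-vs-all cascade retrains $O(K^2)$ SVMs per classified sample; it
  exists for comparison, not throughput.
* Pathway scores inherit the unequal variance of their member counts; no
  shrinkage or size normalization is applied beyond the mean.
* Confidence-tier thresholds (100/50 score units) are meaningful on
  signature-score scales with thousands of weighted genes; on small panels
  or at pathway level, margins are smaller and the tiers should be
  re-calibrated via `assign_confidence()`'s arguments.
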