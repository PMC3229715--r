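---
title: "Ct-value miRNA differential expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ct-value miRNA differential expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirct)
```

## The problem

TaqMan low-density arrays report, for each miRNA assay and each sample, a
cycle-threshold (Ct): the PCR cycle at which fluorescence crosses a fixed
threshold. Lower Ct means more transcript; at perfect amplification
efficiency one cycle is a two-fold difference in abundance. mirct implements
a complete two-group differential-expression analysis on such data — the
design it is built around is a comparison of frontal-cortex miRNA profiles
between FTLD-TDP patients carrying progranulin (*PGRN*) loss-of-function
mutations (8 carriers) and patients without known mutations (32
non-carriers), across 664 assays — followed by a qRT-PCR validation arm and
an anti-correlation integration of the candidate miRNAs against mRNA
differential-expression results.

Ct data have three properties that drive the pipeline's design. First,
missingness is informative: wells fail to amplify when the transcript is
dim, so dropout increases with the underlying Ct. Second, samples carry
global intensity offsets (RNA input, RT efficiency) that must be removed
before comparing groups. Third, with 8-vs-32 samples and hundreds of
assays, per-assay t tests need multiplicity control that respects the
correlation between assays — which permutation of group labels provides
without distributional assumptions.

## Preprocessing

The analysis-ready matrix is produced by four steps in fixed order, each a
plain matrix transform with a stage tag (`raw` → `filtered` → `normalized`
→ `imputed` → `shrunk`) that enforces the order.

**Detection filter.** An assay is excluded when 20% or more of its samples
have a missing Ct or a Ct above 35 (`max_missing_frac = 0.20`, `max_ct =
35`; the boundary counts as excluded). In retained assays, surviving cells
above 35 are set to missing and later imputed, since a Ct that high is a
detection failure rather than a measurement. Both thresholds are exposed;
filtering happens before normalization so the smoother never fits dropout
artifacts.

**Lowess normalization.** Sample-level trends are removed against a
pseudo-reference: the per-assay median Ct across samples. For each sample,
a lowess curve (span 2/3, the classic default) of the deviation
(sample − reference) against the reference Ct is fitted over the observed
assays and subtracted. The median reference is robust to the 8-vs-32 group
imbalance — a group-mean reference would absorb part of any real group
effect. A constant sample offset is removed exactly; smooth Ct-dependent
trends are removed to first order. Samples with fewer than 10 observed
assays cannot support the fit and are an error.

**KNN imputation.** Each missing cell (assay *a*, sample *s*) is replaced
by the unweighted mean, over the `k = 10` assays most similar to *a*, of
their value in *s*. Similarity is Euclidean distance over the samples where
both assays are observed, scaled by the number of shared samples, so
sparsely overlapping assays are not favoured; only assays observed in *s*
are eligible. When fewer than `k` are eligible all are used (warning); zero
eligible neighbours is an error. `k = 10` is the conventional default for
expression-matrix KNN imputation.

**Winsorization.** "Shrinking extreme values toward the centre" is
operationalized as per-assay winsorization at `median ± 3 × 1.4826 × MAD`
(a robust z of 3). This is the mildest rule consistent with the goal of
bounding the influence of single wells on an 8-sample group mean: values
inside the bounds are untouched, values outside are clamped to the bound,
and the operation is idempotent. When the MAD is zero there is no
meaningful scale to clamp against and the assay is left unchanged.

## Differential expression

For each assay, a pooled-variance two-sample Student t test (Welch
optional; the pooled form is the default because the design motivating the
package reports plain two-sample t tests) gives the nominal p-value. With
zero pooled variance the statistic degenerates; the test then reports p = 1
for equal means and p = 0 (flagged) otherwise, preserving the sign.

Multiplicity is controlled by the Westfall–Young min-P step-down procedure
with `n_perm = 1000` label permutations by default. For permutation *b*,
the full vector of per-assay p-values is recomputed on the permuted labels
(the same analytic t p-value used for the observed labels). With assays
ordered by raw p, the adjusted p at rank *i* is

$$\tilde p_{(i)} = \frac{1 + \#\{b : q_{b,(i)} \le p_{(i)}\}}{1 + B},
\qquad q_{b,(i)} = \min_{j \ge i} p_{b,(j)},$$

with monotonicity enforced down the ranking. The `(1 + count)/(1 + B)`
estimator is the standard bias-protected form and never returns an adjusted
p of exactly zero. The *overall P* is the adjusted p of the top-ranked
assay — equivalently the single-step global min-P test, the probability that
a permutation's smallest p-value is at most the observed smallest. When
`n_perm` reaches the number of distinct label assignments
$\binom{n}{n_1}$, the procedure switches to exhaustive enumeration (with a
message), which makes small designs exactly reproducible and is how the
implementation is verified against a brute-force oracle.

Empirical q-values are estimated from the same permutation null: for each
observed $p_i$, the expected count of null p-values at or below $p_i$
(averaged over permutations) divided by the observed count at or below
$p_i$, capped at 1 and monotonized from the largest p downward. The null
proportion $\pi_0$ is fixed at 1, the conservative choice; a Storey-type
$\pi_0$ estimate would scale all q-values down and is deliberately not
applied.

Candidates are the assays with raw p below `alpha = 0.05`, ranked by raw p
and annotated with direction under the convention used throughout: lower
Ct in the carrier group means higher expression, reported as `"up"`. Ties
in raw p are broken by assay id so the step-down ordering is deterministic.

## qPCR validation arm

Validation plates run each assay in duplicate wells, with the small
nucleolar RNA RNU48 as the endogenous control. The steps:

* **Duplicate reconciliation.** Wells agreeing to within 2 cycles are
  averaged. Wells more than 2 cycles apart (strict inequality) indicate a
  technical failure in one well; the well farther, in absolute difference,
  from the assay's centre — the median of all of that assay's wells across
  samples — is deleted. The centre and distance are package choices (the
  rule's reference distribution is otherwise underdetermined); an exact
  distance tie keeps the mean, so the rule is symmetric in well order.
* **ΔCt.** Per sample, target Ct minus control Ct; its negation
  (minus-ΔCt) is the log2 of scaled expression. Any per-sample additive
  offset cancels here exactly.
* **Group comparison.** Pooled two-sample t on minus-ΔCt, with the mean
  difference and its 95% confidence bounds exponentiated base 2 to the
  fold-change scale. `log2(FC)` equals the minus-ΔCt group-mean difference
  by construction, and this identity is asserted to 1e-12 in the tests.
  Validation p-values are reported unadjusted: the arm confirms a short,
  pre-selected candidate list rather than screening a family.
* **Detectability.** An assay whose median reconciled Ct exceeds 35, or
  with more than half its samples missing, is flagged undetectable. (High
  Ct — not low — is the undetectable side; the package follows the
  biologically coherent reading.)

## Target integration

The integration stage encodes the anti-correlation logic of
miRNA-mediated repression: where a miRNA is up-regulated its predicted
targets should be down-regulated. Inputs are two mRNA
differential-expression tables (one per tissue; probeset, gene symbol,
direction, p) and per-miRNA predicted-target lists (TargetScan-style,
consumed as data — no target prediction is performed). A gene qualifies
when at least one of its probesets is down-regulated at p < 0.05 in *each*
tissue (the any-probeset collapse; the published analysis reports 177
probesets but 18 genes, implying such a collapse without describing it),
and it is retained when it appears in at least one candidate miRNA's
target list. The result maps each gene to the candidates targeting it,
with a multiplicity tally. On the published candidate table for the five
cerebellum-validated miRNAs — shipped as
`ftld_candidate_targets()` — the stage yields 18 genes with tally
{3 miRNAs: 3 genes, 2: 7, 1: 8}, the triple-targeted genes being BAI3, GK
and SLC23A2. miR-548b-5p and miR-548c-5p are kept as distinct candidates
even though they share most targets.

## The synthetic-data generator

Every stage is testable without any external data because the generator
plants known truth. The array model is

$$\mathrm{Ct}_{as} = \beta_a + \delta_a\,\mathbb{1}[s \in g_1] + u_s +
\varepsilon_{as},$$

with per-assay baselines $\beta_a \sim N(28, 3^2)$ (typical of miRNA
low-density arrays, spanning abundant assays near Ct 20 and dim ones near
the detection limit), per-sample shifts $u_s \sim N(0, 0.5^2)$ (the
component normalization must remove), well noise $\varepsilon \sim
N(0, 0.6^2)$, and 20 truly differential assays with shifts $|\delta| \in
[0.5, 2]$ cycles, signs split evenly between up and down. Dropout is
logistic in the latent Ct, $P(\text{missing}) =
\mathrm{logit}^{-1}(0.35\,(\mathrm{Ct} - 34))$: missingness and dimness
are coupled, which is exactly what the detection filter assumes. The slope
0.35 was chosen so that, under the baseline distribution, roughly a
quarter of assays fail the 20% filter — making a detectable fraction
around 490/664 plausible — and is configurable. Differential assays are
planted on baselines at least 4 cycles below the dropout midpoint
(expected per-well dropout under ~20%): a study's candidates are by
construction among its detectable assays, and signal planted inside the
dropout zone would measure filter attrition rather than inference.

The qPCR generator adds duplicate-well technical noise (sd 0.25 Ct), a
flat control assay, and, with configurable probability, a one-sided
displacement of a single well by 2.5–6 cycles — the minimal mechanism that
triggers the reconciliation rule. The integration fixture generator wraps
any planted gene→miRNA assignment in target lists and two DE tables, with
decoy genes each failing exactly one filter (down in one tissue only, up,
non-significant, or down-in-both but untargeted).

What the generator does **not** emulate: pre-amplification chemistry,
probe efficiencies different from 2, RNA-quality (RIN) effects, correlated
assay families, or heavy-tailed well noise. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
Gaussian-with-dropout model, not robustness to every artifact of real
plates.

## Numerical and design choices

* All randomness flows from explicit seeds; generators and the
  permutation draw are bit-reproducible given a seed, and `run_pipeline()`
  derives everything from one top-level seed.
* Group statistics are computed by summing each group directly (not by
  subtracting one group's sums from totals), so a label assignment and its
  complement yield bit-identical two-sided p-values — required for the
  exhaustive-enumeration path to match its oracle exactly.
* TSV round-trips write 17 significant digits, so write∘read is the
  identity on doubles.
* Undetermined wells are standardized to missing on ingest; Ct values
  above the instrument range of 40 are accepted with a warning.
* Degenerate cases are explicit: zero-variance tests are flagged rather
  than producing NaN; a MAD of zero disables winsorization for that assay;
  missing cells surviving to the testing stage drop the assay with a
  warning.

## Problem sizes in the test suite

The suite verifies behaviour at the scale the package targets (664 × 40)
where cheap, and at reduced scale where a property needs replication: the
family-wise error simulation uses 200 null datasets of 100 assays with 200
permutations each; exhaustive-oracle checks use 2-vs-2 and 2-vs-3 designs
(6 and 10 assignments); imputation is verified cell-for-cell against an
O(n²) oracle on 50 × 20 matrices; planted-effect recovery uses 25
full-scale replicates. These sizes are the package's own verification
design and are stated here so they can be scaled up by anyone wanting
tighter Monte-Carlo intervals.

## Limitations

Raw p-values come from the t distribution while adjustment is
permutation-based; under heavy non-normality the two can drift apart (the
suite checks their agreement under Gaussian data only). The lowess
reference profile assumes most assays are non-differential; a majority of
truly changed assays would bias normalization. The empirical q-values are
conservative by the fixed $\pi_0 = 1$. The integration stage treats the
target lists as given and applies no enrichment statistic — the gene list
is exported for external pathway tools.
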