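---
title: "mmra: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mmra: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmra)
```

# The problem

Transcriptional subtypes of a tumour cohort (or any sample collection with a
per-sample classification) are usually defined on mRNA data alone. `mmra`
asks which **microRNAs** are plausible upstream drivers of each subtype's
expression programme, given a paired microRNA expression matrix over the same
samples. Because any single statistical association is weak evidence, the
package chains four *independent* lines of evidence into a candidate funnel;
a microRNA must survive all of them:

1. it is differentially expressed in the subtype;
2. its *predicted targets* are over-represented in the subtype's signature;
3. the genes most *mutually informative* with it (its regulon) are enriched
   in the signature;
4. it *quantitatively explains* a large share of signature-gene expression in
   a per-gene regression.

# Stage 1 — subtype-core differential expression

**Core samples.** For a classifier, a sample belongs to a subtype core when
its classification FDR is below 0.05 and its distance-to-template δ is
*strictly* below the 95th percentile of the pooled δ distribution of all
samples (linear-interpolation percentile, `quantile(type = 7)`; the package
uses this percentile definition everywhere). Restricting to cores removes
borderline samples that would blur the contrast. Samples assigned to the
test subtype with low confidence are excluded from *both* sides of the
contrast, not shifted to the background group.

**Test.** Each microRNA is contrasted between the subtype core and all other
samples with a bootstrap Kolmogorov–Smirnov test: the pooled sample is
resampled with replacement into groups of the original sizes `n_boot` times
and `p = (1 + #{D_boot ≥ D}) / (1 + n_boot)`. The KS statistic makes no
distributional assumption, and the bootstrap calibrates it at small group
sizes. The fold change is the linearized log2-mean ratio,
`FC = 2^(mean(x) − mean(y))` (a geometric-mean FC; whether means should be
taken on the linear scale instead is genuinely ambiguous — the geometric
form is the package's choice and is applied consistently). A microRNA is
retained when `p < 0.001` and `FC > 2` or `FC < 1/2`.

Note the resolution constraint: with `n_boot` resamples the smallest
attainable p is `1/(n_boot + 1)`, so `p < 0.001` requires `n_boot ≥ 1000`
(the default).

**Threshold justification.** `permutation_fdr_grid()` reshuffles the sample
labels and reports, per (p, FC) grid cell, the ratio of the mean permuted
significant count to the observed count. The minimum-FDR pair is
recommended, with the caveat (attached to the result) that when several
pairs tie, the intermediate pair balances selectivity against sensitivity
for a first-stage filter.

# Stage 2 — target enrichment

Predicted microRNA→target maps are built by `combine_target_predictions()`:
a pair needs agreement of at least two prediction databases, and
experimentally validated pairs enter unconditionally. Enrichment of a
microRNA's targets in the matching subtype signature (UP and DOWN tested
separately; whichever passes carries the association) uses the upper-tail
hypergeometric test plus the observed/expected overlap ratio. The Bonferroni
family is the number of (microRNA, signature) tests performed within a
classifier — the natural unit, since thresholds are selected per classifier.
The gene universe defaults to the genes present in both the expression
matrix and the target map's gene space.

Thresholds are calibrated with a randomized-set FDR: random microRNA sets of
the same size as the observed subtype-specific set are tested identically,
and the grid cell minimizing (mean random significant count)/(observed
count) is chosen per classifier. This construction also absorbs biases from
databases with systematically larger target lists, because the same bias
affects the random sets.

# Stage 3 — regulons and master regulator analysis

**Preprocessing.** For each surviving microRNA, the mRNA matrix and the
single microRNA row are stacked, delogged (`Y = 2^X`), quantile-normalized
across samples (mean-of-sorted reference, `limma::normalizeQuantiles`),
relogged, and genes with s.d. below `sd_min` are dropped (hub exempt). The
default `sd_min = 1.2` suits deeply heterogeneous tumour compendia; the
filter's role is to remove genes whose variation is noise-level, so on data
of different dispersion the value should track the noise floor (the
synthetic analyses below use 0.7 ≈ 1.4× the generator noise s.d. of 0.5).

**Mutual information.** The estimator is a Gaussian-kernel density MI on
copula-transformed data: values are replaced by average ranks scaled to
(0, 1), and a product kernel with bandwidth `h = n^(−1/6)/√12` (a
Silverman-type two-dimensional rule; the factor is the standard deviation of
a uniform variate, the marginal distribution after the rank transform) is
used in the standard leave-none-out KDE MI formula, clamped at zero. The
rank transform makes the estimate exactly symmetric and exactly invariant
under strictly monotone transforms of either argument. On bivariate Gaussian
data the estimate tracks the closed form `−½·log(1−ρ²)` within ±0.1 at
n = 2000 across ρ ∈ {0.2, 0.5, 0.8} (tested); a mild negative bias at high ρ
is the usual KDE smoothing bias and is immaterial for thresholding, which is
calibrated on the same estimator.

**Edge significance.** The null MI distribution is obtained by permuting
rank vectors; a linear model of log(survival probability) versus MI is
fitted to the null tail (largest 5%) and extrapolated to the target level
(default 1e-7), which reaches far beyond what any feasible permutation count
could resolve directly. The extrapolated threshold agrees with the direct
empirical quantile within 10% where both are computable (tested at 1e-3).

**Bootstrap consensus.** `n_boot` bootstrap networks are built (samples
resampled with replacement); an edge's support count is tested against a
binomial null whose success rate is the total kept-edge rate — the model of
edges falling uniformly at random across the `n_boot × n_genes` slots.
Edges with support p below `consensus_p` form the regulon. The defaults
(100 bootstraps, 1e-12) belong together: the smallest achievable support p
is `rate^n_boot`, so halving the bootstraps requires relaxing the consensus
level correspondingly (the scaled analyses below use 50 bootstraps with
1e-6). A consequence of the rate renormalization worth knowing: raising the
MI threshold shrinks every support count, but can still *admit* an edge the
looser threshold rejected, because the null rate shrinks too. Support counts
are monotone; the final edge set is not guaranteed to be.

With a single imposed hub there are no indirect-path triplets, so no
data-processing-inequality pruning is applied.

**MRA.** Each regulon is tested for overlap with the associated signature by
the upper-tail Fisher exact test over the expression-matrix gene universe
(one fixed universe for candidates and null model — simpler and more
comparable than per-hub preprocessed universes). The p-value threshold comes
from a null model: microRNAs that are expressed (detected in >10% of
samples) but not differential anywhere, whose regulons overlap every
candidate regulon by <70% (shared / smaller regulon). "Not differential" is
implemented as |SNR| < 0.05 with SNR = (m₁ − m₂)/(s₁ + s₂); a literal
one-sided reading (SNR < −0.05) is available via
`null_model_spec(literal_sign = TRUE)` for users who want it. The MRA
threshold is the null p-value's lower 5th percentile (95% of null tests lie
above it), falling back to 1e-4 when no microRNA qualifies. When the null
regulons are empty (as on compact synthetic panels where non-differential
microRNAs link to nothing) the threshold degenerates to ≈1 and the gate is
flagged as permissive in the log — the earlier gates then carry the
specificity.

`mi_rank_enrichment()` additionally asks whether signature genes concentrate
among the *highest-MI* members of a regulon: a weighted running-sum score
over the MI-ranked regulon, normalized against gene-label permutations.

# Stage 4 — stepwise regression attribution

Every signature gene found in at least one surviving regulon is regressed
(log2 scale, original matrix — not the network-preprocessed one) on the
microRNAs whose regulons contain it, pooled across classifiers. The search
is bidirectional from the full model with AIC stopping; AIC comparisons use
a 1e-8 tolerance with ties broken toward the smaller model and then by
variable name, making the selection invariant to candidate order. A
perfect-fit guard floors the residual sum of squares. Users should know the
intrinsic operating point of AIC selection: an independent decoy candidate
enters with probability P(χ²₁ > 2) ≈ 0.157, so "exact support" recovery
plateaus near 84% per decoy even when the true predictor is recovered
essentially always.

Attribution fractions — per (microRNA, signature, coefficient sign), the
share of signature genes whose selected set includes the microRNA — use the
**full signature** (intersected with the expression matrix) as denominator:
a signature gene with no regression model is a gene the microRNA does not
explain, and counting only modelled genes would inflate fractions toward 1
whenever few signature genes carry models. The candidate gate is the 90th
percentile of all pooled fractions, strictly exceeded; most pooled
fractions are random associations, so the percentile adapts to the run's
own null level. A final record also stores whether the microRNA's
expression direction is opposite to its associated signature (the
biologically expected configuration for a repressor).

# The synthetic generator

`simulate_dataset()` emulates the structure the pipeline assumes: subtypes
with planted driver microRNAs whose targets are anti-correlated members of
the subtype's UP signature. Defaults: 3 subtypes × 60 samples, 2 drivers
shifted −1.5 log2 in their subtype, 40 targets each generated as
`baseline + slope·microRNA + ε` with slope −0.8, Gaussian noise σ = 0.5 on
the log2 scale throughout, 20 additional subtype-shifted UP genes (+1.0),
and per-signature "stale" label-only genes. Classification FDRs are drawn
low (5% of samples get low-confidence values ≥0.05) and δ from Beta(2, 5),
so the pooled-95th-percentile core rule trims about 5%.

Choices worth making explicit:

* **Only the UP-side programme is planted.** Driver loss derepresses its
  targets, which is the mechanism under study; DOWN signatures are carried
  as labels without a planted programme. A second planted DOWN programme
  would be collinear with the subtype indicator and would add no independent
  structure to test against.
* **Stale signature genes** model the reality that published signatures
  contain genes that do not co-vary in a new cohort; they exercise the
  full-signature denominator of stage 4.
* Gaussian log2 noise, not negative-binomial counts: the pipeline consumes
  already-normalized log2 matrices, so count-level realism is out of scope.
  Consequently, passing tests demonstrate the *logic* of the funnel (gating,
  calibration, recovery, specificity) — not robustness to RNA-seq count
  noise, batch structure, or stromal admixture, none of which the generator
  emulates.

# Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run the full pipeline on the default
generator (500 genes × 60 microRNAs × 180 samples) with 1000 KS bootstraps,
a 100-permutation FDR grid, 100 randomized enrichment sets, a 2·10⁴-value MI
null, and 50 bootstrap networks at consensus 1e-6 — sizes chosen so a
complete run takes seconds while every gate still operates away from its
degenerate regimes. Null calibration uses 500 microRNAs × 200 permutations;
estimator oracles use n = 2000 (MI) and 100 replicates at n = 450 (stepwise
recovery).

# Known limitations

* The randomized-set FDR and the binomial consensus both assume
  exchangeability of microRNAs/edges; strong target-count imbalance is
  absorbed only to the extent the random sets reproduce it.
* On small gene panels the MRA null model is weak (empty null regulons →
  permissive gate); specificity then rests on stages 1–2 and the stage-4
  percentile gate, which the end-to-end tests confirm is sufficient there.
* Two-group designs without meaningful δ (e.g. MSI/MSS) are supported via
  `use_delta = FALSE`, which reduces cores to the FDR rule.
* Identifier matching is exact string match after upper-casing; no alias
  resolution is attempted.
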