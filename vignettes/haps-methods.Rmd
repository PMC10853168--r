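---
title: "Scoring HLA-I tumor-antigen presentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring HLA-I tumor-antigen presentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapscore)
library(dplyr)
```

## The problem

Whether a tumor neoantigen triggers a CD8+ T-cell response depends on the
patient's HLA class I machinery actually presenting it. Two genotype-level
quantities bear on that capacity: how many mutant peptides are predicted to
bind the patient's HLA-I molecules (the tumor neoantigen burden, TNB), and
how physicochemically different the two alleles at each locus are (the
evolutionary divergence of the peptide-binding domain, which widens the
presentable peptide space). `hapscore` combines the two into a single
per-patient score — the HLA tumor-Antigen Presentation Score (HAPS) — and
provides the surrounding machinery a translational analyst needs: survival
dichotomization and cut-off scanning, HLA loss-of-heterozygosity (LOH)
stratification, TCR β CDR3 repertoire metrics, and a small neural network
that integrates presentation, mutational burden and T-cell diversity into a
response classifier for immune-checkpoint-inhibitor (ICI) treated patients.

## Allele divergence from Grantham distances

Divergence between the two alleles at a locus is measured over the aligned
181-residue peptide-binding domain (exons 2–3) with the Grantham
amino-acid distance,

$$D_{ij} = \rho\left[\alpha (c_i-c_j)^2 + \beta (p_i-p_j)^2 +
  \gamma (v_i-v_j)^2\right]^{1/2},$$

where $c$, $p$, $v$ are side-chain composition, polarity and molecular
volume, $\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$, and $\rho$
scales the mean over the 190 residue pairs to 100.

Two numerical points deserve care:

* **Which matrix is canonical.** The integer table printed in 1974 cannot
  be reproduced exactly from the formula: the original computation rounded
  intermediate values, most entries differ from a full-precision evaluation
  by at most one unit, and the printed Asp–Trp entry (181) differs by ten
  (formula: 191). Since downstream divergence analyses in this field use
  the printed table, `grantham_matrix()` returns it verbatim;
  `build_grantham_matrix()` exposes the formula for property-level work,
  and the test suite pins the two to each other within these documented
  bounds.
* **Normalization.** The package reports the *mean per-site* distance over
  aligned positions where neither sequence has a gap (gap columns are
  excluded from numerator and denominator, so alignment artifacts cannot
  inflate divergence). A raw summed variant is available via
  `normalize = "sum"`. Homozygous loci score exactly 0 without a sequence
  lookup.

Allele names are normalized to two-field resolution (`"A*02:01:01"` →
`"A*02:01"`); unknown alleles are a hard error, never imputed, and class II
names are rejected — the score is defined over HLA-A, -B, -C only.

## Neoantigen burden and the score

Binding predictions (NetMHCpan-style tables) are filtered with a strict
inequality: IC50 < 500 nM by default, or percentile rank < 1% in rank mode.
Per locus, a mutant peptide counts once even if both alleles bind it —
burden measures presentable peptides, not peptide–allele pairs (a `"pairs"`
mode exists for sensitivity analysis). The score is then

$$\mathrm{HAPS} = \frac{1}{3}\sum_{i \in \{A,B,C\}}
  \mathrm{HED}_i \cdot \log_{10}(\mathrm{TNB}_i + 1),$$

zero exactly when every locus is homozygous or presents nothing, and
monotone in every coordinate. Patients are called `"high"` when the score
is at or **above** the cut-off; the published cut-offs (10 for whole-exome
cohorts, 1.31 for panel cohorts) ship as mode defaults. Ties at the
boundary are resolved upward for consistency with the network threshold
convention (score ≥ threshold ⇒ positive call).

## Cut-off scanning

`scan_cutoff()` reproduces the HR-curve procedure that produced those
cut-offs: every unique score value between the 10th and 90th percentiles
is a candidate, each must leave at least 10% of the cohort in each arm,
and a Cox proportional-hazards model (high vs low) is fitted at each. Two
departures from a naive argmin are deliberate:

* **One-standard-error tie rule.** The sampling noise of a single-cohort
  HR (SE of log HR ≈ 0.1 at n = 500 with ~400 events) dwarfs any small
  fixed percentage, so the scan treats every cut-off within one SE of the
  minimum (log scale) as statistically tied and picks the tied candidate
  closest to the cohort median. In threshold-recovery simulations
  (n = 500, protective HR 0.4 above the generative threshold, 20%
  censoring) this selects a cut-off within one grid step of the truth in
  ≥ 90% of replicates, whereas a 1% tie band recovers barely half — the
  argmin alone lands on noise dips.
* **Multiplicity-corrected existence tag.** Scanning hundreds of
  correlated dichotomies guarantees optimistic pointwise intervals: in
  pure-noise cohorts some per-cut-off CI excludes 1 about 70% of the time.
  The scan therefore judges whether *any* cutpoint exists by the
  maximally-selected-statistic correction (the Lausen–Schumacher
  approximation applied to the maximal Wald statistic over the admissible
  quantile range, the same correction behind `maxstat`-style cutpoint
  tools) and tags the result `"no significant cutpoint"` when the
  corrected p ≥ 0.05. Pointwise CIs are still reported, uncorrected, in
  the grid for plotting.

Kaplan–Meier medians use the standard convention (first time the curve
reaches 0.5, midpoint if it sits exactly at 0.5 over an interval; `NA` =
not reached), and `cox_hr()`/`km_logrank()` delegate the fits to the
survival package — the package's tests hold them to within 1e-6 of
independent partial-likelihood and log-rank oracles.

## HLA-LOH stratification

A locus is called lost when the tumor's minor-allele copy number is below
0.5 **and** allelic imbalance is significant (p < 0.01); requiring both
published thresholds jointly avoids over-calling LOH from copy-number noise
alone (a `cn_only` rule is exposed). A patient is `"LOH"` if any classical
locus is lost — with the underlying inference operating per locus, any-locus
loss already compromises the corresponding peptide space. Joint strata
combine the score class with LOH status; the two-stratum mode pools
everything except `HAPShigh/HLAintact`, the group with both high predicted
presentation and intact machinery.

## TCR repertoire metrics

Clones are identified by their CDR3 amino-acid sequence; nucleotide-distinct
clonotypes translating identically are merged before any metric. Diversity
is the Shannon index $H = -\sum_i p_i \ln p_i$; clonality is
$1 - H/\ln n$ with the single-clone case defined as 1 (the limit of
vanishing evenness). Fixed-depth comparisons use seeded multivariate
hypergeometric downsampling (sampling reads without replacement), mirroring
the common practice of analyzing a fixed number of qualified reads (10^6 in
the motivating study) per sample.

Edit-distance summaries over the top 30 clones (count-descending, ties
broken lexicographically for reproducibility) use Levenshtein distance,
which handles the length variation that dominates real CDR3 repertoires;
all unordered pairs are averaged by default with a nearest-neighbour option.
The similarity *network* instead follows the fixed-length convention:
edges connect equal-length sequences differing by at most three
substitutions (Hamming), so sequences of unequal length are never linked.

## The three-factor response network

The integration model is a single-hidden-unit logistic network over
standardized (HAPS, TMB, TCR diversity):

$$s = \sigma\!\left(b_{out} + w_{out}\,
  \sigma\!\left(b_h + \textstyle\sum_k w_k x_k\right)\right).$$

The architecture is pinned down by the published parameter count — one
hidden intercept (1.9214) plus three input weights (1.54006, 1.4383,
2.46875), and two output-layer numbers read as output bias (−0.42557) plus
hidden-to-output weight (−1.76532). That reading is documented, not
asserted as the original authors' intent; the frozen coefficients ship as
`nn_reference_model()` for forward-pass regression (score 0.1229 at the
standardized origin) and are never presented as retrainable truth. Note the
negative output weight: the reference score *decreases* in the hidden
activation, which the tests assert rather than assume away.

Training minimizes the sum of squared errors with resilient
backpropagation (iRPROP−: per-parameter steps grown ×1.2 under a stable
gradient sign, halved on a sign flip), stopping when |ΔSSE| < 0.01 or
after 20 full-batch iterations — deliberately few, which together with the
single hidden unit bounds overfitting: separable synthetic cohorts reach
training AUC ≥ 0.95 while label-shuffled nulls stay near 0.5. Whether the
original work standardized inputs is unstated; this package always
standardizes and stores the parameters with the model, because RPROP step
sizes are not scale-free. Initialization is seeded and mandatory — there is
no hidden global RNG state.

The decision threshold maximizes Youden's J = sensitivity + specificity − 1
over the observed scores (predicted positive at score ≥ threshold, ties to
the lowest threshold); factor importance is the mean AUC drop under seeded
per-feature permutations, a transparent substitute for caret's unspecified
internal ranking.

## The synthetic cohort generator

`simulate_cohort()` exists so that every pipeline stage is testable without
any external download, and its defaults are fixed study conditions, not
tuning knobs: 181-column alignments with alleles substituted from a locus
consensus at 4% per site (typical heterozygote divergences of a few units,
as in real cohorts), 10% homozygous loci, a Poisson mean of 30 candidate
peptides per patient with log-uniform IC50 spanning the 500 nM threshold,
exponential survival with a protective hazard ratio applied at/above a
generative score threshold (default: the cohort median), uniform-fraction
censoring at an expected 20%, 19% patient-level LOH prevalence (the range
observed in the motivating cohorts), power-law clone abundances, and a
logistic response model on the standardized three factors. A master seed
fans out deterministically to per-stage seeds
(`(seed * 7919 + stage) mod (2^31 - 2) + 1`), so stages are individually
reproducible and whole bundles are byte-identical under a fixed seed.

What the generator does *not* emulate: population HLA allele frequencies
and linkage, sequence motifs of real binding peptides, germline mutational
signatures, batch effects, or informative censoring. Passing tests
therefore demonstrate the estimators' statistical behavior under the
generative model — threshold recovery, calibration, direction of effects —
not clinical performance on real cohorts, which requires real data.

## Problem sizes and runtime choices

The shipped tests run the scan-recovery study at 50 cohorts of n = 500
(HR 0.4, 20% censoring) and the null study at 10 cohorts; the
end-to-end check simulates and scores a 300-patient bundle twice to verify
byte-identical reruns. These sizes give the binomial bounds used in the
assertions reasonable power while keeping the whole suite around two
minutes on a single core; the same estimates stabilize but do not change
at larger n.

## Known limitations

* The published WES/panel cut-offs and network coefficients are consumed
  as constants; the cohorts that produced them are access-controlled, so
  none of the headline clinical numbers are re-derived here.
* The quality score consumes $K_d$ and $EC_{50}$ quantities; the upstream
  cross-reactivity model that produces $EC_{50}$ values is out of scope.
* LOH calls are taken from allele-specific copy-number output; the
  BAM-level inference that generates them is not reimplemented.
* The Lausen–Schumacher tag is asymptotic; on small cohorts its null
  false-flag rate is somewhat above the nominal 5%.
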