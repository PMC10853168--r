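# hapscore

Quantifying how well a cancer patient's HLA class I genotype can present
tumor neoantigens, and what that predicts about benefit from immune
checkpoint inhibitors (ICIs).

Response to ICIs requires that mutant peptides be produced, presented by
HLA-I, and recognized by T cells. `hapscore` implements a genotype-level
presentation score combining two signals per classical locus
(HLA-A, -B, -C): the evolutionary divergence between the patient's two
alleles over the aligned 181-residue peptide-binding domain (mean per-site
Grantham distance, `HED_i`), and the tumor neoantigen burden presented by
that locus (`TNB_i`, distinct mutant peptides with predicted binding
IC50 < 500 nM or %rank < 1):

```
HAPS = mean over i in {A, B, C} of  HED_i * log10(TNB_i + 1)
```

A homozygous locus contributes zero (no divergence), as does a locus
presenting nothing. Around the score the package provides, as tested
tibble-in/tibble-out functions:

* the Grantham distance matrix (published 1974 table as canonical, plus the
  composition/polarity/volume formula), aligned-sequence divergence with
  principled gap handling, and per-patient divergence profiles;
* NetMHCpan-style binding-table filtering, per-locus burden counting, TMB,
  and the neoantigen quality (self-discrimination) score;
* survival tooling: Cox hazard ratios, Kaplan–Meier + log-rank, and an
  HR-minimizing cut-off scan with a one-standard-error tie rule and a
  maximally-selected-statistic significance tag;
* HLA loss-of-heterozygosity calls (minor-allele copy number < 0.5 with
  allelic-imbalance p < 0.01) and joint HAPS × LOH strata;
* TCR β CDR3 repertoire metrics: seeded hypergeometric downsampling,
  Shannon diversity, clonality, top-clone Levenshtein summaries, and
  Hamming similarity networks (edges ≤ 3 substitutions, equal length);
* a single-hidden-unit logistic network over (HAPS, TMB, TCR diversity)
  trained by resilient backpropagation on SSE, with Youden-index
  thresholding, permutation importance, JSON serialization, and the frozen
  published coefficients as a reference model;
* a fully seeded synthetic-cohort generator (`simulate_cohort()`) emitting
  mutually consistent FASTA/TSV bundles so the entire pipeline runs with no
  external data, plus `run_haps_pipeline()` and a thin CLI
  (`inst/cli/haps simulate|run`).

Results objects ship `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a 120-patient cohort, score it, and test the survival split:

```r
library(hapscore)
library(dplyr)

cfg    <- cohort_config(n_patients = 120, seed = 2024)
bundle <- simulate_cohort(cfg)

divergence <- hla_divergence(bundle$genotypes, bundle$alleles)
burden     <- tnb_per_locus(filter_binders(bundle$binding), bundle$genotypes)
scored     <- compute_haps(divergence, burden) |>
  classify_haps(cutoff = median(compute_haps(divergence, burden)$haps))

scored |> select(patient_id, hed_mean, tnb_total, haps, haps_class) |> head(4)
#> # A tibble: 4 x 5
#>   patient_id hed_mean tnb_total  haps haps_class
#>   <chr>         <dbl>     <int> <dbl> <chr>
#> 1 P0001          4.40        14  2.65 low
#> 2 P0002          3.90        14  2.55 low
#> 3 P0003          4.80        14  3.77 low
#> 4 P0004          7.77         7  3.10 low
```

`hed_mean` is the mean per-site Grantham divergence over the three loci
(dimensionless; 0 = fully homozygous), `tnb_total` the patient's distinct
predicted binders, and `haps` their combination above. Does the high group
do better on simulated survival (the generator applied a protective hazard
ratio of 0.5 above the median score)?

```r
clin <- left_join(bundle$clinical,
                  select(scored, patient_id, haps_class), by = "patient_id")
cox_hr(clin, "haps_class")
#> # A tibble: 1 x 7
#>      hr ci_low ci_high        p n_high n_low n_events
#>   <dbl>  <dbl>   <dbl>    <dbl>  <int> <int>    <int>
#> 1 0.483  0.314   0.742 0.000880     60    60       96

km_logrank(clin, "haps_class")
#> Kaplan-Meier comparison
#> # A tibble: 2 x 4
#>   group     n events median
#>   <chr> <dbl>  <dbl>  <dbl>
#> 1 low      60     46   14.4
#> 2 high     60     50   22.9
#> log-rank p = 0.0007041
```

The estimated hazard ratio (0.48, CI excluding 1) recovers the generative
effect, and the high-score arm's median overall survival is 22.9 months
versus 14.4. The cut-off scan re-finds the generative threshold from the
data alone:

```r
scan <- scan_cutoff(left_join(clin, select(scored, patient_id, haps),
                              by = "patient_id"), "haps")
scan
#> Cut-off scan over 96 candidates (haps)
#> chosen cutoff 4.34 (HR 0.505); minimum HR
autoplot(scan)   # HR curve with CI ribbon and the chosen cut-off
```

The same flow runs from the shell over a written bundle:

```sh
Rscript inst/cli/haps simulate --n 300 --seed 1 --out cohort/
Rscript inst/cli/haps run --dir cohort/ --out results.tsv
```

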