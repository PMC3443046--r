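# longampr

Simulation, alignment and variant validation for high-indel long-read
amplicon sequencing.

## The problem

Single-molecule long-read platforms trade read length for a peculiar error
profile: errors are dominated by **insertions (~12% of aligned bases)**, with
deletions around 2% and apparent mismatches around 1%, distributed uniformly
along reads that average ~700 bases (about 5% exceed 2,500). Standard
short-read pipelines break on this data in three places: aligners tuned for
mismatches fragment the reads, base qualities need recalibrating from a flat
prior, and the alignment itself can "hide" a true SNP inside an insertion,
biasing pileups toward the reference. `longampr` is a desk-scale,
fully-seeded reimplementation of an amplicon resequencing evaluation
pipeline for this data type, aimed at people studying SNP validation and
discovery with long reads: it simulates the data, processes it, and measures
how well the calls recover a planted truth.

## What's inside

| Stage | Functions | Model |
|---|---|---|
| Synthetic data | `make_panel()`, `simulate_reads()` | diploid amplicon panel with TRUE_DE_NOVO het sites and ARTIFACT (truth-only) sites; log-normal read lengths solved from mean 700 / 5% > 2500; per-base deletion, mismatch and geometric-run insertion events |
| Alignment | `align_reads()`, `align_glocal()` | exact affine-gap glocal DP (read-global, reference-local), match 1 / mismatch 5 / gap open 2 / gap extend 1 — gap open **below** mismatch |
| Error profiling | `profile_errors()`, `gc_bias()`, `read_length_stats()` | per-mode rates over aligned bases, per-cycle error table, GC-binned relative coverage |
| Recalibration | `build_recal_table()`, `recalibrate_reads()` | empirical quality −10·log10((m+1)/(n+2)) over read group × reported quality × cycle × dinucleotide, hierarchical deltas with min-observation fallback |
| Genotyping | `call_site()`, `call_region()` | Bayesian diploid model, P(b\|a) = 1−e or e/3, priors (1−3θ/2, θ, θ/2), Q10 base floor, 50% deletion-fraction site filter |
| Validation | `genotype_and_validate()`, `confusion_metrics()` | forced-allele calls at truth sites → TP/FN/FP/TN → sensitivity/specificity/PPV/NPV |
| Reference bias | `allele_balance()`, `hidden_allele_scan()` | het-site allele balance; recovery of alt bases hidden inside insertions within k bases of the site |
| Orchestration | `run_validation_experiment()`, `run_discovery_experiment()` | one seed, per-stage substreams, byte-reproducible bundles |

Everything is tibble-first and pipe-friendly; result objects have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(longampr)

cfg <- pipeline_config(sim = sim_config(seed = 42), n_amplicons = 4,
                       amplicon_len = 2000, seed = 42)
run <- run_validation_experiment(cfg)

glance(run$profile)
#> # A tibble: 1 × 7
#>   n_aligned_bases mismatch_rate insertion_rate deletion_rate total_rate
#>             <int>         <dbl>          <dbl>         <dbl>      <dbl>
#> 1          562727       0.00864          0.120        0.0180      0.146
#> # ℹ 2 more variables: mean_read_length <dbl>, frac_reads_gt_2500 <dbl>

glance(run$validation)
#> # A tibble: 1 × 9
#>      tp    fp    tn    fn n_no_data sensitivity specificity   ppv   npv
#>   <int> <int> <int> <int>     <int>       <dbl>       <dbl> <dbl> <dbl>
#> 1    38     0    60     0         0         100         100   100   100

run$bias_truth$median_alt_fraction    # ~0.5: unbiased truth alignments
#> [1] 0.5343413
run$bias_aligned$median_alt_fraction  # pulled well below 0.5 by the aligner
#> [1] 0.3333333
sum(run$hidden$n_hidden)              # alt copies sitting inside insertions
#> [1] 246
```

The profile recovers the simulated error modes: insertions ≈ 12.0% of
aligned bases, deletions ≈ 1.8%, mismatches ≈ 0.86% (slightly below the raw
1% because the aligner renders some mismatches — including hidden
heterozygous alternate bases — as gaps). All 98 truth sites are classified
correctly at 70x in this run: 38 planted heterozygous sites called
polymorphic, 60 artifact sites called monomorphic. The allele-balance
medians show the reference bias the scoring scheme induces — the alternate
allele is under-observed in aligned pileups even though the calls are right —
and `run$hidden` locates the 246 missing copies inside insertions anchored
near the sites.

The published confusion table this design emulates is reproduced by
`confusion_metrics(tp = 37, fn = 1, fp = 1, tn = 59)` → sensitivity 97,
specificity 98, PPV 97, NPV 98 (rounded percent).

## Scope

SNP-only (indels are modelled as errors, not called); amplicon panels, not
genomes; no heuristic seeding, mapping qualities, duplicate marking or
VQSR-style filtering. See the methods vignette
(`vignettes/longampr-methods.Rmd`) for the models, parameter defaults and
design decisions.
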