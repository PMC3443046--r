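---
title: "Methods: simulating, aligning and genotyping high-indel long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, aligning and genotyping high-indel long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`longampr` evaluates single-molecule long-read amplicon data for human SNP
validation and discovery. Early single-molecule long reads carry an error
profile unlike short-read data: errors are dominated by insertions (~12% of
aligned bases), followed by deletions (~2%) and apparent mismatches (~1%),
and — crucially — the error rate does not grow with position in the read.
Reads average ~700 bases with a wide length distribution (about 5% exceed
2,500 bases). This vignette describes the models and numerical choices
behind each stage of the package. All coordinates in the package are 1-based
and closed, the R/Bioconductor convention; SAM and VCF positions therefore
serialise without conversion.

## The synthetic data generator

Every downstream stage is testable without any external download because the
generator produces the complete study design: a diploid amplicon panel, a
truth-status VCF and simulated long reads with per-base truth alignments.

**Panel and truth sites.** `make_panel()` draws random amplicon references
(optionally at target GC fractions) and plants two classes of single-base
sites: `TRUE_DE_NOVO` sites, added as heterozygous variants to exactly one
haplotype, and `ARTIFACT` sites, recorded in the truth VCF but absent from
both haplotypes — a correct caller must see them as monomorphic. Defaults are
38 true and 60 artifact sites (98 in total), the validated site counts of the
validation design the package emulates. Sites keep at least 10 bases of
separation and 20 bases from amplicon ends. The default panel layout for the
validation experiment is 4 amplicons of 2,000 bp; the amplicon length matches
the emulated validation design, while the amplicon count is a desk-scale
choice (the source design's count is not stated) that keeps a full run in
tens of seconds.

**Read lengths.** The only stated constraints on the length law are its mean
(700) and upper tail (5% > 2,500). A log-normal is the natural two-parameter
family satisfying both: solving
$\exp(\mu + \sigma^2/2) = 700$ and $(\ln 2500 - \mu)/\sigma = \Phi^{-1}(0.95)$
gives a quadratic in $\sigma$ whose smaller positive root is used
($\sigma \approx 1.245$, $\mu \approx 5.776$); the larger root concentrates
mass near zero and is not a read-length distribution. Draws are truncated
below at 50 bases and above at the available template, so realised read
lengths on short amplicons fall below the law's mean. An infeasible
constraint pair (including a tail fraction of exactly zero, which no
log-normal attains) is rejected with an error.

**Error model.** `simulate_reads()` accumulates reads per amplicon until
the emitted bases reach `depth` times the amplicon length, so the configured
depth is the realised mean fold coverage (the amplicon share of reads is
thereby proportional to its length, and the read count exceeds
`depth * L / 700` by the truncation factor). Haplotype and strand are
uniform, the start uniform along the template. The walk then emits, per
template base:

* a deletion with probability `p_del` (the template base is skipped);
* otherwise the template base, substituted by a uniformly chosen different
  base with probability `p_mis`;
* after every emitted base, a geometric run of uniformly random inserted
  bases with continuation probability `p_ins`.

The geometric-run convention makes the expected fraction of inserted bases
among all emitted bases exactly `p_ins`. Because deletions remove
denominator bases, the recovered deletion rate against aligned read bases is
`p_del/(1-p_del) * (1-p_ins)` (about 1.8% at the default 2%/12%), and the
recovered mismatch rate is `p_mis * (1-p_ins)` (about 0.88% at 1%) — both
within the half-point band used by the recovery checks. Event rates are
position-independent by construction; an optional late-cycle mismatch
multiplier (off by default) exists solely to exercise the recalibrator's
cycle covariate. Reported base qualities are flat Q20, mirroring the flat
prior from which recalibration starts. Every read carries a truth alignment
(start, strand, CIGAR and a per-base event string), which acts as the oracle
for the aligner, profiler and reference-bias tests.

What the generator does **not** emulate: polymerase kinetics, circular
consensus sub-read structure, chimeras, PCR duplicates or quality-value
noise. Tests passing on this generator demonstrate the pipeline's behaviour
under the stated error model, not on any particular instrument's artefacts.

## The aligner

High indel rates break aligners tuned for mismatch-dominated data, so the
scoring follows the adapted convention: match +1, mismatch 5, gap open 2,
gap extend 1 — the gap-open penalty *below* the mismatch penalty. The
alignment is glocal (read-global, reference-local): the read aligns end to
end and free reference gaps at either end become the start offset, never
CIGAR operations. This keeps every read base available to the pileup. The
implementation is an exact three-state affine DP (Rcpp); heuristic seeding
and z-best search of production mappers are deliberately out of scope — with
a small amplicon panel, exact scoring of every read against every amplicon
in both orientations is affordable, and `assign_amplicon()` does exactly
that with a score-only pass before one full traceback of the winner.

Determinism is fixed by tie-breaks: predecessor preference M over I over D,
and the leftmost reference placement among equal-scoring ends. Indel
operations are *not* left-normalised afterwards: the traced CIGAR is
reported as-is because reference bias — the phenomenon under study — lives in
exactly those gap placements. A banded variant (`align_score_banded()`)
restricts the DP to a diagonal corridor of half-width
`max(32, ceil(3 * read_len * p_indel))`; it is an optional accelerator and is
tested for equality with the full DP.

Tests compare scores against a plain-R three-matrix oracle (written before
the implementation) on every read/reference length combination up to 8 x 10
and hundreds of random larger instances, and against
`Biostrings::pairwiseAlignment(type = "global-local")` as a second,
independent library. Every emitted alignment's score is also recomputed from
its CIGAR.

## Error profiling and GC bias

`profile_errors()` decomposes alignments into per-base events. The
denominator for all three mode rates is aligned read bases *including*
insertions, so the three rates sum to the total rate; the source material
never states its denominator, and this is the only choice under which the
insertion fraction equals the generator's `p_ins` exactly. Deleted reference
bases attach to the preceding read base for the positional table, and
reverse-strand alignments are re-indexed from the read's 3' reference end so
"cycle" always means sequencing order. By default every base is counted,
including those over known variant sites (matching the stated plotting
convention, which is why the positional average sits slightly above the raw
error rate); an exclusion switch exists. The positional table truncates at
cycle 1,000 by default, and position-independence is summarised by the
observation-weighted least-squares slope of rate on cycle.

`gc_bias()` computes fold coverage per non-overlapping reference window
(aligned reference-consuming bases divided by window size; 100 bp windows
and 5% GC bins by default, both configurable since the emulated figures
state neither), bins windows by GC fraction and normalises by the global
mean window coverage, so the window-weighted mean relative coverage is 1 by
construction. Bins with fewer than 5 windows or zero coverage are flagged.
The microbial genomes behind the original GC figures are out of scope;
synthetic genomes with controlled GC spectra stand in for them, labelled as
synthetic throughout.

## Base-quality recalibration

Recalibration starts from the flat Q20 prior and replaces it with empirical
qualities keyed on four covariates: read group, reported quality, cycle and
dinucleotide (previous sequencing-orientation base, current base, with an
`N` sentinel at cycle 1). Only M-op bases outside known variant sites count;
insertions and deletions are excluded, so the signal is mismatch-only. The
empirical quality uses additive smoothing,

$$Q = -10\,\log_{10}\frac{m + 1}{n + 2},$$

capped at 60: no estimator is stated in the source material, and the
smoothing keeps error-free bins finite (an empty bin yields the
uninformative ~3.01). Per base, the recalibrated quality composes the
read-group baseline with per-covariate deltas (each level's quality minus
its parent's), a delta applying only where its bin holds at least `min_obs`
observations (default 100), then clamps to [2, 60] and rounds to the nearest
integer. The rounding quantises reported qualities by up to half a point,
which the calibration tests account for. At desk scale (~10^6 bases spread
over ~2,000 distinct cycles) raw per-cycle bins are sparse; analyses that
need per-base stability should raise `min_obs` so sparse bins fall back to
their parent — the tests use 5,000 for exactly this reason. Instrument
qualities, when present in real FASTQ input, are just another reported-
quality level; no correction offset is hard-coded.

## Genotyping

`call_site()` implements standard Bayesian diploid SNP calling with two
adaptations for indel-dominated data. First, bases below Q10 are excluded —
empirical long-read qualities sit around Q20–24, so the usual Q17-style
floor would discard usable evidence. Second, a site where more than
`max_deletion_fraction` of spanning reads carry a deletion is not called
(default 0.5). The stated tolerance ("up to 50% deletions") and the quoted
flag value (0.8) conflict in the source; the prose's 50% is the default and
the threshold is exposed in `genotyper_config()`. Per retained base with
error probability $e = 10^{-Q/10}$: $P(b \mid a) = 1-e$ if $b = a$, else
$e/3$; a diploid genotype averages its two alleles. Genotype priors follow
the conventional diploid parameterisation $(1 - 3\theta/2,\ \theta,\
\theta/2)$ with $\theta = 10^{-3}$, QUAL is $-10 \log_{10} P(\text{hom-ref}
\mid \text{data})$, and a site is polymorphic at QUAL >= 30 (the cited
caller's default emission threshold; the source is silent). Discovery mode
(`call_region()`) tests the most frequent non-reference base at every
position carrying one; validation mode (`genotype_and_validate()`) restricts
the alleles to the truth VCF's ref/alt pair, classifies each outcome
(TP/FN/FP/TN, with NO_DATA for uncovered or filtered sites excluded from
metric denominators) and reports sensitivity, specificity, PPV and NPV at
full precision and rounded to whole percents.

## Reference bias

With gap open below mismatch, an alignment can tie or beat the mismatch
rendering of a true SNP by placing the alternate base inside an insertion
(typically when a sequencing insertion lands adjacent to the site), leaving
the pileup showing the reference or a deletion: mapping stays correct, but
allele balance at heterozygous sites is pulled below 0.5. `allele_balance()`
measures that pull (aligned data versus truth alignments), and
`hidden_allele_scan()` recovers the hidden copies: a spanning read is
VISIBLE if its pileup base equals the alternate allele, HIDDEN if any
insertion anchored within `k` bases of the site (default 5; the emulated
figure gives no window) contains the alternate base, otherwise ABSENT. Only
exact base matches count as HIDDEN — conservative and testable. Local
realignment to *correct* the bias is out of scope. Because the exact median
alternate fraction is not published, the checks are directional: the aligned
median never exceeds the truth-alignment median, and recombining
VISIBLE+HIDDEN never lowers the recovered fraction.

## Pipeline and reproducibility

`run_validation_experiment()` and `run_discovery_experiment()` chain the
stages under one master seed, with per-stage sub-seeds derived from hashed
stage names so any stage can be re-run standalone. Recalibration changes
qualities only, so alignments are computed once and re-used with the new
qualities re-attached. Discovery misses are partitioned into
`low_coverage` (retained depth below 10), `reference_bias` (at least two
reads with the alternate allele hidden in nearby insertions) and `other`;
the real-data discovery counts of the emulated study are not reproducible at
the desk, so only this partition property is asserted. With an `out_dir`
set, each stage product is written in its standard format (FASTA, truth VCF,
FASTQ, SAM) together with a YAML manifest carrying the seed, the package
version and content hashes; identical configurations reproduce every file
byte for byte.

## Problem sizes used by the test-suite and acceptance script

The acceptance script simulates two ~140k-base panels (error-model recovery
and recalibration); the end-to-end validation fixture uses 4 x 2,000 bp
amplicons, 98 truth sites and nominal 70x; positional and calibration
properties use a ~1e6-base truth-alignment simulation. These sizes were
chosen so each stochastic check has at least an order of magnitude more data
than its tolerance needs.

## Known limitations

* SNP-only: indels are modelled as errors and used as a site filter, never
  called.
* The simulator's uniform read starts under-cover amplicon ends; sites are
  therefore kept 20 bases from the ends, and realised coverage is below the
  nominal depth on short amplicons.
* Exact all-against-all DP alignment scales with panel size x read bases;
  the package targets amplicon panels, not genomes.
* The recalibrator's cycle covariate is unbinned; at small data sizes it
  relies on the `min_obs` fallback rather than shrinkage.
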