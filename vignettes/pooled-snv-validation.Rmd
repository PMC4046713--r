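---
title: "Validating and detecting somatic SNVs in non-indexed tumor pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and detecting somatic SNVs in non-indexed tumor pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsnv)
```

# The model

`poolsnv` works at the level of per-site read counts. At a candidate
single-nucleotide variant site, an experiment yields counts of reads
supporting the reference base, the alternate base, and any other base; the
allele fraction is the alternate count over the total depth. Everything in
the package is built from four ideas:

1. **Paired-sample classification.** A true somatic variant is present in
   the tumor but absent from the matched normal. With deep targeted
   counts, the rule "tumor AF ≥ 0.1, normal AF < 0.01, depth ≥ 30 in
   both" separates somatic variants from germline variants that escaped
   upstream filtering (which sit near the tumor = normal diagonal,
   including loss-of-heterozygosity sites at tumor AF ≈ 1, normal 0.5)
   and from upstream false positives (AF ≈ 0 in both).

2. **Linear dilution in pools.** Pooling DNA of N samples before capture,
   without index barcodes, turns a variant with allele fraction $p$ in one
   member into expected pooled fraction $\sum_i w_i p_i$ (equal weights:
   $p/N$). Detection of a known somatic SNV uses the threshold
   $0.05/N$ — half the lowest expected value given the 0.1 validation
   cutoff — inclusive, so that mixing inaccuracy and sampling noise do not
   systematically drop borderline variants.

3. **Private variants give free negatives.** Somatic SNVs are essentially
   never recurrent across patients, so one patient's validated SNVs act as
   known negatives in pools that contain only the other patient. That
   yields a real confusion matrix without extra experiments, and
   FDR $= \mathrm{FP}/(\mathrm{TP}+\mathrm{FP})$.

4. **Expected-AF windows for novel variants.** A novel heterozygous
   variant private to one pool member is expected at $0.5/N$. Scanning
   all target sites and keeping AFs within $[\tfrac12, 2] \times 0.5/N$
   suppresses both sequencing noise (below the window) and variants shared
   by two or more members, i.e. germline polymorphisms (above it), before
   the blacklist and cross-experiment filters finish the job.

# Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `min_tumor_af` | 0.1 | lowest subclonal AF the validation accepts; inclusive |
| `max_normal_af` | 0.01 | contamination tolerance in the normal; exclusive |
| `min_depth` | 30 reads | depth below which an AF is uninformative; inclusive, both samples |
| detection numerator | 0.05 | half of `min_tumor_af`; detection threshold is 0.05/N, inclusive |
| de novo expected numerator | 0.5 | heterozygous single-member variant |
| de novo window | [0.5×, 2×] | inclusive both ends ("less than half / more than twice" is excluded) |
| de novo depth | 30·N reads | reads are unindexed, so "30 per pooled sample" is applied to the total |
| cross-experiment max AF | 0.01 | a variant above 1% elsewhere is germline or a recurrent artifact |
| cross-experiment min depth | 30 reads | shallower experiments are not evidence of absence |

Two conventions are deliberate choices where the procedure's description
leaves room:

- **Allele-fraction denominator.** The default denominator is the *total*
  depth including other-base reads; a `ref_alt` denominator is available.
  At realistic error rates the difference is far below any threshold.
- **Zero-depth sites in the confusion matrix.** Pool sites with no reads
  are excluded from the tallies and reported separately (capture failure
  is not detection failure); `exclude_undetermined = FALSE` counts them as
  misses instead.

The median ratio is defined as observed/expected, so MR > 1 means the
focal sample is over-represented; rescaling divides observed AFs by MR and
caps at 1. The Gini index uses the plain mean-absolute-difference
definition without the $n/(n-1)$ correction (available as an option);
the CV uses the population standard deviation. Both are scale-invariant,
so ordinal comparisons between materials are unaffected by the variant
chosen.

# What the generator emulates — and what it does not

The synthetic cohort reproduces the *statistical structure* the analysis
must cope with:

- subclonal somatic AF clusters, by default a 50/50 mixture at means 0.2
  and 0.45 (SD 0.04, truncated to [0.05, 0.98]) — one patient-like sample
  with a clear two-subclone structure, one dominated by the higher
  cluster;
- shared heterozygous germline panel SNPs (AF 0.5 in tumor and normal),
  germline "escapee" candidates on the diagonal, a loss-of-heterozygosity
  subset (tumor AF near 1), and variant-free candidate sites;
- negative-binomial depths, mean ≈ 1400 with dispersion 0.15 for genomic
  DNA and mean ≈ 1550 with dispersion 0.60 for whole-genome-amplified
  material. Only the *ordinal* claim — WGA coverage is less even — is
  calibrated; the magnitudes are a modeling choice;
- weighted pool mixing: the pooled-stock composition is a fixed study
  condition (the default roster over-represents the focal sample of the
  five- and ten-sample pools 1.2-fold, i.e. weights 0.24 and 0.12),
  while per-capture pipetting noise is a symmetric Dirichlet with
  concentration 5000 (≈ 3–4% relative SD). Replicates share the stock and
  differ only in pipetting and sequencing, which is why replicate pairs
  agree with each other while both show the stock's skew;
- symmetric sequencing error (default 0.001 per base, miscalls uniform
  over the three other bases), with alternate counts binomial given depth.

It does **not** emulate alignment artifacts, mappability or repeat
structure, capture-probe dropout correlated between experiments, strand
bias, or index hopping. Consequences worth stating plainly: the simulated
false-positive counts (and hence FDRs near 0%) and heterozygous-SNP
deviations (≈ 0.011 at depth 1400, pure counting noise) are *better* than
real capture data, where artifacts dominate. Passing tests therefore show
that the decision rules are implemented correctly and behave as designed
under the study's statistical structure — not that real data would achieve
the same error rates.

# Numerical and degenerate-input choices

- All boundary comparisons are exact (`>=`, `<`) with no epsilon; AFs are
  ratios of small integers, so thresholds like $5/1000 = 0.005$ compare
  exactly.
- An allele fraction at depth 0 is an *error* (or `NA` in bulk paths),
  never 0: an unobserved site is not a reference call.
- A germline variant heterozygous in exactly two of N members lands
  *exactly on* the inclusive upper de novo window bound ($2 \times 0.5/N$),
  so under sampling noise the window alone removes only about half of
  such sites. Suppression of that boundary case relies — as in practice —
  on the blacklist (shared polymorphisms are catalogued) and the
  cross-experiment filter; variants in three or more members fall clearly
  above the window.
- Each count-table row carries one alternate allele; the de novo scan
  evaluates the row's recorded alternate base rather than re-deriving the
  maximal non-reference base, which is the natural contract when the
  input is a count table rather than a pileup.
- Every stochastic component draws a substream seed from one master seed
  (`derive_seed`), so full runs are bit-reproducible and replicates are
  decorrelated by construction.

# Problem sizes

The default simulated study uses 227 and 305 somatic truths for the two
focal samples, 19 panel SNPs, ~490 germline-escapee and ~490 null
candidates, 2 variants per uncharacterized sample, and 1500 background
target sites — about 3 × 10³ sites per experiment across 12 experiments,
which runs in a couple of seconds. Power checks in the test suite use
2000 Monte-Carlo replicates per cell against the analytic binomial tail;
evenness oracles compare against the brute-force double sum up to n = 50.
These sizes were chosen so the statistics of interest (mixture means,
median ratios, detection rates) are estimated to well inside the asserted
tolerances.

# Known limitations

- No member attribution for pool calls (impossible without indexing or
  follow-up genotyping; the simulator's truth table provides it for
  evaluation only).
- The binary somatic/non-validated outcome does not separate the
  germline-escapee, upstream-false-positive and LOH patterns, although
  the generator produces all three.
- Overlapping-pool designs that would allow combinatorial member
  attribution are out of scope.
- BAM/pileup parsing is out of scope: the contract starts at count
  tables (BED target regions, TSV/VCF site lists and the TSV count
  dialect are the supported inputs).
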