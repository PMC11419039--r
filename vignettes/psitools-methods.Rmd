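---
title: "Methods: PSI-based splicing analysis with psitools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSI-based splicing analysis with psitools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psitools)
```

This vignette is the package's own account of the statistical procedures
it implements: the models and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the procedure left room.

## 1. PSI and the differential-splicing model

Percent spliced in for one alternative-splicing event in one sample is

$$\mathrm{PSI} = 100 \cdot \frac{I}{I + E},$$

where $I$ and $E$ are length-normalized counts supporting the inclusion
and exclusion isoform. Cells with $I + E$ below `min_total` are treated
as missing. The floor defaults to 10 normalized counts: the upstream
tooling leaves it unstated, and 10 is the smallest value that prevents
single-read cells from producing degenerate PSI of exactly 0 or 100.
PSI is scale-invariant, so the choice of length normalization upstream
does not affect any downstream statistic beyond the floor.

`compare_groups()` tests each event for a mean PSI difference between two
groups with a two-sample t-test. The default is the pooled-variance
flavor, matching the customary default of the splicing tool family this
pipeline models; Welch is available via `test_flavor = "welch"` because
PSI variance is mean-dependent near the boundaries. The t-test treats PSI
as approximately normal within group — adequate at moderate coverage and
interior PSI, questionable for PSI near 0/100 at low coverage, which is
one reason the coverage floor exists.

Multiplicity is handled by Benjamini–Hochberg across *tested* events only
(events with at least two non-missing values per group); untested events
are reported but never enter the correction family, matching the
per-comparison adjustment of the original analyses. An event is called
significant when $p_{\mathrm{adj}} < 0.25$ and $|\Delta\mathrm{PSI}| \ge
10$ — both thresholds taken from the published analysis and kept as
defaults everywhere.

Degenerate events are resolved deterministically: both groups constant
and equal gives $p = 1$; constant and unequal gives the smallest positive
double. This avoids NaN propagation without inventing evidence in either
direction.

Event-level exclusions follow the published filters:
`diff_splicing_rules()` removes junction-only alternative 5′/3′
splice-site events (weak read support) and intron-retention events whose
junctions are not annotated; `burden_rules()` additionally removes all
junction-only events and events missing in more than 25% of samples. The
missing fraction is computed over all samples of the analysis cohort (not
per group), and after the coverage floor has been applied — the source
analysis does not say whether its 25% rule counts cells missing before or
after the floor; counting after is the conservative reading for the
burden statistic, which consumes the same floored PSI matrix.

### Redundancy

Splicing tables describe the same underlying change several times (e.g. a
cassette exon seen from either flanking junction). `make_nonredundant()`
keeps, per redundancy group, the event with the smallest adjusted p,
breaking ties by larger $|\Delta\mathrm{PSI}|$ and then by smallest event
id. The original selection rule is not documented; this rule is the
natural "most significant representative" choice and is deterministic.
For real tables without explicit groups, `assign_redundancy_groups()`
offers a conservative proxy: events of the same gene and event type are
linked when their identifiers share any long numeric coordinate token.
It is isolated behind one function so a better annotation can replace it.

### Event-type distributions

Significant, non-redundant events are tallied over the eight categories
(cassette, mutually exclusive, coordinate cassette, alternative 5′/3′
splice site, alternative first/last exon, intron retention).
`compare_distributions()` tests the overall 2×8 table exactly when the
network algorithm can enumerate it, otherwise falling back to a
Monte-Carlo p with a fixed seed and $10^5$ resamples; per category it
runs a 2×2 Fisher test of that category against all others,
BH-corrected across the eight categories (the "row-wise" analysis).

## 2. The outlier-burden statistic

For each event, the cohort median and IQR of PSI are computed over
non-missing samples; a sample is *altered* at that event when

$$|\mathrm{PSI} - \mathrm{median}| > 1.5 \cdot \mathrm{IQR}
\quad\text{and}\quad |\mathrm{PSI} - \mathrm{median}| > 10.$$

A sample's burden is its number of altered events. Two readings of the
source rule were possible and both are settled here, with the flag
`k`/`min_dev` arguments keeping them configurable:

- **Two-sided deviation.** The rule is applied to the absolute deviation,
  so both excess inclusion and excess exclusion count. A one-sided
  reading would halve the statistic's sensitivity for no stated reason.
- **"10%" means 10 PSI points.** PSI is already a percentage, so the
  second clause is an absolute margin of 10 points, not a relative 10% of
  the median.

Quartiles are linearly interpolated order statistics (R's default type 7,
the common default of mainstream numeric libraries), chosen for
reproducibility across implementations; whether the original analysis
used interpolated quartiles or Tukey hinges is unknowable from the text,
so the method is a `quartile_type` option. With IQR = 0 the rule reduces
exactly to the 10-point margin. Events with fewer than four usable values
are excluded — no meaningful IQR exists below that.

Medians and IQRs include the sample being flagged (the source computes
them "from samples" without exclusion); at cohort sizes of tens of
samples the self-inclusion bias is negligible, and a leave-one-out
variant can be composed by the user if needed.

Group burdens are compared with a two-sided Mann–Whitney U test: exact
when both groups have at most eight observations and no ties, otherwise
the normal approximation with continuity and tie correction. Burden
counts tie heavily, so the approximation is the realistic path at cohort
scale; its size is verified by simulation in the test suite.

## 3. Preranked enrichment

Ranked lists: expression results are filtered to padj < 0.05 and scored
by signed log2FC (duplicates keep the largest |log2FC|); splicing results
are filtered to padj < 0.25 and scored by |ΔPSI| (per gene, the event
with the largest |ΔPSI| wins — multiple events per gene are the rule, not
the exception). Splicing scores are all non-negative, so splicing-based
enrichment asks only "is this set unusually *affected*", not in which
direction. Ties in the ranking are broken by gene symbol for
determinism.

The enrichment score is the weighted Kolmogorov–Smirnov-style running
sum: walking the list, hits add $|s|^w / \sum_{hits} |s|^w$, misses
subtract $1/(N - N_{hits})$, and ES is the signed maximum deviation from
zero. The weight defaults to $w = 1$, the "weighted" statistic and the
long-standing default of the reference tool; $w = 0$ gives the classic
KS walk. Magnitude ties between the positive and negative excursion
resolve to the positive one; a set covering the whole universe has no
misses and scores ES = 1 by its monotone walk. The implementation
computes ES only at hit boundaries (O(hits) per evaluation); tests prove
it equal to the full running-sum recomputation and to an independent
implementation.

The null for preranked input is gene-set permutation: size-matched random
sets drawn from the ranked universe, `n_perm` times. Nominal p uses the
add-one estimator over same-sign null scores (so $p \ge 1/(n_{perm}+1)$);
NES divides ES by the mean same-sign null |ES|; FDR q is the permutation
ratio — the fraction of the pooled, per-set-normalized null NES at least
as extreme, divided by the fraction of observed NES at least as extreme,
computed separately for positive and negative NES and clipped to [0, 1].
The exact q formula of any given external tool version varies; this
implementation targets the published method and is validated by
calibration (nominal p uniform under random sets) rather than
bit-equality with a tool. `fdr_method = "bh"` applies BH to the nominal
p-values instead, for comparison.

Permutation streams are seeded per distinct set size from the master
seed: results are reproducible and invariant to the order of the gene-set
collection, and equal-size sets share a null, which is statistically
equivalent to independent size-matched sampling.

Reporting follows the published convention: NES are kept where FDR q <
0.25 and nominal p < 0.05, and non-passing cells of the comparisons ×
sets matrix are set to 0 (`filter_enrichment()`), ready for heat-mapping.
`restrict_gene_set()` implements evidence-based set restriction (e.g.
keeping only genes with differential protein–RNA binding) as an
order-preserving intersection.

## 4. Mutant-allele mRNA ratio

The mutant fraction is the mutant-base read count over the total of all
four bases at the locus, per sample, requiring `min_depth` (default 20)
reads — below that, a fraction is too noisy to band-classify (binomial
s.e. ≈ 0.11 at depth 20). Classification uses three bands with inclusive
bounds: quasi-WT at fraction ≤ 0.31 (the top of the published quasi-WT
range 0.27–0.31), typical at ≥ 0.43 (the published "0.43 or above"), and
indeterminate between. A two-band scheme could have been forced by
splitting the gap, but the published ranges genuinely leave (0.31, 0.43)
unassigned — and the double-mutant cell lines of interest fall partly in
that gap — so the three-band scheme is the default and both edges are
arguments. Whether upstream read filters (mapping quality) were applied
before counting is absorbed into `min_depth` and the user's pileup.

Co-occurrence with a second driver is a 2×2 Fisher exact test
(classes × driver status, indeterminates excluded), reporting both the
sample cross-product odds ratio and the conditional MLE. Fraction
comparisons between genotypes reuse the Mann–Whitney machinery.

## 5. What the generator emulates — and what it does not

`simulate_splicing_cohort()` draws, per event, a baseline PSI from
Beta(2, 2)·100 (interior-heavy, symmetric — typical of quantifiable
events), plants a ±`effect_dpsi` shift in the test group for a fraction
of events (clamped to [0, 100], with the clamped truth recorded), and
generates counts as Poisson totals (mean `coverage_mean`) with
beta-binomial inclusion counts at overdispersion ρ (`dispersion`,
default 0.01 — mild biological-replicate scatter). Missing cells blank
both counts, mimicking coverage dropout. Redundant events are planted as
duplicates with jittered identifiers and counts, giving the
non-redundancy step a real target. The burden generator shares one
baseline per event across samples plus Gaussian noise (sd 2 PSI points)
and displaces a fraction of events in designated outlier samples by 30
PSI points (direction chosen to stay in range), enriched in the exposed
group. Expression results and pileups are simulated directly at the
summary-table level.

The generators reproduce the *statistical structure* the analyses assume
— two groups with replicates and clone batches, eight event categories,
missingness, redundancy, planted effects with recorded truth — not the
biology of splicing: no real noise model of PSI is published for these
data, so the beta-binomial choice is a reasonable stand-in, and passing
recovery tests demonstrates correctness of the pipeline's inference, not
that real data meet its assumptions. Event discovery from alignments,
genomic coordinates with meaning, and correlated events within a gene are
all out of scope.

All randomness flows from a single integer seed; each table derives a
deterministic sub-stream, so identical configurations regenerate
byte-identical output (the demo manifest checksums are the regression
test for this).

## 6. Problem sizes and numerical notes

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path with tight Monte-Carlo error: differential
benchmarks use 2000 events × 12 samples × 50 replicate cohorts
(the false-discovery benchmark, `benchmark_fdr()`); burden recovery uses
500 events × 20 samples; enrichment calibration uses 200 random sets of
30 genes in a 500-gene universe at 200 permutations; the demo uses 400
events and finishes in about a second. The observed mean
false-discovery proportion of the caller under the benchmark conditions
is well below the nominal BH level, because the |ΔPSI| ≥ 10 margin
discards most BH false positives — the nominal level is therefore an
upper bound, not an estimate.

Known limitations: no paired designs or covariate adjustment in the
differential stage; no leading-edge analysis in the enrichment stage; the
redundancy proxy for unannotated tables is deliberately conservative; and
the t-test's normality assumption thins out for events pinned near PSI 0
or 100.
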