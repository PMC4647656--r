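---
title: "Models and methods in rdipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rdipr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rdipr)
```

rdipr implements the downstream statistics of a directional RDIP-seq
experiment: mapping RNA:DNA hybrids (R-loops) genome-wide and asking,
per locus, which strand carried the RNA, how its base composition is
skewed, where in the genome the hybrids sit, and what regional features
predict their density.  This vignette records the models, the tunable
parameters and their defaults, the numerical decisions, and what the
test suite does and does not establish.

## RNA-strand inference from SAM flags

The library chemistry incorporates dUTP into the strand synthesized
complementary to the RNA of the hybrid and degrades it with UNG before
amplification.  The surviving second-in-pair read therefore carries the
RNA-derived sequence, and its alignment orientation identifies the
strand of origin.  In SAM terms the informative flags are composed from
template bits, not hard-coded:

* top strand: paired (0x1) + proper pair (0x2) + mate reverse (0x20) +
  second in pair (0x80) = **163**
* bottom strand: paired + proper pair + read reverse (0x10) + second in
  pair = **147**

All other flags — first-in-pair mates (83/99), discordant, secondary,
duplicate, supplementary, unmapped — are excluded as strand evidence.
A read pair is assigned to a peak when the second-in-pair alignment
overlaps the peak by at least 1 bp; the RNA-derived read is the evidence
carrier, so its position (not the fragment's) decides membership.

Each peak is scored $s = (n_{top} - n_{bottom}) / (n_{top} +
n_{bottom}) \in [-1, +1]$, with $s$ undefined (and the strand call
`ambiguous`) for peaks with no classified reads.

**The 10 % filter.**  "Remove the 10 % of peaks with intermediate
strandedness" is implemented as a quantile rule: the
$\lfloor 0.1\,n \rfloor$ peaks with smallest $|s|$ are removed, with
ties broken by lower read depth first and genomic order second.  A
fixed two-sided band around 0 would remove a data-dependent count; the
quantile reading removes exactly the stated fraction and is the
recorded design decision (the alternative is not distinguishable from
the published description).

## Nucleotide skew statistics

On the top strand of an interval with base counts $A, C, G, T$ (N never
enters a denominator):

$$\mathrm{AT\ skew} = \frac{A - T}{A + T},\qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},\qquad
  \mathrm{purine\ fraction} = \frac{G + A}{A + C + G + T}.$$

These are the standard skew definitions; under reverse complement both
skews negate and purine fractions of a strand and its complement sum
to 1, which the property suite checks against a brute-force character
counter.  Zero-denominator statistics are reported `NA`, never 0 — a
sequence with no A or T has no AT skew, not a neutral one.

For RNA-strand statistics the peak sequence is reverse complemented
when the strand call is `-`, so every reported composition is that of
the inferred RNA 5'→3'.  Positional profiles rescale each peak to unit
length in that orientation before binning, so a 5' displacement of the
purine-rich component appears as a decreasing profile regardless of
peak length.

## Genomic-context enrichment

Context assignment is exclusive: each peak takes the highest-precedence
label among features it overlaps (default promoter > lncRNA > gene
body), falling back to intergenic, so the tally partitions the peak
set.  Per-feature enrichment is kept separate (a peak may be both
promoter and repeat): observed overlap is the basepair intersection of
the peak union with the feature union, expected is peak occupancy ×
feature fraction of the genome, and significance comes from a
permutation null.

**The permutation null** relocates every peak uniformly within its own
chromosome, preserving lengths, allowing overlaps among relocated
peaks, and not excluding assembly gaps unless a mask is supplied (the
original analysis does not state whether gaps were excluded; the mask
argument records that ambiguity).  The p-value is two-sided and
add-one corrected: $p = \min(1,\ 2(\min(\#\{null \ge obs\},
\#\{null \le obs\}) + 1)/(n_{perm}+1))$, with resolution
$1/(n_{perm}+1)$; the default $n_{perm} = 999$ gives resolution 0.001
at desk scale.  Internally the null loop runs on linearized
coordinates with prefix-sum overlap so 200 calibration runs × 199
permutations finish in about a minute; the fast path is exactly
equivalent to `shuffle_intervals()` + `overlap_bp()` draw-for-draw,
which the unit suite asserts.

Promoters default to TSS ± 1 kb (conventional and configurable; the
source analysis never defines its promoter extent).  Methylation
contrasts are unweighted per-CpG means, inside peaks versus all sites,
with a Wilcoxon rank-sum comparison.

## Strand-oriented metagene profiles

Bins are 100 bp windows anchored at the TSS (or TES) and indexed in
transcriptional orientation (bin +1 = first window downstream); for
minus-strand genes genomic coordinates are flipped.  A peak
intersecting a bin increments it once per (gene, bin) — presence
counting, not bp weighting — in the *sense* channel when the hybrid's
RNA strand equals the gene strand, else *antisense*.  Defaults span
2 kb upstream to 5 kb downstream of the TSS, covering the
first-1.5-kb-downstream signal with context.  Expression strata are a
zero-expression class plus quartiles among expressed genes (the
stratification count is not fixed by the source analysis; quartiles are
the default, `k_quantiles` the knob).  The proportions test is the
two-sample chi-square without continuity correction.

## rDNA coverage

The rDNA repeat unit is treated as a named auxiliary reference span
with unit-relative coordinates rather than physically spliced into a
chromosome — the same analysis with cleaner coordinates.  The pipeline
is: exact-duplicate sequence removal (first occurrence kept), per-bp
depth, input subtraction, then means over non-overlapping 50 bp windows
with the terminal partial window averaged over its true width.
Whether the original subtraction was library-size scaled is not
printed, so both modes exist: `per_million` (default — "frequencies"
implies normalization) and `raw` for exactness tests.  Negative values
are retained; they are informative about input excess.

## Lasso-path regression of peak density

The response is the peak count per window (500 kb default), scaled to
the nominal window width for partial terminal windows, centered;
covariates (per-window feature fractions or track means) are centered
and scaled to unit Euclidean norm.  Standardization is not stated in
the source analysis but is required for the entry order to be
scale-free; it is the default and the documented choice.

`lars_lasso_path()` traces the exact lasso solution path
$\hat\beta(\lambda)$ of $\tfrac12\lVert y - X\beta\rVert^2 +
\lambda\lVert\beta\rVert_1$ by the least-angle homotopy **with the
lasso modification**: between knots the active coefficients move
linearly along $(X_A^\top X_A)^{-1} s_A$, a variable enters when its
absolute residual correlation reaches the active level, and leaves when
its coefficient crosses zero.  Invariants checked to $10^{-8}$: active
correlations tie at $\lambda$, inactive ones never exceed it.  The path
agrees with an independent coordinate-descent solver to $10^{-6}$ on
random small instances.  Numerical guards: knots closer than $10^{-10}$
terminate the path; a candidate whose Gram submatrix has reciprocal
condition below $10^{-12}$ is skipped with a warning.

**The covariance test.**  For the $k$-th entry at knot $\lambda_k$ with
next knot $\lambda_{k+1}$,

$$T_k = \frac{\langle y, X\hat\beta(\lambda_{k+1})\rangle -
\langle y, X_A\tilde\beta_A(\lambda_{k+1})\rangle}{\hat\sigma^2},$$

where $A$ is the active set just before the entry and $\tilde\beta_A$
the lasso refitted on $A$ alone at the same $\lambda_{k+1}$ (computed
by re-running the path on the submatrix and interpolating — the path is
piecewise linear in $\lambda$).  Under the null that $A$ already
contains all signal variables, $T_k$ is asymptotically Exp(1), so
$p = e^{-T_k}$.  The noise variance $\hat\sigma^2$ comes from
full-model OLS residuals when $n > p + 1$ (the regional regression has
thousands of windows and tens of covariates, so this is the standard
regime); otherwise from the saturated end of the path, with the
degrees-of-freedom bookkeeping documented in `estimate_sigma2()`.

**Calibration design.**  The Exp(1) limit is asymptotic in $p$ and the
convergence is logarithmic; in addition $\hat\sigma^2$ contributes
chi-square noise when its residual degrees of freedom are small.  A KS
test over 500 null replicates is sensitive enough to detect these
finite-size gaps: at $n = 100, p = 10$ it sits exactly at the
$\alpha = 0.01$ boundary *even with the true variance plugged in*.
The calibration experiment therefore runs where the asymptotic claim
lives: $n = 300$, $p = 100$, $\hat\sigma^2$ from OLS (199 df), where
the KS statistic returns to its noise floor.  The small-$p$ regime is
still covered by the mean check ($\bar T_1$ within 3 SE of 1 at
$n = 100, p = 10$), which is robust to the tail discrepancy.  This is a
property of the statistic, not of the implementation; analysts applying
the covariance test at small $p$ should read its p-values as
approximate.

## The synthetic-data generator

The generator states a world with the signal structure the analysis is
built to detect; all distributional choices are stand-ins (the real
generative process of hybrid formation is unknown) and are listed here
with their defaults:

| parameter | default | meaning |
|---|---|---|
| `chrom_lengths` | 2 × 5 Mb | uniform-composition background genome |
| `n_genes` | 200 | log-normal lengths, median 20 kb |
| `promoter_width` | 2 kb | TSS ± 1 kb |
| `n_peaks` | 500 | normal lengths, mean 600 bp (sonication scale), min 200 bp |
| `reads_per_peak` | Poisson(50) | read pairs per peak |
| `p_strand` | 0.95 | probability a pair reports the planted strand |
| `delta` | 0.15 | planted RNA-strand purine excess (E[purine] = 0.65) |
| `promoter_enrichment` | 5 | placement multiplier inside promoters |
| `tss_peak_fraction` | 0.25 | peaks planted in the first 1.5 kb downstream of expression-weighted TSSs |
| `zero_inflation` | 0.3 | fraction of silent genes; expression log-normal |
| `meth_decrement` | 0.1 | Beta-mean drop inside peaks (0.7 → 0.6) |
| regression | 40 × 12, AR(1) ρ = 0.3 | planted coefficients (3, 2, 1, 0, …), noise SD 0.5 |

Mechanics worth knowing: peak sequences are *rewritten* in the genome
with per-base purine probability $0.5 + \delta$ on the planted RNA
strand (the complement strand gets the mirror), so sequence-level and
read-level signals agree; reads are emitted directly as aligned SAM
records (no FASTQ/aligner round trip — the package's scope starts at
alignments, and this keeps tests hermetic); placement enrichment uses
the exact mixture $q = m f / (m f + 1 - f)$ for promoter fraction $f$
and multiplier $m$, which is also the closed form the tests check.

What the generator does **not** emulate: sequencing error, fragment
size variation, GC bias, mappability, multi-mapping, copy-number
structure, or any thermodynamic model of hybrid stability.  A green
test therefore establishes that the statistics recover *planted*
signals of realistic magnitude at desk scale — not that the pipeline
reproduces any real dataset's numbers, which would require the original
accession and genome-scale annotation.

## Degenerate inputs and tie-breaks

* Peaks with no classified reads: score `NA`, call `ambiguous`,
  excluded (and counted) by the skew and metaplot stages; the decile
  filter refuses `NA` scores.
* `s = 0` peaks are called `ambiguous`, not arbitrarily `+`.
* Decile filter ties: lower read depth removed first, then genomic
  order — deterministic output for identical inputs.
* Zero-occupancy features: enrichment ratio `NA`, reported as such.
* Constant covariates are dropped with a warning before
  standardization; a constant response is a hard error (no noise
  variance).
* Empty peak sets: overlap proportions return `NA` with `n = 0` rather
  than silently returning 0.

## Known limitations

* SAM text only (convert BAM upstream); adequate at desk scale, not
  for full-depth libraries.
* The strand model trusts the proper-pair flag; aberrant pairs are
  silently excluded rather than rescued.
* The permutation null is uniform-within-chromosome; real placement
  nulls (GC- or mappability-matched) are out of scope, though the mask
  hook admits a territory restriction.
* Covariance-test p-values at small $p$ are approximate (see above).
* The exclusive-context precedence is a modeling choice; changing the
  order changes the tally, which is why it is an explicit argument.
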