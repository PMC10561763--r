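---
title: "Classifying X- and Y-linked contigs from male/female read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying X- and Y-linked contigs from male/female read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexlinkr)
library(dplyr)
```

## The problem and the model

In an XY system, a female genome carries two copies of every autosome and
of the X and no Y, while a male carries two autosomal copies and one copy
each of X and Y. Whole-genome sequencing of both sexes therefore encodes
chromosome linkage in read depth: relative to the library's overall depth
$D$, an autosomal locus is covered at $D$ in both sexes, an X-linked locus
at $D$ in females but $D/2$ in males, and a Y-linked locus at $D/2$ in
males and not at all in females. `sexlinkr` turns this into contig-level
calls for a draft assembly:

1. tile each contig with fixed windows and record GC and mean raw depth
   per window (`profile_sample()`);
2. fit an expected-depth-vs-GC curve per sample and divide it out
   (`fit_gc_model()`, `correct_depth()`);
3. scale corrected depth to copy number, $\mathrm{cn} = 2\,d_{\mathrm{corr}}/D$,
   where $D$ is the sample's length-weighted mean raw window depth — the
   overall sequencing depth (`add_copy_number()`);
4. average copy numbers across replicates of a sex and take the median
   across each contig's windows (`combine_replicates()`, `contig_cn()`);
5. classify each contig from its male and female copy number
   (`classify_contigs()`).

The classification rules, applied in a fixed order:

* **Y-linked** — single copy in males ($|\mathrm{cn}_m - 1| \le 0.35$) and
  not detectable in females ($\mathrm{cn}_f \le 0.2$);
* **X-linked** — at most a single male copy
  ($\mathrm{cn}_m \le 1.35$), present in females, and a twofold
  female:male ratio ($\mathrm{cn}_f/\mathrm{cn}_m \in [1.6, 2.4]$);
* **autosomal** — balanced ratio
  ($|\mathrm{cn}_f/\mathrm{cn}_m - 1| \le 0.35$) with both copy numbers
  near diploid ($\in [1.65, 2.35]$); a balanced pair away from the
  diploid level (say 1.5/1.5) is deliberately left ambiguous;
* otherwise **ambiguous**; contigs without usable windows are
  **unclassifiable**.

Y precedes X precedes autosomal because female absence is the most
specific signature. With the default tolerances the three acceptance
regions are disjoint (checked at construction and by a grid test), so the
order only matters for degenerate threshold choices. A contig absent in
*both* sexes is deliberately ambiguous, not Y-linked: a Y call requires
male presence. The tolerances themselves are free parameters of
`linkage_thresholds()`; the defaults are wide enough to absorb Poisson
depth noise at 30x with three replicates per sex and narrow enough to
keep the regions disjoint.

## GC correction

Sequencing depth depends systematically on window GC. We model expected
depth as a smooth function of GC using LOESS (tricube weights, local
linear fit, span 0.3 by default), evaluated on a 101-point GC grid;
corrections interpolate linearly on the grid, which makes them cheap and
deterministic. Fitted values are floored at $10^{-3}$ of the reference
depth so the correction ratio is always finite, and evaluation outside
the observed GC range clamps to the nearest endpoint.

A subtlety dominates the design here: the fitting sample itself contains
sex-linked windows at half (or zero) depth. If those windows cluster
anywhere along GC — and with a handful of sex-linked contigs they always
do — a curve fitted through *all* windows is dragged toward the mixture
level with a GC-dependent distortion, which later inflates male copy
numbers. We therefore treat window depth explicitly as a constrained
mixture $\ell \cdot b(\mathrm{gc})$ with $\ell \in \{D, D/2, 0\}$:
starting from the flat global 0.7 depth quantile (an upper quantile
starts on the diploid level no matter how windows cluster along GC,
whereas a running median sits at a mixture-fraction-dependent
sub-diploid quantile), each window is assigned to the copy level nearest
its depth ratio against the current curve, the LOESS is refitted on
diploid-assigned windows only, and assignment and refit are iterated
three times. The result is the *diploid* bias curve, so corrected diploid
depth equals the sample's overall raw depth by construction and the
copy-number formula in step 3 is centred without any further
normalisation. `refit_diploid = FALSE` gives the plain single-pass fit
for diploid-only data. The robust (bisquare) LOESS family guards against
residual off-level leakage in the refit subset.

Windows with more than 50% N (or no A/C/G/T at all) are excluded from
fitting and from the depth baseline but still receive a corrected depth —
via the clamped nearest-GC expectation, or factor 1 when GC is undefined
— so gappy contigs are never silently dropped.

## The synthetic study

Validation runs on a synthetic study whose generative structure is
exactly what the inference assumes — a known diploid genome with labelled
autosomal, X and Y contigs and simulated male/female coverage tracks —
so every call can be checked against truth. The default `sim_config()`
encodes the study conditions used throughout the tests:

* 30 contigs — 20 autosomal, 5 X, 5 Y — with lengths uniform in
  300–600 kb (3–6 windows per contig at the 100 kb default window);
* segment-wise GC heterogeneity: constant-GC segments of 100 kb with
  target GC drawn uniformly from 0.25–0.65;
* mean diploid depth 30x; multiplicative GC bias
  $b(\mathrm{gc}) = \exp(-s\,(2(\mathrm{gc}-0.5))^2)$ with $s = 0.5$
  (unimodal, $b(0.5) = 1$, monotone on each side of 0.5; the form is
  recorded in the emitted config so the correction cannot silently
  overfit one functional family);
* per-window Poisson counts (negative binomial with dispersion 0.05
  available), drawn per sample from named substreams of one master seed,
  so adding a replicate never perturbs the genome or other tracks;
* three male and three female tracks, mirroring a triplicate-per-sex
  whole-genome design.

Depth is simulated directly at window resolution, not via read placement:
the inference consumes only window depths, so a read-level simulator
would add cost without exercising any additional code path. Consequences
for interpretation: passing tests show the *statistical* machinery
(windowing, GC correction, copy-number scaling, rule thresholds,
replicate averaging) recovers truth under the assumed generative model.
They do not exercise mappability artefacts, reference bias, collapsed
repeats beyond what the median absorbs, pseudoautosomal regions (the
simulator labels whole contigs), or alignment-level errors in real depth
tracks. The per-contig median and the `low_evidence`/`min_windows = 3`
flag are the main defences the pipeline offers against such artefacts on
real data.

On this scenario the full pipeline is exact in the noise-free limit and
recovers ≥95% of contigs (in practice ~97–100%) under Poisson noise
across seeds, never calling a true X contig Y-linked; the testthat suite
and `scripts/acceptance.R` recompute these numbers.

## Copy-number baseline

The baseline dividing corrected depth is the sample's length-weighted
mean raw window depth over non-excluded windows — the overall sequencing
depth, reproducible from the depth track alone. Because the GC model is
anchored to the diploid mixture component, corrected diploid windows sit
at exactly this level, so autosomes land at cn 2 and hemizygous contigs
at cn 1 even when a third of the assembly is sex-linked. A
length-weighted *median* of raw depth is available
(`baseline = "median"`) for samples with pathological high-depth tails.
An explicit numeric baseline can be passed when the true diploid depth is
known.

## Haplotig purging

Redundant allelic contigs are detected with canonical k-mers (k = 21,
odd so no k-mer is its own reverse complement; k-mers containing N are
skipped). K-mers are classed by assembly-wide occurrence count — unique
(1), duo (2), repeat (≥3) — and only non-repeat evidence is used: a
haplotig pair shares *duo* k-mers across the length of the shorter
contig. The pairing score is
$s(a,b) = \#\text{shared duo}/\#\text{duo in the shorter contig}$, so a
short haplotig fully contained in its primary scores near 1; pairs with
$s \ge 0.6$ *and* at least 50 shared duo k-mers become edges (the
absolute floor exists because a contig with no allelic partner has
almost no duo k-mers, and a single chance collision would otherwise
score $s = 1$). Within each connected component the longest contig is
kept and its neighbours purged, recursing on the remainder with
lexicographic tie-breaks — a deterministic greedy rule, not a
maximum-weight independent set. Counts are assembly-internal rather than
read-based, which is the appropriate formulation when only the assembly
is available.

At the simulated duplication parameters (90% length, 1% substitutions)
the expected surviving-k-mer fraction is roughly $0.99^{21} \approx 0.81$
of the shared span, and mutated k-mers become unique rather than duo, so
genuine pairs score near 1 — comfortably above the 0.6 threshold.

## Assembly statistics

`nx()` uses the ≥ cumulative convention (N50 is the length at which the
cumulative sum of descending lengths first reaches half the total);
`fold_ratio()` rounds half to even at the requested precision; GC%
excludes N from the denominator. These conventions are stated because
summary tables in the wild rarely define them.

## Numerical choices and degenerate inputs

* LOESS grid: 101 points; fit floor $10^{-3} \times$ reference depth;
  out-of-range GC clamps; undefined GC corrects with factor 1.
* The LOESS span is floored so every local fit sees at least ~25
  windows: with few windows a small span hugs noise and swings across GC
  gaps, and the bias curve is smooth enough that a wide span is the
  right bias/variance trade-off at small sample sizes.
* Fewer than 20 usable windows is an error (the advice is to shrink the
  window); zero GC variance yields a constant model, and applying a
  constant model to GC-varying data warns.
* If the iterative diploid refit collapses (any grid value below 5% of
  the reference — a degenerate assignment), the single-pass fit is used
  instead.
* Contig medians average the central pair for even window counts;
  contigs with no usable windows are unclassifiable rather than guessed.
* All randomness flows from one integer seed through named substreams
  (genome, duplicates, per-sample depth).
* Validation problem sizes (9–30 contigs of 30–600 kb) were chosen so
  the whole suite exercises every stage end-to-end in minutes on one
  CPU; they are stated here so results can be reproduced exactly.

## Known limitations

* A GC bias stronger than ~2x across the observed GC range lets the
  diploid and half-depth bands overlap in raw depth, degrading the
  level-assignment initialisation; within the simulated range
  (strength ≤ 1) this does not occur.
* Whole-contig calls cannot resolve pseudoautosomal segments or X/Y
  chimeras; the per-window copy numbers are exposed for inspection
  (`keep_intermediates` in `run_classify()`), but no within-contig
  segmentation is attempted.
* The purge step detects redundancy only through shared duo k-mers;
  diverged haplotigs below ~97% identity (where $0.99^{21}$-style
  survival collapses) or duplications present in three or more copies
  (repeat k-mers, deliberately ignored) are out of reach.
* Depth tracks are trusted as given; no mappability masking or repeat
  masking is applied before copy-number calling (an exclusion flag per
  window is the extension point).
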